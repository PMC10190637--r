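# Training protocols under the increase-only constraint: the hardware
# one-shot Widrow-Hoff iteration, the touchpad spike-count protocol, and an
# idealized pulse-quantized LMS trainer. No protocol ever decreases a
# conductance; weight decreases are realized by growing the opposing device
# of the two-wire pair.

#' Create a pulse schedule
#'
#' A pulse schedule lists the write pulses routed to individual devices:
#' one row per (pixel, device) target with the pulse count, amplitude and
#' width. Schedules are what protocol front-ends (touchpad, LMS) emit and
#' what [apply_schedule()] consumes.
#'
#' @param pixel Integer pixel keys (1-based).
#' @param device `"plus"` or `"minus"` per entry.
#' @param pulses Pulse counts (>= 1).
#' @param amplitude_v Pulse amplitudes in V.
#' @param width_s Pulse widths in s.
#' @param saturated Logical flag: TRUE when a demanded update exceeded the
#'   per-step pulse cap and was clipped.
#' @return A data.frame of class `pulse_schedule`.
#' @export
pulse_schedule <- function(pixel = integer(), device = character(),
                           pulses = integer(), amplitude_v = numeric(),
                           width_s = numeric(), saturated = FALSE) {
  if (length(pixel) && !all(device %in% c("plus", "minus"))) {
    stop("device must be 'plus' or 'minus'", call. = FALSE)
  }
  if (length(pixel) && any(pulses < 1)) stop("pulse counts must be >= 1", call. = FALSE)
  sched <- data.frame(
    pixel = as.integer(pixel),
    device = as.character(device),
    pulses = as.integer(pulses),
    amplitude_v = as.numeric(amplitude_v),
    width_s = as.numeric(width_s),
    stringsAsFactors = FALSE
  )
  class(sched) <- c("pulse_schedule", class(sched))
  attr(sched, "saturated") <- isTRUE(saturated)
  sched
}

#' Apply a pulse schedule to an array
#'
#' @param array A `synapse_array`.
#' @param sched A `pulse_schedule`.
#' @return The updated `synapse_array`.
#' @export
apply_schedule <- function(array, sched) {
  stopifnot(inherits(array, "synapse_array"), inherits(sched, "pulse_schedule"))
  for (r in seq_len(nrow(sched))) {
    k <- sched$pixel[r]
    if (k < 1L || k > array$n_pixels) stop("schedule pixel out of range", call. = FALSE)
    dev <- sched$device[r]
    array$pixels[[k]][[dev]] <- write_pulse(
      array$pixels[[k]][[dev]], array$params,
      v = sched$amplitude_v[r], n = sched$pulses[r]
    )
  }
  array
}

#' One hardware training iteration (paired one-shot writes)
#'
#' One iteration writes the positive-class pattern in the positive mode and
#' the negative-class pattern in the negative mode, both with background
#' writes, `pulses` write pulses each — the fixed-increment hardware
#' realization of a Widrow-Hoff step. On a fresh ideal array a single
#' iteration already separates the trained pair.
#'
#' @param array A `synapse_array`.
#' @param p_pos Pattern to classify positive.
#' @param p_neg Pattern to classify negative.
#' @param pulses Write pulses per targeted device (>= 1).
#' @return The updated `synapse_array`.
#' @export
one_shot_iteration <- function(array, p_pos, p_neg, pulses = 1L) {
  array <- write_pattern(array, p_pos, "positive", pulses = pulses,
                         background = TRUE)
  write_pattern(array, p_neg, "negative", pulses = pulses, background = TRUE)
}

#' Convert touchpad presses into a pulse schedule
#'
#' Each pressed key emits a train of fixed-width voltage spikes for as long
#' as it is held: the pulse count is `ceiling(duration / period)`. The pulse
#' amplitude is the source voltage divided down by a resistive divider.
#' Only pressed keys appear in the schedule (no background writes); tracing
#' a letter for the positive class routes to the EOECT+ devices, for the
#' negative class to EOECT-.
#'
#' @param strokes Named numeric vector: names are pixel keys (1-16), values
#'   press durations in s (> 0). May be empty.
#' @param device Target device for every pressed key: `"plus"` or
#'   `"minus"`.
#' @param period Spike period in s.
#' @param duty Spike width in s.
#' @param v_source Source voltage in V.
#' @param r_series,r_shunt Divider resistances in ohm; the delivered
#'   amplitude is `v_source * r_shunt / (r_series + r_shunt)`.
#' @return A `pulse_schedule`.
#' @examples
#' touchpad_session(c(`1` = 1.35, `6` = 0.05))
#' @export
touchpad_session <- function(strokes, device = c("plus", "minus"),
                             period = 0.2, duty = 0.1,
                             v_source = 5, r_series = 82e3, r_shunt = 10e3) {
  device <- match.arg(device)
  if (length(strokes) == 0L) return(pulse_schedule())
  keys <- as.integer(names(strokes))
  if (anyNA(keys) || any(keys < 1L | keys > 16L)) {
    stop("stroke names must be pixel keys in 1..16", call. = FALSE)
  }
  dur <- as.numeric(strokes)
  if (any(dur <= 0)) stop("press durations must be > 0", call. = FALSE)
  amplitude <- v_source * r_shunt / (r_series + r_shunt)
  pulse_schedule(
    pixel = keys,
    device = rep(device, length(keys)),
    pulses = ceiling(dur / period),
    amplitude_v = rep(amplitude, length(keys)),
    width_s = rep(duty, length(keys))
  )
}

#' LMS trainer configuration
#'
#' @param eta Learning rate in uS per uA of output error: maps the error to
#'   a desired total weight change.
#' @param max_pulses_per_step Cap on the write pulses any one device may
#'   receive in a single step (>= 1).
#' @param target_uA Magnitude in uA of the desired output for a +/-1 class
#'   target.
#' @return An object of class `lms_config`.
#' @export
lms_config <- function(eta = 20, max_pulses_per_step = 5L, target_uA = 1) {
  if (eta <= 0) stop("eta must be > 0", call. = FALSE)
  if (max_pulses_per_step < 1) stop("max_pulses_per_step must be >= 1", call. = FALSE)
  if (target_uA <= 0) stop("target_uA must be > 0", call. = FALSE)
  structure(list(eta = eta, max_pulses_per_step = as.integer(max_pulses_per_step),
                 target_uA = target_uA),
            class = "lms_config")
}

# Best integer pulse count (0..cap) approximating a demanded conductance
# increase under the growth law, ties broken toward fewer pulses (less
# irreversible material).
.quantize_pulses <- function(state, params, demand, cap) {
  n0 <- state$n_pulses
  gains <- conductance_at(params, n0 + 0:cap, state$dev_factor) -
    conductance_at(params, n0, state$dev_factor)
  err <- abs(gains - demand)
  k <- which(err == min(err))[1] - 1L  # which() returns the first = fewest
  list(k = k, saturated = (k == cap && gains[cap + 1L] < demand))
}

#' One quantized LMS (Widrow-Hoff) training step
#'
#' Computes the output error `e = target_current - read(p)` and the desired
#' per-pixel weight change `dw_i = eta * e * x_i / n_pixels`, then realizes
#' it under the two-wire increase-only rule: a positive `dw` is approximated
#' by write pulses on EOECT+, a negative one by pulses on EOECT-, choosing
#' the integer pulse count (up to the cap) whose predicted conductance gain
#' under the growth law best matches `|dw|`. Conductances never decrease; a
#' demand beyond the cap is clipped and flagged as saturated.
#'
#' Because single-pulse conductance increments grow with the accumulated
#' pulse count under the calibrated power law, small demands can all fall
#' inside the quantizer's dead zone (nearest count 0) even while the
#' pattern is still misclassified, which would stall training permanently.
#' In that case the step escapes the stall minimally: one pulse is written
#' to the targeted device with the smallest realizable increment, which by
#' the two-wire sign rule always moves the output toward the target.
#'
#' @param array A `synapse_array`.
#' @param p An `eoect_pattern`.
#' @param target Class target, +1 or -1.
#' @param cfg An `lms_config`.
#' @return A list with elements `array` (updated) and `schedule` (the
#'   `pulse_schedule` that was applied).
#' @export
lms_step_quantized <- function(array, p, target, cfg = lms_config()) {
  stopifnot(inherits(array, "synapse_array"), inherits(cfg, "lms_config"))
  if (!(target %in% c(-1, 1))) stop("target must be +1 or -1", call. = FALSE)
  px <- if (inherits(p, "eoect_pattern")) p$pixels else as.integer(p)
  e <- target * cfg$target_uA - read_pattern(array, p)
  if (e == 0) return(list(array = array, schedule = pulse_schedule()))
  dw <- cfg$eta * e * px / array$n_pixels
  pixel <- integer(); device <- character(); pulses <- integer()
  saturated <- FALSE
  for (k in seq_along(dw)) {
    if (dw[k] == 0) next
    dev <- if (dw[k] > 0) "plus" else "minus"
    q <- .quantize_pulses(array$pixels[[k]][[dev]], array$params,
                          abs(dw[k]), cfg$max_pulses_per_step)
    saturated <- saturated || q$saturated
    if (q$k > 0L) {
      pixel <- c(pixel, k); device <- c(device, dev); pulses <- c(pulses, q$k)
    }
  }
  misclassified <- classify(target * cfg$target_uA - e) !=
    ifelse(target > 0, "positive", "negative")
  if (length(pixel) == 0L && misclassified) {
    # dead-zone stall escape: smallest single-pulse increment among the
    # pixels with a nonzero demand
    cand <- which(dw != 0)
    gains <- vapply(cand, function(k) {
      dev <- if (dw[k] > 0) "plus" else "minus"
      st <- array$pixels[[k]][[dev]]
      conductance_at(array$params, st$n_pulses + 1L, st$dev_factor) - st$g
    }, numeric(1))
    k <- cand[which.min(gains)]
    pixel <- k
    device <- if (dw[k] > 0) "plus" else "minus"
    pulses <- 1L
  }
  sched <- pulse_schedule(
    pixel = pixel, device = device, pulses = pulses,
    amplitude_v = rep(array$params$v_poly, length(pixel)),
    width_s = rep(array$params$pulse_width, length(pixel)),
    saturated = saturated
  )
  list(array = apply_schedule(array, sched), schedule = sched)
}

#' Run the quantized LMS trainer over epochs
#'
#' Sweeps the training set once per epoch in order, applying
#' [lms_step_quantized()] per pattern, and stops early once every pattern is
#' classified with the correct sign.
#'
#' @param array A `synapse_array`.
#' @param patterns List of `eoect_pattern`s.
#' @param targets Numeric vector of +/-1 class targets, one per pattern.
#' @param cfg An `lms_config`.
#' @param epochs Maximum epochs.
#' @return A list with `array`, `epochs_run`, `converged`, and `history`
#'   (data.frame of per-epoch misclassification counts).
#' @export
lms_train <- function(array, patterns, targets, cfg = lms_config(),
                      epochs = 10L) {
  stopifnot(length(patterns) == length(targets), all(targets %in% c(-1, 1)))
  n_wrong <- function(arr) {
    sum(vapply(seq_along(patterns), function(i) {
      cls <- classify(read_pattern(arr, patterns[[i]]))
      cls != ifelse(targets[i] > 0, "positive", "negative")
    }, logical(1)))
  }
  history <- data.frame(epoch = integer(), misclassified = integer())
  ep <- 0L
  while (ep < epochs) {
    if (n_wrong(array) == 0L) break
    ep <- ep + 1L
    for (i in seq_along(patterns)) {
      array <- lms_step_quantized(array, patterns[[i]], targets[i], cfg)$array
    }
    history <- rbind(history,
                     data.frame(epoch = ep, misclassified = n_wrong(array)))
  }
  list(array = array, epochs_run = ep, converged = n_wrong(array) == 0L,
       history = history)
}
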