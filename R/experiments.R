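# Fixture pattern library (the six T/J placements) and end-to-end protocol
# runners: the three-phase training experiment and the classifier-to-neuron
# biointerface sequence, both with structured, replayable logging.

#' The six-letter fixture library
#'
#' The 4x4 letter fixtures used throughout: T and J drawn on the left
#' columns (positive keys {1,2,3,6,10,14} and {3,7,9,11,13,14,15}
#' respectively, full height, width 3), their one-column right
#' translations, and their 90-degree clockwise rotations — six objects in
#' all, to be classified T (positive) versus J (negative).
#'
#' @return Named list of six `eoect_pattern`s: `T_left`, `J_left`,
#'   `T_right`, `J_right`, `T_rot`, `J_rot`.
#' @examples
#' lib <- pattern_library()
#' print(lib$T_left)
#' pattern_dot(lib$T_left, lib$J_left)  # -2
#' @export
pattern_library <- function() {
  t_left <- pattern_from_keys(c(1, 2, 3, 6, 10, 14), name = "T_left")
  j_left <- pattern_from_keys(c(3, 7, 9, 11, 13, 14, 15), name = "J_left")
  list(
    T_left = t_left,
    J_left = j_left,
    T_right = pattern_shift_right(t_left, name = "T_right"),
    J_right = pattern_shift_right(j_left, name = "J_right"),
    T_rot = pattern_rotate_cw(t_left, name = "T_rot"),
    J_rot = pattern_rotate_cw(j_left, name = "J_rot")
  )
}

.new_log <- function(records, seed, config) {
  structure(records, class = c("experiment_log", class(records)),
            seed = seed, config = config)
}

#' @export
print.experiment_log <- function(x, ...) {
  cat(sprintf("Experiment log: %d records (seed %s)\n", nrow(x),
              if (is.null(attr(x, "seed"))) "none" else attr(x, "seed")))
  NextMethod()
}

# Mean/sd over n successive reads of one pattern (noise, if configured,
# enters through read_pattern).
.characterize <- function(array, p, n_reads) {
  i <- vapply(seq_len(n_reads), function(k) read_pattern(array, p), numeric(1))
  list(mean = mean(i), sd = stats::sd(i))
}

#' Run the three-phase training experiment
#'
#' Initializes the array with random weights, characterizes all six
#' fixtures (phase 0), then applies three one-shot training iterations —
#' on the left pair, the right pair, and the rotated pair in turn — with a
#' full characterization after each (phases 1-3). Each characterization
#' reads every fixture `n_reads` times and logs the mean, standard
#' deviation and class of the reads.
#'
#' @param seed Integer seed for the random initialization (and read noise,
#'   if enabled).
#' @param pulses Write pulses per device per training pass (>= 1).
#' @param params Shared `eoect_params`.
#' @param pulse_range Initialization pulse-count range (see
#'   [init_random()]).
#' @param n_reads Successive reads per characterization point.
#' @param noise_rel Relative read noise for characterization (0 disables).
#' @return An `experiment_log` data.frame with columns `phase`, `op`,
#'   `pattern`, `mean_uA`, `sd_uA`, `class`, `n_reads`; the trained array
#'   is attached as attribute `"array"`.
#' @export
run_three_phase <- function(seed = NULL, pulses = 1L,
                            params = device_params(),
                            pulse_range = c(2L, 5L),
                            n_reads = 4L, noise_rel = 0) {
  if (pulses < 1) stop("pulses must be >= 1", call. = FALSE)
  lib <- pattern_library()
  pairs <- list(c("T_left", "J_left"), c("T_right", "J_right"),
                c("T_rot", "J_rot"))
  cfg <- read_config(noise_rel = noise_rel)
  array <- init_random(params, pulse_range, seed = seed, cfg = cfg)
  rows <- list()
  log_phase <- function(phase) {
    for (nm in names(lib)) {
      ch <- .characterize(array, lib[[nm]], n_reads)
      rows[[length(rows) + 1L]] <<- data.frame(
        phase = phase, op = "read", pattern = nm,
        mean_uA = ch$mean, sd_uA = ch$sd, class = classify(ch$mean),
        n_reads = n_reads, stringsAsFactors = FALSE
      )
    }
  }
  log_phase(0L)
  for (it in seq_along(pairs)) {
    pr <- pairs[[it]]
    array <- one_shot_iteration(array, lib[[pr[1]]], lib[[pr[2]]],
                                pulses = pulses)
    rows[[length(rows) + 1L]] <- data.frame(
      phase = it, op = "train", pattern = paste(pr, collapse = "/"),
      mean_uA = NA_real_, sd_uA = NA_real_, class = NA_character_,
      n_reads = 0L, stringsAsFactors = FALSE
    )
    log_phase(it)
  }
  log <- .new_log(do.call(rbind, rows), seed,
                  list(pulses = pulses, pulse_range = pulse_range,
                       n_reads = n_reads, noise_rel = noise_rel,
                       params = unclass(params)))
  attr(log, "array") <- array
  log
}

#' Run the classifier-to-neuron biointerface sequence
#'
#' Presents the positive- and negative-class letters to a pre-trained
#' array `n_each` times each (alternating by default) for `on_s` seconds
#' at `period_s` intervals. Each presentation reads the classifier,
#' bridges the current into the neuron, simulates the spike train over the
#' on-window, and evaluates the contraction proxy. The array must already
#' classify the positive letter positive and the negative letter negative.
#'
#' @param array A trained `synapse_array`.
#' @param p_pos,p_neg The trained positive/negative patterns (defaults:
#'   `T_left` and `J_left` from [pattern_library()]).
#' @param n_each Presentations per letter (>= 1).
#' @param on_s Input-on duration per presentation in s.
#' @param period_s Interval between presentation onsets in s (> `on_s`).
#' @param order `"alternating"` (T J T J ...) or `"blocked"` (all T then
#'   all J).
#' @param neuron A `neuron_params`.
#' @param bridge A `bridge_params`; `NULL` sizes the gain so the trained
#'   positive letter drives the neuron at the top of its range.
#' @param k Contraction-proxy scale (response units per spike).
#' @param seed Optional integer seed (only relevant with read noise).
#' @return An `experiment_log` data.frame, one row per presentation, with
#'   columns `idx`, `t_start_s`, `pattern`, `i_classifier_uA`, `class`,
#'   `i_inj_uA`, `f_Hz`, `n_spikes`, `contraction_peak`; the bridge gain is
#'   attached as attribute `"gain"`.
#' @export
run_biointerface <- function(array, p_pos = NULL, p_neg = NULL,
                             n_each = 5L, on_s = 2, period_s = 20,
                             order = c("alternating", "blocked"),
                             neuron = neuron_params(), bridge = NULL,
                             k = 1, seed = NULL) {
  stopifnot(inherits(array, "synapse_array"))
  order <- match.arg(order)
  if (n_each < 1) stop("n_each must be >= 1", call. = FALSE)
  if (on_s <= 0 || on_s >= period_s) {
    stop("need 0 < on_s < period_s", call. = FALSE)
  }
  lib <- pattern_library()
  if (is.null(p_pos)) p_pos <- lib$T_left
  if (is.null(p_neg)) p_neg <- lib$J_left
  if (!is.null(seed)) set.seed(seed)
  if (classify(read_pattern(array, p_pos)) != "positive" ||
      classify(read_pattern(array, p_neg)) != "negative") {
    stop("array is not trained on this pattern pair: train it (e.g. with ",
         "one_shot_iteration) before running the biointerface", call. = FALSE)
  }
  if (is.null(bridge)) bridge <- default_bridge_gain(array, p_pos, neuron)
  seq_pat <- if (order == "alternating") {
    rep(c("pos", "neg"), n_each)
  } else {
    c(rep("pos", n_each), rep("neg", n_each))
  }
  rows <- vector("list", length(seq_pat))
  for (j in seq_along(seq_pat)) {
    p <- if (seq_pat[j] == "pos") p_pos else p_neg
    i_cls <- read_pattern(array, p)
    i_inj <- bridge_current(i_cls, bridge)
    train <- simulate_spike_train(i_inj, on_s, neuron)
    prox <- contraction_proxy(train, window = on_s, k = k)
    rows[[j]] <- data.frame(
      idx = j, t_start_s = (j - 1) * period_s,
      pattern = if (is.null(p$name)) seq_pat[j] else p$name,
      i_classifier_uA = i_cls, class = classify(i_cls),
      i_inj_uA = i_inj, f_Hz = spike_frequency(i_inj, neuron),
      n_spikes = spike_count(train),
      contraction_peak = max(prox$response),
      stringsAsFactors = FALSE
    )
  }
  log <- .new_log(do.call(rbind, rows), seed,
                  list(n_each = n_each, on_s = on_s, period_s = period_s,
                       order = order, gain = bridge$gain, k = k,
                       neuron = unclass(neuron)))
  attr(log, "gain") <- bridge$gain
  log
}
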