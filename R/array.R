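# The two-wire synapse array: each pixel holds a pair of increase-only
# EOECT channels (EOECT+ / EOECT-), and the signed weight is their
# conductance difference w = G1 - G2. Reading applies +V to one device and
# -alpha*V to the other (swapped for a -1 input); all pixel currents sum at
# a shared output, and the sign of the total classifies the pattern against
# the natural zero boundary.

#' Read configuration for the synapse array
#'
#' @param v Read-voltage magnitude in V (sub-threshold).
#' @param alpha Scaling constant applied to the negative read input so that
#'   reading a pattern and its inverse produce currents of equal magnitude.
#' @param epsilon Read-polarity conductance asymmetry: under a negative
#'   applied voltage a device conducts with factor `1 - epsilon`. 0 models
#'   an ideal symmetric channel.
#' @param noise_rel Relative (multiplicative Gaussian) read noise applied to
#'   whole-pattern reads; 0 disables it.
#' @return An object of class `read_config`.
#' @export
read_config <- function(v = 0.05, alpha = 1, epsilon = 0, noise_rel = 0) {
  if (!is.numeric(v) || v <= 0) stop("read voltage must be > 0", call. = FALSE)
  if (alpha <= 0) stop("alpha must be > 0", call. = FALSE)
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)", call. = FALSE)
  if (noise_rel < 0) stop("noise_rel must be >= 0", call. = FALSE)
  structure(list(v = v, alpha = alpha, epsilon = epsilon, noise_rel = noise_rel),
            class = "read_config")
}

#' Create a fresh synapse array
#'
#' All channels start unformed (zero conductance, ideal device factors).
#'
#' @param params Shared `eoect_params` for every channel (one gate, one
#'   output).
#' @param cfg A `read_config`.
#' @param n_pixels Number of pixels (16 for the 4x4 classifier).
#' @return An object of class `synapse_array`.
#' @export
synapse_array <- function(params = device_params(), cfg = read_config(),
                          n_pixels = 16L) {
  stopifnot(inherits(params, "eoect_params"), inherits(cfg, "read_config"))
  if (cfg$v >= params$v_poly) {
    stop("read voltage must stay below the polymerization threshold", call. = FALSE)
  }
  pixels <- lapply(seq_len(n_pixels), function(i) {
    list(plus = new_eoect(), minus = new_eoect())
  })
  structure(list(pixels = pixels, params = params, cfg = cfg,
                 n_pixels = as.integer(n_pixels)),
            class = "synapse_array")
}

#' Initialize an array with random weights
#'
#' Each of the `2 * n_pixels` channels receives an independently drawn
#' uniform integer number of write pulses and its own variability factor,
#' producing sign-mixed pixel weights `w = G+ - G-`.
#'
#' @param params Shared `eoect_params`.
#' @param pulse_range Integer pair `(low, high)`, `low >= 2` (a one-pulse
#'   channel has not percolated, so a random weight below 2 pulses is
#'   degenerate).
#' @param seed Optional integer seed; recorded in the result's `"seed"`
#'   attribute.
#' @param cfg A `read_config`.
#' @param n_pixels Number of pixels.
#' @return A `synapse_array`.
#' @export
init_random <- function(params = device_params(), pulse_range = c(2L, 5L),
                        seed = NULL, cfg = read_config(), n_pixels = 16L) {
  pulse_range <- as.integer(pulse_range)
  if (length(pulse_range) != 2L || anyNA(pulse_range)) {
    stop("pulse_range must be an integer pair", call. = FALSE)
  }
  if (pulse_range[1] < 2L) {
    stop("pulse_range low must be >= 2: a one-pulse device has no channel",
         call. = FALSE)
  }
  if (pulse_range[2] < pulse_range[1]) {
    stop("pulse_range must be non-decreasing", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  arr <- synapse_array(params, cfg, n_pixels)
  fac <- draw_dev_factors(2L * arr$n_pixels, params$cv_device)
  counts <- pulse_range[1] +
    sample.int(pulse_range[2] - pulse_range[1] + 1L,
               2L * arr$n_pixels, replace = TRUE) - 1L
  k <- 0L
  for (i in seq_len(arr$n_pixels)) {
    for (dev in c("plus", "minus")) {
      k <- k + 1L
      st <- new_eoect(dev_factor = fac[k])
      arr$pixels[[i]][[dev]] <- write_pulse(st, params, params$v_poly, counts[k])
    }
  }
  attr(arr, "seed") <- seed
  arr
}

#' Pixel conductances of an array
#' @param array A `synapse_array`.
#' @return Numeric matrix `n_pixels x 2` with columns `plus`, `minus` (uS).
#' @export
array_conductances <- function(array) {
  stopifnot(inherits(array, "synapse_array"))
  m <- t(vapply(array$pixels,
                function(px) c(px$plus$g, px$minus$g), numeric(2)))
  colnames(m) <- c("plus", "minus")
  m
}

#' Signed pixel weights (G+ - G-) of an array
#' @param array A `synapse_array`.
#' @return Numeric vector of weights in uS.
#' @export
array_weights <- function(array) {
  g <- array_conductances(array)
  g[, "plus"] - g[, "minus"]
}

#' @export
print.synapse_array <- function(x, ...) {
  w <- array_weights(x)
  cat(sprintf("Synapse array: %d pixels (2 EOECTs each), growth law '%s'\n",
              x$n_pixels, x$params$growth_law))
  cat(sprintf("  weights (uS): min %.3g, median %.3g, max %.3g\n",
              min(w), stats::median(w), max(w)))
  invisible(x)
}

#' Read the current contributed by one pixel
#'
#' For a +1 input, `+v` is applied to EOECT+ and `-alpha*v` to EOECT-; for a
#' -1 input the two voltages are swapped. A device under negative applied
#' voltage conducts with factor `1 - epsilon`. With `epsilon = 0` and
#' `alpha = 1` the pixel current is exactly `x * v * (G1 - G2)`.
#'
#' @param pixel A list with `plus` and `minus` `eoect_state`s.
#' @param x Input value, +1 or -1.
#' @param cfg A `read_config`.
#' @return Current in uA.
#' @export
read_pixel <- function(pixel, x, cfg = read_config()) {
  if (!is.numeric(x) || length(x) != 1L || !(x %in% c(-1, 1))) {
    stop("pixel input must be +1 or -1", call. = FALSE)
  }
  v <- cfg$v
  neg <- cfg$alpha * v * (1 - cfg$epsilon)
  if (x > 0) {
    v * pixel$plus$g - neg * pixel$minus$g
  } else {
    -neg * pixel$plus$g + v * pixel$minus$g
  }
}

#' Read the summed output current for a pattern
#'
#' All pixel outputs are wired together, so the array output is the sum of
#' the per-pixel currents. Reading is non-destructive and, when
#' `noise_rel > 0`, subject to multiplicative Gaussian read noise.
#'
#' @param array A `synapse_array`.
#' @param p An `eoect_pattern` (or a bare vector of +1/-1 of matching
#'   length).
#' @return Current in uA.
#' @export
read_pattern <- function(array, p) {
  stopifnot(inherits(array, "synapse_array"))
  px <- if (inherits(p, "eoect_pattern")) p$pixels else as.integer(p)
  if (length(px) != array$n_pixels || !all(px %in% c(-1L, 1L))) {
    stop("pattern does not match the array (need ", array$n_pixels,
         " values of +1/-1)", call. = FALSE)
  }
  i <- sum(vapply(seq_along(px), function(k) {
    read_pixel(array$pixels[[k]], px[k], array$cfg)
  }, numeric(1)))
  if (array$cfg$noise_rel > 0) {
    i <- i * (1 + stats::rnorm(1, 0, array$cfg$noise_rel))
  }
  i
}

#' Classify an output current against the zero boundary
#'
#' @param current Output current in uA.
#' @param tol Dead-band half-width in uA (>= 0): currents within
#'   `[-tol, tol]` are `"indeterminate"` rather than silently assigned.
#' @return One of `"positive"`, `"negative"`, `"indeterminate"`.
#' @export
classify <- function(current, tol = 0) {
  if (tol < 0) stop("tol must be >= 0", call. = FALSE)
  if (current > tol) "positive" else if (current < -tol) "negative" else "indeterminate"
}

#' Write a pattern into the array
#'
#' In the positive writing mode every +1 pixel's EOECT+ is pulsed and, if
#' `background` is set, every -1 pixel's EOECT-; the negative mode swaps
#' the targets. `background = FALSE` reproduces traced-keys-only writing
#' (as when letters are drawn on a touchpad), where untouched pixels are
#' left alone.
#'
#' @param array A `synapse_array`.
#' @param p An `eoect_pattern`.
#' @param polarity `"positive"` or `"negative"`.
#' @param pulses Write pulses per targeted device (>= 1).
#' @param background Also write the opposite device of the off-pattern
#'   pixels (default TRUE).
#' @param v Pulse amplitude in V (defaults to the polymerization threshold).
#' @return The updated `synapse_array`.
#' @export
write_pattern <- function(array, p, polarity = c("positive", "negative"),
                          pulses = 1L, background = TRUE,
                          v = array$params$v_poly) {
  stopifnot(inherits(array, "synapse_array"))
  polarity <- match.arg(polarity)
  if (!is.numeric(pulses) || length(pulses) != 1L || pulses < 1) {
    stop("pulses must be >= 1", call. = FALSE)
  }
  px <- if (inherits(p, "eoect_pattern")) p$pixels else as.integer(p)
  if (length(px) != array$n_pixels || !all(px %in% c(-1L, 1L))) {
    stop("pattern does not match the array", call. = FALSE)
  }
  for (k in seq_along(px)) {
    target <- if (px[k] == 1L) {
      if (polarity == "positive") "plus" else "minus"
    } else if (background) {
      if (polarity == "positive") "minus" else "plus"
    } else {
      NA_character_
    }
    if (!is.na(target)) {
      array$pixels[[k]][[target]] <-
        write_pulse(array$pixels[[k]][[target]], array$params, v, pulses)
    }
  }
  array
}

#' Calibrate the negative-input scaling constant
#'
#' Finds `alpha` such that reading a probe pattern and its inverse produce
#' output currents of equal magnitude (opposite sign), compensating the
#' read-polarity asymmetry `epsilon`. With `epsilon = 0` the array is
#' symmetric and the calibration returns 1.
#'
#' @param array A `synapse_array` with at least one formed channel.
#' @param probe Probe `eoect_pattern` (default: all +1).
#' @return The calibrated `alpha`.
#' @export
calibrate_negative_scale <- function(array, probe = NULL) {
  stopifnot(inherits(array, "synapse_array"))
  if (sum(array_conductances(array)) == 0) {
    stop("calibration undefined: every channel in the array is unformed",
         call. = FALSE)
  }
  if (is.null(probe)) probe <- pattern(rep(1L, array$n_pixels))
  imbalance <- function(alpha) {
    arr <- array
    arr$cfg$alpha <- alpha
    arr$cfg$noise_rel <- 0
    read_pattern(arr, probe) + read_pattern(arr, pattern_negate(probe))
  }
  stats::uniroot(imbalance, interval = c(1e-6, 1e3), tol = 1e-12)$root
}
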