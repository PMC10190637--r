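# Single-EOECT phenomenological model: pulse-driven conductance growth,
# sub-threshold (non-destructive) reads, gate modulation, device-to-device
# variability, and dry-state retention drift.
#
# Units used throughout the package: conductance in uS, current in uA,
# voltage in V, pulse widths in s, storage age in h.

# -- growth-law registry ------------------------------------------------------

# Built-in laws map a pulse count n to a conductance in uS given the params.
# "power" is the calibrated physical model: no percolated channel before the
# second pulse, then G(n) = g_first * (n - 1)^gamma. "linear" is an idealized
# equal-increment reference law G(n) = g_step * n (no percolation threshold),
# useful for closed-form reasoning about training algebra.
.builtin_growth_laws <- list(
  power = function(n, params) {
    ifelse(n < 2, 0, params$g_first * (pmax(n, 2) - 1)^params$gamma)
  },
  linear = function(n, params) params$g_step * n
)

.growth_law_registry <- new.env(parent = emptyenv())

#' Register a custom conductance growth law
#'
#' A growth law maps a cumulative write-pulse count to a channel conductance
#' in microsiemens. The built-in laws are `"power"` (the default calibrated
#' electropolymerization model) and `"linear"` (an idealized equal-increment
#' law). Registered laws are selected by setting `growth_law` in
#' [device_params()].
#'
#' @param name Character name of the law.
#' @param fn Function `(n, params)` returning conductance in uS; must be
#'   vectorized over `n` and non-decreasing in `n`.
#' @return The name, invisibly.
#' @export
register_growth_law <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name), is.function(fn))
  assign(name, fn, envir = .growth_law_registry)
  invisible(name)
}

#' List available growth-law names
#' @return Character vector of law names.
#' @export
growth_laws <- function() {
  sort(unique(c(names(.builtin_growth_laws), ls(.growth_law_registry))))
}

.get_growth_law <- function(name) {
  if (exists(name, envir = .growth_law_registry, inherits = FALSE)) {
    return(get(name, envir = .growth_law_registry, inherits = FALSE))
  }
  fn <- .builtin_growth_laws[[name]]
  if (is.null(fn)) {
    stop("unknown growth law '", name, "'; see growth_laws()", call. = FALSE)
  }
  fn
}

#' Conductance predicted by the growth law at a given pulse count
#'
#' @param params An `eoect_params` object from [device_params()].
#' @param n Cumulative write-pulse count (vectorized).
#' @param dev_factor Per-device multiplicative variability factor.
#' @return Conductance in uS.
#' @export
conductance_at <- function(params, n, dev_factor = 1) {
  fn <- .get_growth_law(params$growth_law)
  dev_factor * fn(n, params)
}

# -- parameters ---------------------------------------------------------------

#' Device parameters for an evolvable OECT channel
#'
#' Collects the phenomenological constants of a single electropolymerized
#' channel. Defaults reproduce the characterization anchors of the device
#' this model emulates: a channel first percolates on the second 0.5 V /
#' 1 s write pulse at 0.4 uS and reaches 145 uS after 20 pulses; a negative
#' gate bias of -0.5 V raises the drain current 12-fold while +0.5 V
#' suppresses it 3500-fold; the dry-state resistance changes by 1% in 9.5 h;
#' and device-to-device variability is a 7% coefficient of variation.
#'
#' @param g_first Conductance in uS reached after the 2nd write pulse.
#' @param g_at_20 Conductance in uS after 20 pulses (second calibration
#'   anchor for the default power law).
#' @param gamma Growth exponent. `NULL` (default) calibrates it from the two
#'   anchors so that `G(20) = g_at_20` exactly.
#' @param v_poly Electropolymerization threshold voltage in V; writes occur
#'   at or above it, reads must stay strictly below.
#' @param v_read Default read voltage in V.
#' @param pulse_width Write-pulse duration in s.
#' @param cv_device Device-to-device multiplicative variability expressed as
#'   a coefficient of variation (lognormal, unit mean).
#' @param drift_rate Dry-state fractional resistance increase per hour.
#' @param on_factor,off_factor Drain-current enhancement at `vg_on` and
#'   suppression at `vg_off`, relative to 0 V gate.
#' @param vg_on,vg_off Reference gate voltages in V for the two factors.
#' @param kappa_on,kappa_off Gate-modulation exponents in 1/V. `NULL`
#'   (default) calibrates them from the factors and reference voltages.
#' @param growth_law Name of the conductance growth law (see
#'   [growth_laws()]).
#' @param g_step Per-pulse conductance increment in uS for the `"linear"`
#'   idealized law.
#' @return An object of class `eoect_params`.
#' @examples
#' p <- device_params()
#' conductance_at(p, c(1, 2, 20))
#' @export
device_params <- function(g_first = 0.4,
                          g_at_20 = 145,
                          gamma = NULL,
                          v_poly = 0.5,
                          v_read = 0.05,
                          pulse_width = 1,
                          cv_device = 0.07,
                          drift_rate = 0.01 / 9.5,
                          on_factor = 12,
                          off_factor = 3500,
                          vg_on = -0.5,
                          vg_off = 0.5,
                          kappa_on = NULL,
                          kappa_off = NULL,
                          growth_law = "power",
                          g_step = 1) {
  if (!is.numeric(g_first) || g_first <= 0) {
    stop("g_first must be a positive conductance (uS)", call. = FALSE)
  }
  if (is.null(gamma)) {
    if (!is.numeric(g_at_20) || g_at_20 <= g_first) {
      stop("g_at_20 must exceed g_first to calibrate the growth exponent",
           call. = FALSE)
    }
    gamma <- log(g_at_20 / g_first) / log(19)
  }
  if (gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  if (cv_device < 0 || cv_device >= 1) {
    stop("cv_device must be in [0, 1)", call. = FALSE)
  }
  if (drift_rate < 0) stop("drift_rate must be >= 0", call. = FALSE)
  if (v_read >= v_poly) {
    stop("v_read must be below v_poly: reads are sub-threshold", call. = FALSE)
  }
  if (vg_on >= 0 || vg_off <= 0) {
    stop("vg_on must be negative and vg_off positive", call. = FALSE)
  }
  if (on_factor < 1 || off_factor < 1) {
    stop("on_factor and off_factor must be >= 1", call. = FALSE)
  }
  if (is.null(kappa_on)) kappa_on <- log(on_factor) / (-vg_on)
  if (is.null(kappa_off)) kappa_off <- log(off_factor) / vg_off
  if (g_step <= 0) stop("g_step must be > 0", call. = FALSE)
  structure(
    list(
      g_first = g_first, g_at_20 = g_at_20, gamma = gamma,
      v_poly = v_poly, v_read = v_read, pulse_width = pulse_width,
      cv_device = cv_device, drift_rate = drift_rate,
      on_factor = on_factor, off_factor = off_factor,
      vg_on = vg_on, vg_off = vg_off,
      kappa_on = kappa_on, kappa_off = kappa_off,
      growth_law = growth_law, g_step = g_step
    ),
    class = "eoect_params"
  )
}

#' @export
print.eoect_params <- function(x, ...) {
  cat("EOECT device parameters\n")
  cat(sprintf("  growth law : %s (g_first = %g uS, gamma = %.4f)\n",
              x$growth_law, x$g_first, x$gamma))
  cat(sprintf("  write      : v_poly = %g V, pulse_width = %g s\n",
              x$v_poly, x$pulse_width))
  cat(sprintf("  read       : v_read = %g V\n", x$v_read))
  cat(sprintf("  gate       : x%g at %g V, /%g at %g V\n",
              x$on_factor, x$vg_on, x$off_factor, x$vg_off))
  cat(sprintf("  variability: CV = %g; drift = %.4g /h\n",
              x$cv_device, x$drift_rate))
  invisible(x)
}

#' Calibrate the growth law from two conductance anchors
#'
#' Solves the power growth law `G(n) = g_first * (n - 1)^gamma` so that it
#' passes exactly through the measured conductances after 2 and after 20
#' write pulses.
#'
#' @param g_at_2 Conductance in uS after 2 pulses.
#' @param g_at_20 Conductance in uS after 20 pulses.
#' @param ... Further arguments passed to [device_params()].
#' @return An `eoect_params` object with the calibrated `g_first` and `gamma`.
#' @examples
#' calibrate_growth(0.4, 145)$gamma
#' @export
calibrate_growth <- function(g_at_2, g_at_20, ...) {
  if (!is.numeric(g_at_2) || !is.numeric(g_at_20) ||
      g_at_2 <= 0 || g_at_20 <= 0) {
    stop("invalid calibration: anchor conductances must be positive",
         call. = FALSE)
  }
  if (g_at_20 <= g_at_2) {
    stop("invalid calibration: conductance must increase from 2 to 20 pulses",
         call. = FALSE)
  }
  device_params(g_first = g_at_2, g_at_20 = g_at_20, gamma = NULL, ...)
}

# -- device state -------------------------------------------------------------

#' Create a fresh (unformed) EOECT channel state
#'
#' @param dev_factor Fixed multiplicative variability factor of this device
#'   (drawn once at fabrication; 1 for an ideal device).
#' @return An object of class `eoect_state` with zero conductance, zero
#'   accumulated pulses and zero dry-storage age.
#' @export
new_eoect <- function(dev_factor = 1) {
  stopifnot(is.numeric(dev_factor), dev_factor > 0)
  structure(
    list(g = 0, n_pulses = 0L, age_h = 0, dev_factor = dev_factor, g_ref = 0),
    class = "eoect_state"
  )
}

#' @export
print.eoect_state <- function(x, ...) {
  cat(sprintf("EOECT state: g = %.4g uS after %d pulses (age %.2g h, dev x%.3f)\n",
              x$g, x$n_pulses, x$age_h, x$dev_factor))
  invisible(x)
}

#' Draw per-device multiplicative variability factors
#'
#' Factors are lognormal with unit mean and coefficient of variation
#' `cv`, modelling fabrication spread across an array; `cv = 0` returns
#' exactly 1 for every device.
#'
#' @param n Number of devices.
#' @param cv Coefficient of variation in [0, 1).
#' @return Numeric vector of length `n`.
#' @export
draw_dev_factors <- function(n, cv) {
  stopifnot(n >= 0, cv >= 0, cv < 1)
  if (cv == 0) return(rep(1, n))
  sigma <- sqrt(log1p(cv^2))
  exp(stats::rnorm(n, mean = -sigma^2 / 2, sd = sigma))
}

#' Apply write (electropolymerization) pulses to a channel
#'
#' Pulses at or above the polymerization threshold `v_poly` grow the channel:
#' the pulse counter advances by `n` and the conductance moves to the growth
#' law's value at the new count (scaled by the device factor), never
#' decreasing. Sub-threshold pulses are a no-op. Writing resets the
#' dry-storage age.
#'
#' @param state An `eoect_state`.
#' @param params An `eoect_params`.
#' @param v Pulse amplitude in V (non-negative).
#' @param n Number of pulses (integer >= 1).
#' @return The updated `eoect_state`.
#' @export
write_pulse <- function(state, params, v = params$v_poly, n = 1L) {
  stopifnot(inherits(state, "eoect_state"), inherits(params, "eoect_params"))
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 1) {
    stop("n must be a positive integer pulse count", call. = FALSE)
  }
  if (!is.numeric(v) || v < 0) stop("v must be >= 0", call. = FALSE)
  if (v < params$v_poly) return(state)  # sub-threshold: no polymerization
  state$n_pulses <- state$n_pulses + as.integer(n)
  g_new <- conductance_at(params, state$n_pulses, state$dev_factor)
  state$g <- max(state$g, g_new)
  state$g_ref <- state$g
  state$age_h <- 0
  state
}

#' Read the channel current at a sub-threshold voltage
#'
#' The channel is ohmic in the small-signal regime, so the read current is
#' simply `v * g`. The read is non-destructive: the state is not modified,
#' and voltages at or above the polymerization threshold are rejected
#' because they would write.
#'
#' @param state An `eoect_state`.
#' @param params An `eoect_params`.
#' @param v Read voltage in V, `|v| < v_poly`.
#' @return Current in uA.
#' @export
read_current <- function(state, params, v = params$v_read) {
  stopifnot(inherits(state, "eoect_state"), inherits(params, "eoect_params"))
  if (abs(v) >= params$v_poly) {
    stop("sub-threshold violation: |v| must stay below v_poly (a read must never write)",
         call. = FALSE)
  }
  v * state$g
}

#' Gate-modulation transfer ratio
#'
#' Multiplier applied to the drain current as a function of gate voltage,
#' relative to operation at 0 V gate. The channel is p-type in a hybrid
#' accumulation-depletion mode: negative gate bias enhances the current
#' (up to the calibrated on-factor) and positive bias suppresses it (down
#' to the reciprocal of the off-factor). Piecewise-exponential and
#' non-increasing in `vg`, with `m(0) = 1`.
#'
#' @param params An `eoect_params`.
#' @param vg Gate voltage in V (vectorized).
#' @return Dimensionless multiplier.
#' @examples
#' p <- device_params()
#' gate_transfer_ratio(p, c(-0.5, 0, 0.5))
#' @export
gate_transfer_ratio <- function(params, vg) {
  stopifnot(inherits(params, "eoect_params"), all(is.finite(vg)))
  ifelse(vg <= 0, exp(-params$kappa_on * vg), exp(-params$kappa_off * vg))
}

#' Apply dry-state retention drift
#'
#' In dry storage the channel resistance creeps upward linearly with time:
#' relative to the last write, `R(age) = R0 * (1 + drift_rate * age_h)`.
#' Successive calls accumulate additively through the stored age, so drift
#' over 19 h equals two 9.5 h intervals exactly. Zero hours is the identity.
#'
#' @param state An `eoect_state`.
#' @param params An `eoect_params`.
#' @param hours Elapsed dry-storage time in hours (>= 0).
#' @return The updated `eoect_state`.
#' @export
apply_drift <- function(state, params, hours) {
  stopifnot(inherits(state, "eoect_state"), inherits(params, "eoect_params"))
  if (!is.numeric(hours) || length(hours) != 1L || !is.finite(hours) || hours < 0) {
    stop("hours must be a non-negative duration", call. = FALSE)
  }
  state$age_h <- state$age_h + hours
  if (state$g_ref > 0) {
    state$g <- state$g_ref / (1 + params$drift_rate * state$age_h)
  }
  state
}

#' Simulate a population of independently fabricated devices
#'
#' Draws a variability factor for each device, grows each channel with the
#' same number of write pulses, and reads all of them at a common voltage.
#' Used to study array-level device-to-device spread.
#'
#' @param n_devices Number of devices.
#' @param pulses Write pulses applied to each device.
#' @param params An `eoect_params`.
#' @param v_read Read voltage in V.
#' @param seed Optional integer seed for the variability draws.
#' @return A data.frame with columns `device`, `dev_factor`, `n_pulses`,
#'   `g_uS`, `i_uA`.
#' @examples
#' pop <- grow_device_population(32, 5, seed = 1)
#' 100 * stats::sd(pop$i_uA) / mean(pop$i_uA)  # sample CV in percent
#' @export
grow_device_population <- function(n_devices, pulses,
                                   params = device_params(),
                                   v_read = params$v_read,
                                   seed = NULL) {
  stopifnot(n_devices >= 1, pulses >= 1)
  if (!is.null(seed)) set.seed(seed)
  fac <- draw_dev_factors(n_devices, params$cv_device)
  states <- lapply(fac, function(f) {
    write_pulse(new_eoect(dev_factor = f), params, params$v_poly, pulses)
  })
  data.frame(
    device = seq_len(n_devices),
    dev_factor = fac,
    n_pulses = vapply(states, `[[`, integer(1), "n_pulses"),
    g_uS = vapply(states, `[[`, numeric(1), "g"),
    i_uA = vapply(states, read_current, numeric(1), params = params, v = v_read)
  )
}
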