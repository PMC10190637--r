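# The organic electrochemical neuron (OECN) output stage: a transimpedance
# bridge scales the classifier read current into the neuron's operating
# range; the neuron fires cathodic voltage spikes at a frequency set
# affinely by a positive injected current and stays silent for negative
# current (hard rectification at zero).

#' Parameters of the spiking-neuron stage
#'
#' Defaults reproduce the characterized operating point: spike frequencies
#' of 1 to 2.5 Hz over injected currents of 0.5 to 5 uA, cathodic spikes of
#' 0.47 V peak amplitude and 100 ms full width at half maximum, rendered at
#' 1 kHz.
#'
#' @param i_min,i_max Input-current operating range in uA.
#' @param f_min,f_max Spike frequencies in Hz at the range endpoints.
#' @param amplitude Cathodic spike peak amplitude in V (positive number;
#'   the rendered excursion is negative-going).
#' @param half_width Spike full width at half maximum in s.
#' @param fs Waveform sampling rate in Hz.
#' @return An object of class `neuron_params`.
#' @export
neuron_params <- function(i_min = 0.5, i_max = 5, f_min = 1, f_max = 2.5,
                          amplitude = 0.47, half_width = 0.1, fs = 1000) {
  if (i_min >= i_max) stop("i_min must be < i_max", call. = FALSE)
  if (f_min <= 0 || f_max < f_min) stop("need 0 < f_min <= f_max", call. = FALSE)
  if (amplitude <= 0) stop("amplitude must be > 0", call. = FALSE)
  if (half_width <= 0) stop("half_width must be > 0", call. = FALSE)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  structure(list(i_min = i_min, i_max = i_max, f_min = f_min, f_max = f_max,
                 amplitude = amplitude, half_width = half_width, fs = fs),
            class = "neuron_params")
}

#' Transimpedance bridge parameters
#'
#' The bridge is a linear, sign-preserving gain between the classifier
#' output current (read at 50 mV) and the current injected into the neuron.
#'
#' @param gain Dimensionless current gain (> 0).
#' @return An object of class `bridge_params`.
#' @export
bridge_params <- function(gain) {
  if (!is.numeric(gain) || gain <= 0) stop("gain must be > 0", call. = FALSE)
  structure(list(gain = gain), class = "bridge_params")
}

#' Size the bridge gain from a trained array
#'
#' Chooses the gain so that the read current of a reference (trained
#' positive-class) pattern maps exactly to the top of the neuron's
#' operating range `i_max`, driving the neuron at `f_max` while negative
#' classifier outputs stay rectified.
#'
#' @param array A trained `synapse_array`.
#' @param p The reference `eoect_pattern`.
#' @param neuron A `neuron_params`.
#' @return A `bridge_params`.
#' @export
default_bridge_gain <- function(array, p, neuron = neuron_params()) {
  i_ref <- read_pattern(array, p)
  if (i_ref <= 0) {
    stop("cannot size the bridge: the reference pattern does not read positive",
         call. = FALSE)
  }
  bridge_params(gain = neuron$i_max / i_ref)
}

#' Bridge a classifier current into the neuron
#'
#' @param i_classifier Classifier output current in uA (vectorized).
#' @param bridge A `bridge_params`.
#' @return Injected current in uA.
#' @export
bridge_current <- function(i_classifier, bridge) {
  stopifnot(inherits(bridge, "bridge_params"))
  bridge$gain * i_classifier
}

#' Spike frequency of the neuron for an injected current
#'
#' Zero for non-positive current (the neuron shows no response to negative
#' injection). On the operating range the frequency interpolates affinely
#' between `(i_min, f_min)` and `(i_max, f_max)`; above `i_max` it clamps
#' at `f_max`; between 0 and `i_min` the affine segment is extrapolated
#' downward and floored at 0.
#'
#' @param i_inj Injected current in uA (vectorized).
#' @param params A `neuron_params`.
#' @return Frequency in Hz.
#' @examples
#' spike_frequency(c(-1, 0.5, 2.75, 5, 10))
#' @export
spike_frequency <- function(i_inj, params = neuron_params()) {
  stopifnot(inherits(params, "neuron_params"), all(is.finite(i_inj)))
  slope <- (params$f_max - params$f_min) / (params$i_max - params$i_min)
  f <- params$f_min + (i_inj - params$i_min) * slope
  f <- pmin(f, params$f_max)
  f <- pmax(f, 0)
  f[i_inj <= 0] <- 0
  f
}

#' Simulate a spike train and render its voltage waveform
#'
#' Integrate-then-fire timing: the phase advances at the instantaneous
#' frequency and a spike is emitted each time it completes a full cycle, so
#' the first spike occurs one full inter-spike interval after positive
#' current onset, and a constant input of frequency `f` yields
#' `floor(duration * f)` spikes at exactly regular intervals. No spikes are
#' emitted while the frequency is zero. Each spike is rendered on a sampled
#' trace as a negative-going (cathodic) Gaussian pulse with the configured
#' peak amplitude and full width at half maximum, centred on the spike
#' time.
#'
#' @param i_inj Injected current in uA: a constant, or a function of time
#'   `f(t)` in s returning uA.
#' @param duration Simulation length in s (> 0).
#' @param params A `neuron_params`.
#' @return An object of class `spike_train`: list with `times` (spike times
#'   in s), `duration`, `params`, and `trace` (data.frame `t_s`, `v_V`).
#' @examples
#' st <- simulate_spike_train(5, 2)
#' length(st$times)  # 5 spikes at 2.5 Hz over 2 s
#' @export
simulate_spike_train <- function(i_inj, duration, params = neuron_params()) {
  stopifnot(inherits(params, "neuron_params"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("duration must be > 0", call. = FALSE)
  }
  if (is.function(i_inj)) {
    dt <- 1 / params$fs
    tt <- seq(0, duration, by = dt)
    f_t <- spike_frequency(vapply(tt, i_inj, numeric(1)), params)
    phase <- 0
    times <- numeric(0)
    for (k in seq_along(tt)[-length(tt)]) {
      phase <- phase + f_t[k] * dt
      if (phase >= 1) {
        phase <- phase - 1
        times <- c(times, tt[k + 1L])
      }
    }
  } else {
    f <- spike_frequency(i_inj, params)
    times <- if (f > 0) seq_len(floor(duration * f)) / f else numeric(0)
  }
  structure(
    list(times = times, duration = duration, params = params,
         trace = .render_trace(times, duration, params)),
    class = "spike_train"
  )
}

# Sampled voltage trace: sum of cathodic Gaussian pulses, one per spike.
.render_trace <- function(times, duration, params) {
  tt <- seq(0, duration, by = 1 / params$fs)
  v <- numeric(length(tt))
  c4 <- 4 * log(2) / params$half_width^2
  for (s in times) {
    win <- which(abs(tt - s) <= 3 * params$half_width)
    v[win] <- v[win] - params$amplitude * exp(-c4 * (tt[win] - s)^2)
  }
  data.frame(t_s = tt, v_V = v)
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("Spike train: %d spikes over %g s (%.3g Hz mean)\n",
              length(x$times), x$duration, length(x$times) / x$duration))
  invisible(x)
}

#' Number of spikes in a train
#' @param train A `spike_train`.
#' @return Integer spike count.
#' @export
spike_count <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  length(train$times)
}

#' Measure the rendered spike waveform
#'
#' Locates the spike nearest the middle of the train on the sampled trace
#' and measures its peak excursion and full width at half maximum.
#'
#' @param train A `spike_train` with at least one spike.
#' @return List with `peak_v` (signed peak voltage, negative for cathodic
#'   spikes) and `fwhm_s` (width in s at half the peak excursion).
#' @export
measure_spike_waveform <- function(train) {
  stopifnot(inherits(train, "spike_train"))
  if (length(train$times) == 0L) stop("train has no spikes", call. = FALSE)
  p <- train$params
  s <- train$times[ceiling(length(train$times) / 2)]
  tr <- train$trace
  win <- which(tr$t_s >= s - 2 * p$half_width & tr$t_s <= s + 2 * p$half_width)
  t <- tr$t_s[win]
  v <- tr$v_V[win]
  peak <- min(v)
  half <- peak / 2
  below <- which(v <= half)
  i1 <- below[1]; i2 <- below[length(below)]
  # linear interpolation of the two half-level crossings
  t_lo <- if (i1 > 1) {
    t[i1 - 1] + (half - v[i1 - 1]) / (v[i1] - v[i1 - 1]) * (t[i1] - t[i1 - 1])
  } else t[i1]
  t_hi <- if (i2 < length(v)) {
    t[i2] + (half - v[i2]) / (v[i2 + 1] - v[i2]) * (t[i2 + 1] - t[i2])
  } else t[i2]
  list(peak_v = peak, fwhm_s = t_hi - t_lo)
}

#' Contraction-proxy response trace
#'
#' A signal-level stand-in for an actuated muscle response: the spike count
#' in a sliding window, scaled by `k`. Identically zero wherever the window
#' contains no spikes and strictly positive wherever it does.
#'
#' @param train A `spike_train`.
#' @param window Sliding-window length in s (> 0).
#' @param k Response units per spike.
#' @param dt Output sampling interval in s.
#' @return A data.frame with columns `t_s` and `response` (arbitrary
#'   units).
#' @export
contraction_proxy <- function(train, window = 2, k = 1, dt = 0.01) {
  stopifnot(inherits(train, "spike_train"))
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  tt <- seq(0, train$duration, by = dt)
  counts <- vapply(tt, function(t0) {
    sum(train$times > t0 - window & train$times <= t0)
  }, numeric(1))
  data.frame(t_s = tt, response = k * counts)
}
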