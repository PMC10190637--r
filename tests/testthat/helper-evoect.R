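# Shared fixtures: ideal (variability-free) device parameterizations and
# small random-object generators.

ideal_params <- function(...) device_params(cv_device = 0, ...)

# Equal-increment reference law: G(n) = g_step * n, no percolation
# threshold; makes the training algebra exact.
linear_params <- function(g_step = 1, ...) {
  device_params(cv_device = 0, growth_law = "linear", g_step = g_step, ...)
}

fresh_ideal_array <- function(params = ideal_params()) synapse_array(params)

fresh_linear_array <- function(g_step = 1) synapse_array(linear_params(g_step))

random_bipolar_pattern <- function() pattern(sample(c(-1L, 1L), 16, replace = TRUE))

# Explicit independent read oracle: loop over pixels, apply the two-wire
# voltage rule by hand from the raw conductances.
oracle_read <- function(array, px) {
  g <- array_conductances(array)
  v <- array$cfg$v
  sum(ifelse(px > 0, v * (g[, "plus"] - g[, "minus"]),
             v * (g[, "minus"] - g[, "plus"])))
}
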