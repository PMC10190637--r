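# Two-wire array semantics: random init, Eq.-style pixel reads, summation,
# classification, write modes, negative-input calibration.

test_that("random initialization draws bounded sign-mixed weights reproducibly", {
  p <- device_params()
  a1 <- init_random(p, c(2, 5), seed = 123)
  a2 <- init_random(p, c(2, 5), seed = 123)
  expect_identical(array_weights(a1), array_weights(a2))

  # with variability off, every conductance is one of G(2..5)
  a0 <- init_random(ideal_params(), c(2, 5), seed = 7)
  g <- as.vector(array_conductances(a0))
  expect_true(all(vapply(g, function(x) {
    any(abs(x - conductance_at(ideal_params(), 2:5)) < 1e-9)
  }, logical(1))))
  expect_true(any(array_weights(a0) > 0) && any(array_weights(a0) < 0))

  # degenerate case: identical pulse counts, no variability -> all zero
  az <- init_random(ideal_params(), c(2, 2), seed = 1)
  expect_equal(array_weights(az), rep(0, 16))

  expect_error(init_random(p, c(1, 5), seed = 1), "one-pulse")
  expect_error(init_random(p, c(5, 2), seed = 1), "non-decreasing")
})

test_that("pixel reads follow the two-wire voltage rule", {
  cfg <- read_config(v = 0.05)
  px <- list(plus = new_eoect(), minus = new_eoect())
  px$plus$g <- 10; px$minus$g <- 4
  expect_equal(read_pixel(px, +1, cfg), 0.3, tolerance = 1e-12)
  expect_equal(read_pixel(px, -1, cfg), -0.3, tolerance = 1e-12)
  px$minus$g <- 10
  expect_equal(read_pixel(px, +1, cfg), 0)   # balanced pixel
  expect_error(read_pixel(px, 0, cfg), "\\+1 or -1")
})

test_that("pattern reads equal the explicit pixel-loop oracle and never mutate the array", {
  set.seed(31)
  for (k in 1:200) {
    arr <- init_random(device_params(), c(2, 6),
                       seed = sample.int(1e6, 1))
    px <- sample(c(-1L, 1L), 16, replace = TRUE)
    before <- arr
    got <- read_pattern(arr, px)
    expect_equal(got, oracle_read(arr, px), tolerance = 1e-12)
    # antisymmetry under pattern inversion (ideal read config)
    expect_equal(read_pattern(arr, -px), -got, tolerance = 1e-12)
    expect_identical(arr, before)
  }
})

test_that("classification uses the natural zero boundary with an explicit dead band", {
  expect_identical(classify(0.5), "positive")
  expect_identical(classify(-0.5), "negative")
  expect_identical(classify(0), "indeterminate")
  expect_identical(classify(0.05, tol = 0.1), "indeterminate")
  expect_identical(classify(-0.2, tol = 0.1), "negative")
  expect_error(classify(1, tol = -1))
})

test_that("one write pass separates any pattern from its inverse on a fresh ideal array", {
  set.seed(41)
  for (k in 1:200) {
    p <- random_bipolar_pattern()
    arr <- fresh_linear_array()
    arr <- write_pattern(arr, p, "positive", pulses = 1, background = TRUE)
    expect_identical(classify(read_pattern(arr, p)), "positive")
    expect_identical(classify(read_pattern(arr, pattern_negate(p))), "negative")
  }
})

test_that("read current is affine in Hamming distance after a single pattern write", {
  g_step <- 1
  v <- 0.05
  p <- pattern_from_keys(c(1, 4, 6, 11, 16))
  arr <- fresh_linear_array(g_step)
  arr <- write_pattern(arr, p, "positive", pulses = 1, background = TRUE)
  for (h in 0:16) {
    q <- p$pixels
    if (h > 0) q[seq_len(h)] <- -q[seq_len(h)]
    expect_equal(read_pattern(arr, q), v * g_step * (16 - 2 * h),
                 tolerance = 1e-12)
  }
})

test_that("write modes target the correct devices, with and without background", {
  p <- pattern_from_keys(c(1, 5, 9))
  arr <- fresh_ideal_array()
  arr <- write_pattern(arr, p, "positive", pulses = 2, background = FALSE)
  g <- array_conductances(arr)
  expect_true(all(g[c(1, 5, 9), "plus"] > 0))
  expect_equal(sum(g) - sum(g[c(1, 5, 9), "plus"]), 0)  # nothing else touched

  arr2 <- write_pattern(fresh_ideal_array(), p, "positive", pulses = 2,
                        background = TRUE)
  g2 <- array_conductances(arr2)
  expect_true(all(g2[c(1, 5, 9), "plus"] > 0))
  expect_true(all(g2[-c(1, 5, 9), "minus"] > 0))
  expect_equal(sum(g2[c(1, 5, 9), "minus"]), 0)

  # negative polarity swaps the targets
  arr3 <- write_pattern(fresh_ideal_array(), p, "negative", pulses = 2,
                        background = TRUE)
  g3 <- array_conductances(arr3)
  expect_true(all(g3[c(1, 5, 9), "minus"] > 0))
  expect_true(all(g3[-c(1, 5, 9), "plus"] > 0))

  expect_error(write_pattern(arr, p, "positive", pulses = 0), ">= 1")
})

test_that("negative-input scaling calibrates magnitude-matched reads", {
  arr <- init_random(ideal_params(), c(2, 5), seed = 5)
  expect_equal(calibrate_negative_scale(arr), 1, tolerance = 1e-6)

  arr$cfg <- read_config(epsilon = 0.1)
  alpha <- calibrate_negative_scale(arr)
  expect_equal(alpha, 1 / 0.9, tolerance = 1e-3)  # ~1.111
  # verify by re-reading both polarities with the calibrated alpha
  arr$cfg$alpha <- alpha
  p <- pattern_library()$T_left
  expect_lt(abs(abs(read_pattern(arr, p)) -
                abs(read_pattern(arr, pattern_negate(p)))),
            1e-3 * abs(read_pattern(arr, p)))

  expect_error(calibrate_negative_scale(fresh_ideal_array()), "unformed")
})
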