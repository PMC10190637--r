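# Training protocols: paired one-shot writes, touchpad spike counting, and
# the pulse-quantized LMS trainer under the increase-only constraint.

test_that("one iteration on a fresh equal-increment array gives the dot-product currents", {
  lib <- pattern_library()
  g_step <- 1
  v <- 0.05
  arr <- fresh_linear_array(g_step)
  arr <- one_shot_iteration(arr, lib$T_left, lib$J_left, pulses = 1)
  # weights become g_step * (t - j); reads are v * (t.t - t.j) = 18 v dG
  expect_equal(read_pattern(arr, lib$T_left), 18 * v * g_step,
               tolerance = 1e-12)
  expect_equal(read_pattern(arr, lib$J_left), -18 * v * g_step,
               tolerance = 1e-12)
  expect_error(one_shot_iteration(arr, lib$T_left, lib$J_left, pulses = 0))
})

test_that("one iteration separates each fixture pair on a fresh calibrated array", {
  lib <- pattern_library()
  pairs <- list(c("T_left", "J_left"), c("T_right", "J_right"),
                c("T_rot", "J_rot"))
  for (pr in pairs) {
    arr <- fresh_ideal_array()
    arr <- one_shot_iteration(arr, lib[[pr[1]]], lib[[pr[2]]], pulses = 1)
    expect_identical(classify(read_pattern(arr, lib[[pr[1]]])), "positive")
    expect_identical(classify(read_pattern(arr, lib[[pr[2]]])), "negative")
  }
})

test_that("one iteration corrects a randomly initialized array in almost every run", {
  lib <- pattern_library()
  ok <- 0L
  n <- 200L
  for (s in seq_len(n)) {
    arr <- init_random(seed = s)
    arr <- one_shot_iteration(arr, lib$T_left, lib$J_left, pulses = 1)
    ok <- ok + (classify(read_pattern(arr, lib$T_left)) == "positive" &&
                  classify(read_pattern(arr, lib$J_left)) == "negative")
  }
  expect_gte(ok / n, 0.97)  # run-dependent: rare inits need a second iteration
})

test_that("touchpad presses quantize into spike trains through the divider", {
  sched <- touchpad_session(c(`1` = 1.35, `6` = 0.05, `10` = 0.75))
  expect_identical(sched$pulses[sched$pixel == 1L], 7L)   # ceil(1.35/0.2)
  expect_identical(sched$pulses[sched$pixel == 6L], 1L)   # shortest press
  expect_identical(sched$pulses[sched$pixel == 10L], 4L)
  expect_equal(unique(sched$amplitude_v), 5 * 10e3 / (82e3 + 10e3),
               tolerance = 1e-12)                          # ~0.543 V
  expect_equal(unique(sched$width_s), 0.1)
  expect_identical(sort(sched$pixel), c(1L, 6L, 10L))      # pressed keys only

  expect_identical(nrow(touchpad_session(c())), 0L)        # empty is a no-op
  expect_error(touchpad_session(c(`1` = -2)), "> 0")
  expect_error(touchpad_session(c(`99` = 1)), "1..16")
})

test_that("touchpad-written letters classify robustly under random 1-7 spike counts", {
  lib <- pattern_library()
  tk <- positive_keys(lib$T_left)
  jk <- positive_keys(lib$J_left)
  set.seed(61)
  ok <- 0L
  n <- 300L
  for (tr in seq_len(n)) {
    arr <- fresh_ideal_array()
    t_press <- stats::setNames(stats::runif(length(tk), 0.01, 1.39), tk)
    j_press <- stats::setNames(stats::runif(length(jk), 0.01, 1.39), jk)
    arr <- apply_schedule(arr, touchpad_session(t_press, device = "plus"))
    arr <- apply_schedule(arr, touchpad_session(j_press, device = "minus"))
    ok <- ok + (classify(read_pattern(arr, lib$T_left)) == "positive" &&
                  classify(read_pattern(arr, lib$J_left)) == "negative")
  }
  expect_gte(ok / n, 0.97)
})

test_that("a converged LMS step is a no-op and the sign rule routes every pulse", {
  lib <- pattern_library()
  # zero error: no writes at all
  arr <- fresh_linear_array()
  arr <- one_shot_iteration(arr, lib$T_left, lib$J_left, pulses = 1)
  cfg <- lms_config(target_uA = read_pattern(arr, lib$T_left))
  st <- lms_step_quantized(arr, lib$T_left, +1, cfg)
  expect_identical(nrow(st$schedule), 0L)
  expect_identical(array_weights(st$array), array_weights(arr))

  # uniform positive demand: all pulses land on EOECT+
  all_on <- pattern(rep(1L, 16))
  st2 <- lms_step_quantized(fresh_linear_array(), all_on, +1,
                            lms_config(eta = 100))
  expect_gt(nrow(st2$schedule), 0L)
  expect_true(all(st2$schedule$device == "plus"))

  # audit over random steps: pulse direction always matches sign(e * x)
  set.seed(71)
  for (k in 1:50) {
    arr <- init_random(seed = 3000 + k)
    p <- random_bipolar_pattern()
    tgt <- sample(c(-1, 1), 1)
    e <- tgt * 1 - read_pattern(arr, p)
    st <- lms_step_quantized(arr, p, tgt)
    if (nrow(st$schedule)) {
      want <- ifelse(e * p$pixels[st$schedule$pixel] > 0, "plus", "minus")
      expect_identical(st$schedule$device, want)
    }
  }
})

test_that("LMS training never decreases a conductance and flags saturated demands", {
  set.seed(81)
  arr <- init_random(seed = 17)
  lib <- pattern_library()
  g_prev <- array_conductances(arr)
  for (k in 1:20) {
    p <- lib[[sample(length(lib), 1)]]
    arr <- lms_step_quantized(arr, p, sample(c(-1, 1), 1))$array
    g <- array_conductances(arr)
    expect_true(all(g - g_prev >= -1e-12))
    g_prev <- g
  }
  # a demand far beyond what the cap can deliver is flagged
  st <- lms_step_quantized(fresh_ideal_array(), pattern(rep(1L, 16)), +1,
                           lms_config(eta = 1e5, max_pulses_per_step = 2))
  expect_true(attr(st$schedule, "saturated"))
})

test_that("quantized LMS converges on the six-letter set within ten epochs", {
  lib <- pattern_library()
  arr <- init_random(seed = 1)
  fit <- lms_train(arr, unname(lib),
                   targets = ifelse(startsWith(names(lib), "T"), 1, -1))
  expect_true(fit$converged)
  expect_lte(fit$epochs_run, 10L)
  for (nm in names(lib)) {
    want <- if (startsWith(nm, "T")) "positive" else "negative"
    expect_identical(classify(read_pattern(fit$array, lib[[nm]])), want)
  }
})
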