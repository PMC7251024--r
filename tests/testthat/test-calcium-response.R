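# dF/F computation, noise estimation, response scoring and classification.

test_that("compute_dff matches the direct formula and handles edge cases", {
  prot <- small_protocol()
  n <- 200
  # constant cell and background give identically zero dF/F
  tr <- fluorescence_trace("c", rep(2, n), rep(1, n), 10)
  d <- compute_dff(tr, prot)
  expect_equal(d$values, rep(0, n))
  expect_equal(d$f0, 1)

  # doubling of cell-minus-background over f0 gives a peak of exactly 1
  f <- rep(1, n)
  f[101:120] <- 2   # 10-12 s: inside the stimulus window
  tr <- fluorescence_trace("c", f + 1, rep(1, n), 10)
  expect_equal(max(compute_dff(tr, prot)$values), 1)

  # random trace against an independently coded two-line oracle
  set.seed(42)
  fc <- runif(n, 2, 3)
  fb <- runif(n, 0.5, 1)
  tr <- fluorescence_trace("c", fc, fb, 10)
  d <- compute_dff(tr, prot)
  t_s <- (seq_len(n) - 1) / 10
  f0_oracle <- mean((fc - fb)[t_s >= 6 & t_s <= 8])
  expect_equal(d$values, ((fc - fb) - f0_oracle) / f0_oracle,
               tolerance = 1e-12)

  # inverse reconstruction recovers the input
  fc_rec <- d$values * d$f0 + d$f0 + fb
  expect_equal(fc_rec, fc, tolerance = 1e-10)

  # degenerate baseline is rejected
  tr <- fluorescence_trace("c", rep(1, n), rep(1, n), 10)
  expect_error(compute_dff(tr, prot), "degenerate baseline")
  expect_error(fluorescence_trace("c", 1:3, 1:4, 10), "equal length")
})

test_that("estimate_noise is a calibrated robust SD of non-stimulus samples", {
  # iid Gaussian baseline, sd = 0.02, >= 3000 baseline samples
  prot <- stimulus_protocol(150, stim_duration_s = 5, isi_s = 15,
                            frame_rate_hz = 10)
  set.seed(7)
  v <- rnorm(3200, 0, 0.02)
  est <- estimate_noise(make_dff(v), prot)
  expect_gt(as.numeric(est), 0.018)
  expect_lt(as.numeric(est), 0.022)
  expect_false(attr(est, "degenerate"))

  # all-zero baseline: zero with a degenerate flag
  est0 <- estimate_noise(make_dff(rep(0, 3200)), prot)
  expect_equal(as.numeric(est0), 0)
  expect_true(attr(est0, "degenerate"))

  # a huge transient inside the stimulus window does not change the
  # estimate at all (stimulus samples are excluded)
  v2 <- v
  v2[1502:1530] <- 5  # 150.1-152.9 s, inside the window
  expect_identical(as.numeric(estimate_noise(make_dff(v2), prot)),
                   as.numeric(est))

  expect_error(estimate_noise(make_dff(rnorm(20)), small_protocol(1)),
               "baseline samples")
})

test_that("score_repetitions applies the inclusive 2x-noise rule per window", {
  prot <- small_protocol(onsets = c(10, 20), stim = 2)
  v <- rep(0, 300)
  v[105] <- 0.04  # peak exactly 2 x 0.02 inside window 1
  pos <- score_repetitions(make_dff(v), prot, noise_level = 0.02)
  expect_identical(pos, c(TRUE, FALSE))

  # transient between windows scores nothing
  v <- rep(0, 300)
  v[160] <- 1  # 15.9 s: between the two windows
  expect_identical(score_repetitions(make_dff(v), prot, 0.02),
                   c(FALSE, FALSE))

  # zero noise level: positive iff strictly positive
  v <- rep(0, 300)
  v[105] <- 1e-6
  expect_identical(score_repetitions(make_dff(v), prot, 0),
                   c(TRUE, FALSE))

  # window extending past the trace names the repetition
  expect_error(score_repetitions(make_dff(rep(0, 150)), prot, 0.02),
               "repetition 2")
})

test_that("classify_cell implements the three-way >=4 / <=1 rule", {
  expect_equal(classify_cell(c(T, T, T, T, F)), "LS")
  expect_equal(classify_cell(c(TRUE, rep(FALSE, 4))), "NS")
  expect_equal(classify_cell(c(TRUE, TRUE, TRUE, FALSE, FALSE)),
               "excluded")
  expect_equal(classify_cell(rep(FALSE, 5)), "NS")
  expect_equal(classify_cell(rep(TRUE, 5)), "LS")
  expect_error(classify_cell(logical(0)), "at least one")
  # label is invariant to repetition order
  set.seed(1)
  pos <- c(TRUE, FALSE, TRUE, TRUE, TRUE)
  for (i in 1:5)
    expect_equal(classify_cell(sample(pos)), classify_cell(pos))
})

test_that("response_magnitude equals the windowed oracle", {
  prot <- small_protocol(onsets = c(10, 20), stim = 2)
  expect_equal(response_magnitude(make_dff(rep(0, 300)), prot), 0)

  # noiseless transients of peak 0.5 each repetition, zero pre-baseline
  v <- rep(0, 300)
  v[105] <- 0.5
  v[205] <- 0.5
  expect_equal(response_magnitude(make_dff(v), prot), 0.5)

  # arbitrary seeded trace against a brute-force windowed oracle
  set.seed(11)
  v <- rnorm(300, 0, 0.1)
  t_s <- (seq_len(300) - 1) / 10
  per_rep <- vapply(c(10, 20), function(on) {
    max(v[t_s >= on & t_s <= on + 2]) -
      mean(v[t_s >= on - 4 & t_s <= on - 2])
  }, numeric(1))
  expect_equal(response_magnitude(make_dff(v), prot), mean(per_rep),
               tolerance = 1e-12)

  expect_error(response_magnitude(make_dff(rep(0, 160)), prot),
               "repetition 2")
})

test_that("count_events applies hysteresis between 2x and 1x noise", {
  expect_equal(count_events(make_dff(rep(0, 100)), 0.02), 0)

  # three separated pulses
  v <- rep(0, 100)
  v[c(10, 40, 70)] <- 1
  expect_equal(count_events(make_dff(v), 0.02), 3)

  # merged double peak that never dips below 1x noise counts once
  v <- rep(0, 100)
  v[10:30] <- c(rep(0.1, 8), rep(0.03, 5), rep(0.1, 8))  # dip to 1.5x noise
  expect_equal(count_events(make_dff(v), 0.02), 1)
  # but a dip below 1x noise separates the excursions
  v[18:22] <- 0.01
  expect_equal(count_events(make_dff(v), 0.02), 2)

  # window restriction
  v <- rep(0, 100)
  v[c(10, 80)] <- 1
  expect_equal(count_events(make_dff(v), 0.02, window = c(0, 5)), 1)
  expect_error(count_events(make_dff(v), 0.02, window = c(5, 50)),
               "within the trace")
})

test_that("amplitude scaling never decreases the positive count", {
  prot <- small_protocol(onsets = c(10, 20, 30), stim = 2)
  set.seed(3)
  base <- rnorm(400, 0, 0.02)
  transients <- rep(0, 400)
  transients[c(103, 205, 303)] <- c(0.03, 0.05, 0.02)
  counts <- vapply(c(1, 1.5, 2, 5, 20), function(cc)
    sum(score_repetitions(make_dff(base + cc * transients), prot, 0.02)),
    numeric(1))
  expect_true(all(diff(counts) >= 0))
})
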