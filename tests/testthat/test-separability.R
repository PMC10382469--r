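test_that("separability matches hand-evaluated cases", {
  expect_equal(separability_score(list(c(0, 1, 2), c(4, 5, 6))), 2.0)
  # all groups share a median -> zero
  expect_equal(separability_score(list(c(-1, 0, 1), c(-5, 0, 5),
                                       c(0, 0, 2, -2))), 0)
})

test_that("separability is shift/scale invariant and label-symmetric", {
  set.seed(11)
  g <- lapply(1:5, function(i) rnorm(8, mean = i))
  s0 <- separability_score(g)
  expect_equal(separability_score(lapply(g, function(x) x + 17)), s0)
  expect_equal(separability_score(lapply(g, function(x) x * 3.7)), s0)
  expect_equal(separability_score(rev(g)), s0)
})

test_that("separability equals the naive double-loop oracle", {
  set.seed(12)
  for (rep in 1:200) {
    k <- sample(2:7, 1)
    g <- lapply(seq_len(k), function(i)
      rnorm(sample(2:50, 1), mean = runif(1, -2, 2), sd = runif(1, .1, 2)))
    expect_equal(separability_score(g), naive_separability(g),
                 tolerance = 1e-12)
  }
})

test_that("degenerate zero-dispersion pairs are skipped with a warning", {
  expect_warning(s <- separability_score(list(c(1, 1, 1), c(2, 2, 2),
                                              c(0, 1, 2))),
                 "normaliser")
  # remaining pairs: (1,3) and (2,3); d=|1-1|=0? medians 1,2, sd3=1
  expect_equal(s, (abs(1 - 1) / 1 + abs(2 - 1) / 1) / 2)
  expect_error(separability_score(list(1, c(1, 2))), "at least 2 values")
})

test_that("the vectorised batch scorer agrees with the scalar operation", {
  set.seed(13)
  amps <- array(rnorm(4 * 6 * 40), c(4, 6, 40))
  groups <- split(1:40, rep(1:5, each = 8))
  sc <- pitcherp:::batch_separability(amps, groups)
  for (ch in c(1, 4)) for (w in c(2, 6)) {
    g <- lapply(groups, function(idx) amps[ch, w, idx])
    expect_equal(sc[ch, w], separability_score(g), tolerance = 1e-12)
  }
})

test_that("the sliding scan yields 71 windows and finds a planted effect", {
  m <- standard_montage()
  sch <- generate_schedule(21, n_blocks = 2)
  tr <- ground_truth(m, slope = 0.8, noise_sd = 3)
  was <- lapply(1:2, function(s) {
    rec <- simulate_subject(m, sch, tr, seed = 100 + s)
    pitcherp:::continuous_window_amps(rec)
  })
  curve <- scan_windows(was, half = 1)
  expect_equal(nrow(curve), 71)
  expect_equal(curve$window_start, seq(0, 700, 10))
  expect_true(all(curve$score >= 0))
  win <- select_window(curve)
  expect_lte(abs(win$start_ms - 540), 30)
  expect_equal(win$end_ms, win$start_ms + 100)
})

test_that("white-noise epochs give an approximately flat curve", {
  m <- standard_montage()
  sch <- generate_schedule(22, n_blocks = 2)
  tr <- ground_truth(m, slope = 0, noise_sd = 5)
  ratios <- vapply(1:5, function(i) {
    rec <- simulate_subject(m, sch, tr, seed = 200 + i)
    curve <- scan_windows(pitcherp:::continuous_window_amps(rec), half = 1)
    max(curve$score) / median(curve$score)
  }, numeric(1))
  expect_true(all(ratios < 2))
})

test_that("window-selection ties break toward the earliest start", {
  curve <- data.frame(window_start = c(0, 10, 20), score = c(1, 2, 2),
                      sem = 0)
  class(curve) <- c("separability_curve", "data.frame")
  expect_message(win <- select_window(curve), "tie")
  expect_equal(win$start_ms, 10)
  # monotone curve selects the last window
  curve2 <- data.frame(window_start = c(0, 10, 20), score = 1:3, sem = 0)
  class(curve2) <- c("separability_curve", "data.frame")
  expect_equal(select_window(curve2)$start_ms, 20)
})

test_that("scanning errors when a pitch has no usable half-1 trials", {
  s <- small_subject()
  wa <- pitcherp:::continuous_window_amps(s$rec)
  wa$meta$half[wa$meta$pitch == 3] <- 2L
  expect_error(scan_windows(wa, half = 1), "pitch 3")
})
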