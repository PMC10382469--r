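test_that("epochs span [-100, 800) ms with 450 samples and zero baseline", {
  s <- small_subject()
  ep <- epoch_and_filter(s$rec)
  expect_equal(dim(ep$data)[2], 450)
  expect_equal(ep$times[1], -100)
  expect_equal(ep$times[450], 798)
  expect_equal(dim(ep$data)[3], nrow(s$rec$events))
  # baseline-corrected pre-stimulus means are zero
  bl <- apply(ep$data[, ep$times < 0, ], c(1, 3), mean)
  expect_lt(max(abs(bl)), 1e-10)
})

test_that("a constant-voltage channel is exactly zero after baselining", {
  s <- small_subject()
  rec <- s$rec
  rec$data[3, ] <- 42
  ep <- epoch_and_filter(rec)
  expect_true(all(ep$data[3, , ] == 0))
})

test_that("target-pitch trials are marked and excluded from analysis halves", {
  s <- small_subject()
  ep <- epoch_and_filter(s$rec)
  ev <- s$rec$events
  expect_equal(ep$meta$is_target, ev$pitch == ev$target_pitch)
  expect_true(all(is.na(ep$meta$half[ep$meta$is_target])))
  expect_false(anyNA(ep$meta$half[!ep$meta$is_target]))
  # per pitch, every non-target trial is retained across the two halves
  for (p in 1:7) {
    n_all <- sum(ev$pitch == p)
    in_target_blocks <- sum(ev$pitch == p & ev$target_pitch == p)
    expect_equal(sum(ep$meta$pitch == p & !is.na(ep$meta$half)),
                 n_all - in_target_blocks)
  }
})

test_that("the half split is chronological within subject and pitch", {
  s <- small_subject()
  ep <- epoch_and_filter(s$rec)
  for (p in 1:7) {
    h1 <- which(ep$meta$pitch == p & ep$meta$half %in% 1)
    h2 <- which(ep$meta$pitch == p & ep$meta$half %in% 2)
    expect_true(max(h1) < min(h2))
    expect_gte(length(h1), length(h2))
    expect_lte(length(h1) - length(h2), 1)
  }
})

test_that("trials too close to the record edge are dropped with a warning", {
  s <- small_subject()
  rec <- s$rec
  rec$events$onset_sample[1] <- 10
  expect_warning(ep <- epoch_and_filter(rec), "dropped")
  expect_equal(dim(ep$data)[3], nrow(rec$events) - 1)
})

test_that("the continuous fast path equals the epoch-then-window path", {
  s <- small_subject()
  ep <- epoch_and_filter(s$rec)
  wa_slow <- window_amplitudes(ep)
  wa_fast <- pitcherp:::continuous_window_amps(s$rec)
  expect_equal(wa_fast$amps, wa_slow$amps, tolerance = 1e-10)
  expect_identical(wa_fast$meta, wa_slow$meta)
  # and without baseline correction
  ep0 <- epoch_and_filter(s$rec, baseline = FALSE)
  wa0 <- pitcherp:::continuous_window_amps(s$rec, baseline = FALSE)
  expect_equal(wa0$amps, window_amplitudes(ep0)$amps, tolerance = 1e-10)
})
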