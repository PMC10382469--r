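test_that("noiseless forward model reproduces the configured pitch contrast", {
  m <- standard_montage()
  sch <- generate_schedule(2, n_blocks = 2)
  tr <- ground_truth(m, slope = 0.5, noise_sd = 0)
  rec <- simulate_subject(m, sch, tr, seed = 3)
  wa <- pitcherp:::continuous_window_amps(rec)
  i <- which(wa$starts == 540)
  f3 <- match("F3", wa$channels)
  f4 <- match("F4", wa$channels)
  g <- lapply(1:7, function(p) which(wa$meta$pitch == p))
  c_f3 <- mean(wa$amps[f3, i, g[[7]]]) - mean(wa$amps[f3, i, g[[1]]])
  c_f4 <- mean(wa$amps[f4, i, g[[7]]]) - mean(wa$amps[f4, i, g[[1]]])
  expect_equal(c_f3, -3.0, tolerance = 1e-12)   # 6 steps x -0.5
  expect_equal(c_f4, +3.0, tolerance = 1e-12)
  # anti-symmetry: left and right are mirror images about the template
  expect_equal(wa$amps[f3, i, ] + wa$amps[f4, i, ],
               2 * wa$amps[match("Cz", wa$channels), i, ],
               tolerance = 1e-12)
})

test_that("forward model is linear in the configured slope", {
  m <- standard_montage()
  sch <- generate_schedule(4, n_blocks = 2)
  r1 <- simulate_subject(m, sch, ground_truth(m, slope = 0.3, noise_sd = 0),
                         seed = 1)
  r2 <- simulate_subject(m, sch, ground_truth(m, slope = 0.6, noise_sd = 0),
                         seed = 1)
  base <- simulate_subject(m, sch, ground_truth(m, slope = 0, noise_sd = 0),
                           seed = 1)
  expect_equal(r2$data - base$data, 2 * (r1$data - base$data),
               tolerance = 1e-12)
})

test_that("simulation is seed-deterministic and noise is calibrated", {
  s <- small_subject()
  rec2 <- simulate_subject(s$montage, s$schedule, s$truth, seed = 17)
  expect_identical(s$rec$data, rec2$data)
  rec3 <- simulate_subject(s$montage, s$schedule, s$truth, seed = 18)
  expect_false(identical(s$rec$data, rec3$data))
  # empirical noise SD near the configured 5 uV (quiet pre-task padding)
  quiet <- 1:900
  expect_equal(sd(s$rec$data[1, quiet]), 5, tolerance = 0.2)
})

test_that("trial-mean amplitudes match a naive per-trial loop", {
  s <- small_subject()
  rec <- s$rec
  wa <- pitcherp:::continuous_window_amps(rec)
  # naive: cut each epoch by explicit loops, baseline-correct, average
  i540 <- which(wa$starts == 540)
  sel_ch <- match(c("F3", "T8", "Cz"), rec$channels)
  for (k in c(1L, 2L, 25L, 60L, 99L)) {
    o <- rec$events$onset_sample[k]
    for (ci in sel_ch) {
      epoch <- rec$data[ci, (o - 50):(o + 399)]
      epoch <- epoch - mean(epoch[1:50])
      naive <- mean(epoch[(50 + 270 + 1):(50 + 270 + 50)])  # [540, 640) ms
      expect_equal(wa$amps[ci, i540, k], naive, tolerance = 1e-10)
    }
  }
})

test_that("effect windows outside the epoch are rejected", {
  m <- standard_montage()
  expect_error(ground_truth(m, effect_window = c(700, 900)), "800")
  expect_error(ground_truth(m, effect_window = c(-50, 100)), "800")
})

test_that("artifact injection is seeded, Poisson-paced and additive", {
  s <- small_subject()
  expect_identical(inject_artifacts(s$rec, 0, 500, 1)$data, s$rec$data)
  b1 <- inject_artifacts(s$rec, 6, 500, seed = 9)
  b2 <- inject_artifacts(s$rec, 6, 500, seed = 9)
  expect_identical(b1$data, b2$data)
  expect_gt(length(b1$artifact_times), 0)
  expect_gt(max(abs(b1$data - s$rec$data)), 250)
  # burst count across seeds is Poisson-ish around rate * duration
  dur_min <- ncol(s$rec$data) / s$rec$srate / 60
  ks <- vapply(1:30, function(sd) length(inject_artifacts(s$rec, 6, 500,
                                                          seed = sd)$artifact_times),
               numeric(1))
  expect_equal(mean(ks), 6 * dur_min, tolerance = 0.35)
})

test_that("behavioral counts reproduce the published group statistics", {
  mt <- simulate_behavior("MT", 10000, seed = 1)
  nt <- simulate_behavior("NT", 10000, seed = 2)
  expect_lt(abs(mean(mt) - 12.5), 0.1)
  expect_lt(abs(mean(nt) - 3.3), 0.1)
  expect_true(all(mt >= 0 & mt <= 14))
  expect_true(all(nt >= 0 & nt <= 14))
  expect_true(all(simulate_behavior("MT", 50, 3, sd = 0) == 12))
})
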