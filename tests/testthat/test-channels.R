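test_that("strongly shared signals flag no channels", {
  set.seed(1)
  base <- rnorm(5000)
  d <- t(replicate(31, base + rnorm(5000, sd = 0.05)))
  rep <- detect_bad_channels(make_recording(d))
  expect_false(any(rep$flagged))
})

test_that("an independent channel among common-mode channels is flagged", {
  set.seed(2)
  base <- rnorm(5000)
  d <- t(replicate(30, base + rnorm(5000, sd = 0.3)))
  d <- rbind(d, rnorm(5000))                      # independent channel
  rep <- detect_bad_channels(make_recording(d))
  expect_equal(attr(rep, "flagged"), "ch31")
  # oracle: its correlation row really is below threshold for all others
  cc <- cor(t(d))
  expect_true(all(cc[31, -31] < 0.4))
})

test_that("the 70% fraction threshold is strict", {
  set.seed(3)
  n <- 4000
  base <- rnorm(n)
  # channel 1 correlates highly with exactly half of the ten others
  d <- rbind(base,
             t(replicate(5, base + rnorm(n, sd = 0.3))),
             t(replicate(5, rnorm(n))))
  rep <- detect_bad_channels(make_recording(d))
  expect_false(rep$flagged[1])          # 5/10 = 0.5 < 0.7
  expect_equal(rep$low_corr_fraction[1], 0.5)
})

test_that("zero-variance channels warn and are flagged", {
  set.seed(4)
  d <- rbind(matrix(rnorm(3 * 1000), 3), 0)
  expect_warning(rep <- detect_bad_channels(make_recording(d)),
                 "zero-variance")
  expect_true(rep$flagged[4])
})

test_that("spherical-spline interpolation reproduces constants exactly", {
  m <- standard_montage()
  d <- matrix(3.5, 31, 10)
  rec <- make_recording(d, channels = m$channels)
  out <- interpolate_channels(rec, m, c("F3", "Oz"))
  expect_equal(out$data, d, ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("a smooth field is reconstructed within 5% at a left-out site", {
  m <- standard_montage()
  # low-order spherical-harmonic field (analytic values at all electrodes)
  v <- m$positions[, "z"]^2 - 0.3 * m$positions[, "x"]
  scale <- max(abs(v))
  for (ch in c("Cz", "F3", "P8")) {
    rec <- make_recording(matrix(v, 31, 3), channels = m$channels)
    out <- interpolate_channels(rec, m, ch)
    i <- match(ch, m$channels)
    expect_lt(abs(out$data[i, 1] - v[i]) / scale, 0.05)
  }
})

test_that("interpolation leaves good channels bit-identical", {
  s <- small_subject()
  short <- s$rec
  short$data <- short$data[, 1:2000]
  out <- interpolate_channels(short, s$montage, "FC1")
  keep <- setdiff(seq_len(31), match("FC1", s$montage$channels))
  expect_identical(out$data[keep, ], short$data[keep, ])
  expect_error(interpolate_channels(short, s$montage, "XX9"), "unknown")
})
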