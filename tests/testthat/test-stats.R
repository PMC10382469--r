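test_that("BH step-up matches hand and brute-force evaluation", {
  r <- fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.20), q = 0.05)
  expect_equal(r$significant, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_true(all(r$p_adj >= r$p))
  expect_false(any(fdr_bh(rep(1, 6))$significant))
  expect_true(fdr_bh(0.04)$significant)
  expect_equal(nrow(fdr_bh(numeric(0))), 0)
  set.seed(31)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    expect_equal(fdr_bh(p)$significant, bh_reject_bruteforce(p))
  }
})

test_that("KS normality check behaves as an advisory screen", {
  set.seed(32)
  norm_p <- vapply(1:20, function(i) ks_normality(rnorm(10000))$p, 1)
  unif_p <- vapply(1:20, function(i) ks_normality(runif(10000))$p, 1)
  expect_gte(mean(norm_p > 0.05), 0.95)
  expect_gte(mean(unif_p < 0.05), 0.95)
  x <- rnorm(100)
  expect_equal(ks_normality(x)$statistic,
               unname(suppressWarnings(
                 ks.test(x, "pnorm", mean(x), sd(x)))$statistic),
               tolerance = 1e-9)
  expect_warning(r <- ks_normality(rep(1, 10)), "constant")
  expect_equal(r$p, 0)
})

# Per-pitch mean fixture: subjects x channels x pitches. Channel values
# vary only by subject (within-cell dispersion without any between-pitch
# signal, so null channels have F = 0 exactly); `effect` plants a linear
# pitch dependence at named channels.
fake_pm <- function(n_s, channels, effect = NULL, sd = 0.1, seed = 1) {
  set.seed(seed)
  a <- matrix(rnorm(n_s * length(channels), sd = sd), n_s)
  pm <- array(rep(a, 7), c(n_s, length(channels), 7),
              dimnames = list(NULL, channels, NULL))
  if (!is.null(effect)) {
    for (ch in names(effect)) {
      ci <- match(ch, channels)
      pm[, ci, ] <- pm[, ci, ] +
        rep(effect[[ch]] * (1:7 - 4), each = n_s)
    }
  }
  pm
}

test_that("channel selection completes bilaterally and respects midline", {
  m <- standard_montage()
  pm_eff <- fake_pm(10, m$channels, effect = list(F3 = -0.8))
  pm_nul <- fake_pm(10, m$channels, seed = 2)
  sel <- select_channels(list(MT = pm_eff, NT = pm_nul), m)
  expect_setequal(attr(sel, "selected"), c("F3", "F4"))
  expect_equal(sel$origin[sel$channel == "F4"], "symmetric-completion")
  expect_equal(sel$origin[sel$channel == "F3"], "significant")
  expect_equal(attr(sel, "pairs")$left, "F3")

  sel0 <- select_channels(list(MT = fake_pm(10, m$channels, seed = 3),
                               NT = fake_pm(10, m$channels, seed = 4)), m)
  expect_length(attr(sel0, "selected"), 0)

  sel_cz <- select_channels(list(MT = fake_pm(10, m$channels,
                                              effect = list(Cz = 0.8),
                                              seed = 5),
                                 NT = fake_pm(10, m$channels, seed = 6)), m)
  expect_equal(attr(sel_cz, "selected"), "Cz")
  expect_equal(nrow(attr(sel_cz, "pairs")), 0)
})

test_that("the batch pitch ANOVA equals oneway.test", {
  pm <- fake_pm(10, c("A", "B", "C"), effect = list(B = 0.2), sd = 0.5)
  an <- pitcherp:::anova_pitch_batch(pm)
  for (ci in 1:3) {
    y <- as.vector(pm[, ci, ])
    g <- factor(rep(1:7, each = 10))
    ref <- oneway.test(y ~ g, var.equal = TRUE)
    expect_equal(an$F[ci], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(an$p[ci], ref$p.value, tolerance = 1e-10)
  }
})

test_that("paired asymmetry tests match t.test and find planted asymmetry", {
  m <- standard_montage()
  pm <- fake_pm(10, m$channels, effect = list(F3 = -0.8, F4 = 0.8), sd = 0.2)
  pairs <- data.frame(left = "F3", right = "F4")
  res <- paired_asymmetry_tests(list(G = pm), pairs)
  expect_equal(nrow(res), 7)
  # oracle at pitch 1
  tt <- t.test(pm[, match("F3", m$channels), 1],
               pm[, match("F4", m$channels), 1], paired = TRUE)
  expect_equal(res$t[res$pitch == 1], unname(tt$statistic), tolerance = 1e-9)
  expect_equal(res$p[res$pitch == 1], tt$p.value, tolerance = 1e-9)
  # extreme pitches asymmetric, centre pitch not
  expect_true(all(res$significant[res$pitch %in% c(1, 7)]))
  expect_false(res$significant[res$pitch == 4])
  # equal hemispheres give t = 0, p = 1
  pm2 <- pm
  pm2[, match("F4", m$channels), ] <- pm2[, match("F3", m$channels), ]
  res2 <- paired_asymmetry_tests(list(G = pm2), pairs)
  expect_true(all(res2$t == 0 & res2$p == 1))
})

test_that("slope fits are exact on linear data and match normal equations", {
  pm <- array(0, c(2, 2, 7), dimnames = list(NULL, c("A", "B"), NULL))
  pm[1, 1, ] <- 3 - 0.5 * (1:7)
  pm[2, 1, ] <- 2
  set.seed(33)
  pm[, 2, ] <- rnorm(14)
  st <- fit_pitch_slopes(pm)
  expect_equal(unname(st$slope[1, "A"]), -0.5)
  expect_equal(unname(st$intercept[1, "A"]), 3)
  expect_equal(unname(st$slope[2, "A"]), 0)
  for (s in 1:2) {
    ref <- lm(pm[s, 2, ] ~ x, data = list(x = 1:7))
    expect_equal(unname(st$slope[s, "B"]), unname(coef(ref)[2]),
                 tolerance = 1e-12)
    expect_equal(unname(st$intercept[s, "B"]), unname(coef(ref)[1]),
                 tolerance = 1e-12)
  }
})

test_that("one-sample slope tests match t.test and report signs", {
  set.seed(34)
  sl <- structure(list(slope = cbind(A = rnorm(10, -0.5, 0.1),
                                     B = rnorm(10, 0, 0.1),
                                     C = rep(0, 10)),
                       channels = c("A", "B", "C")),
                  class = "slope_table")
  res <- test_slopes_nonzero(sl)
  tt <- t.test(sl$slope[, "A"])
  expect_equal(res$t[1], unname(tt$statistic), tolerance = 1e-9)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-9)
  expect_true(res$significant[1])
  expect_equal(res$sign[1], -1)
  expect_false(res$significant[3])
})

test_that("region contrast uses exact signed-rank and matches enumeration", {
  m <- standard_montage()
  set.seed(35)
  n <- 10
  sl <- matrix(rnorm(n * 31, 0, 0.05), n, 31,
               dimnames = list(NULL, m$channels))
  # plant frontal asymmetry only
  for (pl in m$frontal_pairs) {
    lr <- strsplit(pl, "-")[[1]]
    sl[, lr[1]] <- sl[, lr[1]] - 0.4
    sl[, lr[2]] <- sl[, lr[2]] + 0.4
  }
  st <- structure(list(slope = sl, channels = m$channels),
                  class = "slope_table")
  res <- region_asymmetry_compare(st, m)
  expect_equal(nrow(res), 4)
  expect_true(all(res$significant))
  # oracle: exact enumeration of the signed-rank null
  fa <- sl[, "F4"] - sl[, "F3"]
  pa <- sl[, "P4"] - sl[, "P3"]
  expect_equal(res$p[res$frontal == "F3-F4"], signed_rank_enum_p(fa, pa),
               tolerance = 1e-12)
  # identical asymmetries are never significant
  sl2 <- sl
  for (k in 1:4) {
    f <- strsplit(m$frontal_pairs[k], "-")[[1]]
    p <- strsplit(m$parietal_pairs[k], "-")[[1]]
    sl2[, p[1]] <- sl2[, f[1]]
    sl2[, p[2]] <- sl2[, f[2]]
  }
  st2 <- structure(list(slope = sl2, channels = m$channels),
                   class = "slope_table")
  expect_true(all(region_asymmetry_compare(st2, m)$p == 1))
})

test_that("group slope comparison is Welch-exact and direction-aware", {
  set.seed(36)
  mk <- function(mu) structure(
    list(slope = matrix(rnorm(10 * 2, mu, 0.1), 10, 2,
                        dimnames = list(NULL, c("A", "B"))),
         channels = c("A", "B")), class = "slope_table")
  a <- mk(-1); b <- mk(-0.5)
  res <- compare_groups_slopes(a, b)
  tt <- t.test(abs(a$slope[, 1]), abs(b$slope[, 1]))
  expect_equal(res$t[1], unname(tt$statistic), tolerance = 1e-9)
  expect_equal(res$p[1], tt$p.value, tolerance = 1e-9)
  expect_true(all(res$stiffer == 1))
  same <- compare_groups_slopes(a, a)
  expect_false(any(same$significant))
})

test_that("the earliest discriminative window honours the majority rule", {
  ch <- c("F3", "F4", "Cz")
  n_s <- 10; n_w <- 8
  set.seed(37)
  pm <- array(rnorm(n_s * 3 * n_w * 7, sd = 0.3), c(n_s, 3, n_w, 7),
              dimnames = list(NULL, ch, NULL, NULL))
  starts <- seq(0, 70, 10)
  # effect at all channels from window 1 -> returns the first start
  pm1 <- pm
  for (w in 1:n_w) pm1[, , w, ] <- pm1[, , w, ] +
    rep(0.8 * (1:7 - 4), each = n_s * 3)
  expect_equal(earliest_discriminative_window(pm1, ch, starts), 0)
  # effect in 2/3 channels from window 4 only
  pm2 <- pm
  for (w in 4:n_w) for (ci in 1:2) pm2[, ci, w, ] <- pm2[, ci, w, ] +
    rep(0.8 * (1:7 - 4), each = n_s)
  expect_equal(earliest_discriminative_window(pm2, ch, starts), 30)
  # pure noise: no window qualifies
  expect_true(is.na(earliest_discriminative_window(pm, ch, starts)))
  expect_true(is.na(earliest_discriminative_window(pm, character(0), starts,
                                                   allow_empty = TRUE)))
  expect_error(earliest_discriminative_window(pm, character(0), starts),
               "empty")
})

test_that("behavior rank-sum is exact under ties and matches enumeration", {
  x <- c(3, 5, 6, 7); y <- c(1, 2, 2, 4)
  r <- behavior_test(x, y)
  expect_equal(r$p, rank_sum_enum_p(x, y), tolerance = 1e-12)
  expect_equal(r$method, "exact")
  # identical samples: p at the 1 level
  same <- behavior_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p, 0.9)
  # complete separation at n = 10/10 with heavy ties is p < 1e-4
  sep <- behavior_test(rep(c(11, 12, 13, 14), c(2, 3, 3, 2)),
                       rep(c(1, 2, 3, 4), c(2, 3, 3, 2)))
  expect_lt(sep$p, 1e-4)
  expect_equal(sep$p, 2 / choose(20, 10), tolerance = 1e-9)
})

test_that("behavior-slope correlations match the closed form", {
  set.seed(38)
  counts <- c(round(rnorm(10, 12.5, 1.5)), round(rnorm(10, 3.3, 2)))
  sl <- matrix(rnorm(20 * 3, 0, 0.1), 20, 3,
               dimnames = list(NULL, c("A", "B", "C")))
  sl[, 1] <- sl[, 1] + 0.05 * counts          # linear dependence
  sl[, 3] <- 0.01 * counts                    # noise-free dependence
  st <- structure(list(slope = sl, channels = colnames(sl)),
                  class = "slope_table")
  res <- correlate_behavior_slopes(counts, st)
  rr <- function(v) sum((counts - mean(counts)) * (v - mean(v))) /
    sqrt(sum((counts - mean(counts))^2) * sum((v - mean(v))^2))
  expect_equal(res$r, vapply(1:3, function(i) rr(sl[, i]), 1),
               tolerance = 1e-12)
  expect_equal(res$r[3], 1, tolerance = 1e-12)
  expect_true(res$significant[1])
})
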