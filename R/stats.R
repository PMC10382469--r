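#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate control: returns BH-adjusted p-values and
#' rejection flags at level `q`.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return data.frame with columns `p`, `p_adj`, `significant` (empty for
#'   empty input).
#' @export
fdr_bh <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0)
    return(data.frame(p = numeric(0), p_adj = numeric(0),
                      significant = logical(0)))
  stopifnot(all(pvalues >= 0 & pvalues <= 1, na.rm = TRUE))
  adj <- stats::p.adjust(pvalues, method = "BH")
  data.frame(p = pvalues, p_adj = adj, significant = !is.na(adj) & adj <= q)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS test of a sample against a normal distribution with the
#' sample's own mean and SD. Used as an advisory check before the
#' parametric tests (analyses proceed regardless; with estimated
#' parameters the test is conservative).
#'
#' @param sample Numeric vector (n >= 5).
#' @return data.frame with `statistic`, `p`.
#' @export
ks_normality <- function(sample) {
  stopifnot(length(sample) >= 5)
  s <- stats::sd(sample)
  if (s == 0) {
    warning("constant sample: normality rejected by convention (p = 0)")
    return(data.frame(statistic = NA_real_, p = 0))
  }
  kt <- suppressWarnings(stats::ks.test(sample, "pnorm", mean(sample), s))
  data.frame(statistic = unname(kt$statistic), p = kt$p.value)
}

# --- window-amplitude summaries -------------------------------------------

#' Per-pitch mean window amplitudes for one subject
#'
#' Averages a subject's trial window-mean amplitudes over the trials of
#' each pitch (non-target trials of the requested half only), for every
#' sliding window.
#'
#' @param wa A `window_amps`.
#' @param half Trial half (default 2, the inference half).
#' @param n_pitches Number of pitch classes.
#' @return Array channels x windows x pitches.
#' @export
pitch_window_means <- function(wa, half = 2, n_pitches = 7) {
  stopifnot(inherits(wa, "window_amps"))
  groups <- trial_groups(wa$meta, half = half, n_pitches = n_pitches)
  d <- dim(wa$amps)
  out <- array(NA_real_, c(d[1], d[2], n_pitches),
               dimnames = list(wa$channels, NULL, NULL))
  for (p in seq_len(n_pitches)) {
    g <- groups[[p]]
    if (length(g) == 0) next
    out[, , p] <- rowMeans(array(wa$amps[, , g, drop = FALSE],
                                 c(d[1] * d[2], length(g))))
  }
  out
}

# Stack per-subject [ch x win x pitch] arrays into [subj x ch x win x pitch].
stack_pitch_means <- function(pm_list) {
  d <- dim(pm_list[[1]])
  out <- array(NA_real_, c(length(pm_list), d))
  for (s in seq_along(pm_list)) out[s, , , ] <- pm_list[[s]]
  dimnames(out) <- c(list(NULL), dimnames(pm_list[[1]]))
  out
}

# Balanced one-way ANOVA across pitches, vectorised over cells.
# pm: array [n_subj, n_cells, n_pitch]. Returns list(F, p, df1, df2).
anova_pitch_batch <- function(pm) {
  n_s <- dim(pm)[1]; r <- dim(pm)[2]; k <- dim(pm)[3]
  mp <- apply(pm, c(2, 3), mean)                 # r x k
  gm <- rowMeans(mp)
  ssb <- n_s * rowSums((mp - gm)^2)
  resid <- pm - rep(mp, each = n_s)
  ssw <- apply(resid^2, 2, sum)
  df1 <- k - 1
  df2 <- k * (n_s - 1)
  f <- unname((ssb / df1) / (ssw / df2))
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' ANOVA channel selection with bilateral completion
#'
#' For each channel and group, a one-way ANOVA across the pitch levels
#' (observations: per-subject pitch means of the analysis-window amplitude,
#' half-2 trials) tests whether mean amplitude differs by pitch. P-values
#' are BH-adjusted across channels within each group; a channel enters the
#' selection if significant in either group. The set is then closed under
#' the bilateral pair map: the 10-20 mirror of every selected lateral
#' channel is added (flagged `symmetric-completion`), so asymmetry tests
#' always have complete pairs. Midline channels have no mirror.
#'
#' A KS normality check is run per channel on the pitch-mean residuals and
#' reported as advisory columns.
#'
#' @param pm_groups Named list of per-group arrays `[subjects x channels x
#'   pitches]` (window already fixed), e.g. `list(MT = ..., NT = ...)`.
#' @param montage The `eeg_montage`.
#' @param alpha Significance level (default 0.05; applied to FDR-adjusted
#'   p-values, `q = alpha`).
#' @return Object of class `channel_selection`: data.frame with one row per
#'   selected channel (`channel`, `origin`, per-group raw and adjusted
#'   p-values); attributes `selected` (labels), `pvalues` (all channels),
#'   `pairs` (complete selected pairs as a data.frame).
#' @export
select_channels <- function(pm_groups, montage, alpha = 0.05) {
  stopifnot(is.list(pm_groups), length(pm_groups) >= 1,
            !is.null(names(pm_groups)))
  channels <- dimnames(pm_groups[[1]])[[2]] %||% montage$channels
  n_ch <- length(channels)
  pv <- data.frame(channel = channels)
  sig_any <- rep(FALSE, n_ch)
  for (g in names(pm_groups)) {
    pm <- pm_groups[[g]]
    if (length(dim(pm)) != 3) stop2("group ", g, ": expected a 3-d array")
    an <- anova_pitch_batch(pm)
    bh <- fdr_bh(an$p, q = alpha)
    ks_p <- vapply(seq_len(n_ch), function(ci) {
      resid <- pm[, ci, ] - rep(colMeans(pm[, ci, , drop = FALSE][, 1, ]),
                                each = dim(pm)[1])
      ks_normality(as.vector(resid))$p
    }, numeric(1))
    pv[[paste0("p_", g)]] <- an$p
    pv[[paste0("p_adj_", g)]] <- bh$p_adj
    pv[[paste0("ks_p_", g)]] <- ks_p
    sig_any <- sig_any | bh$significant
  }
  base <- channels[sig_any]
  added <- setdiff(unname(montage$mirror[base[base %in% names(montage$mirror)]]),
                   base)
  selected <- c(base, added)
  origin <- c(rep("significant", length(base)),
              rep("symmetric-completion", length(added)))
  out <- cbind(data.frame(channel = selected, origin = origin),
               pv[match(selected, pv$channel), -1, drop = FALSE])
  rownames(out) <- NULL
  sel_pairs <- montage$pairs[montage$pairs$left %in% selected &
                               montage$pairs$right %in% selected, ]
  attr(out, "selected") <- selected
  attr(out, "pvalues") <- pv
  attr(out, "pairs") <- sel_pairs
  class(out) <- c("channel_selection", "data.frame")
  out
}

#' Paired left-right amplitude tests per pitch
#'
#' For every selected bilateral pair, pitch, and group: a paired t-test
#' across subjects of the left- vs right-channel mean analysis-window
#' amplitude. P-values are BH-adjusted within group across the (pair x
#' pitch) family.
#'
#' @param pm_groups As in [select_channels()].
#' @param pairs data.frame with `left`, `right` channel columns (e.g. the
#'   `pairs` attribute of a `channel_selection`).
#' @param q FDR level.
#' @return data.frame: group, pair, pitch, mean_diff (left - right), t, p,
#'   p_adj, significant.
#' @export
paired_asymmetry_tests <- function(pm_groups, pairs, q = 0.05) {
  out <- list()
  for (g in names(pm_groups)) {
    pm <- pm_groups[[g]]
    channels <- dimnames(pm)[[2]]
    rows <- list()
    for (k in seq_len(nrow(pairs))) {
      li <- match(pairs$left[k], channels)
      ri <- match(pairs$right[k], channels)
      for (p in seq_len(dim(pm)[3])) {
        l <- pm[, li, p]; r <- pm[, ri, p]
        if (sum(stats::complete.cases(l, r)) < 3) {
          warning("pair ", pair_label(pairs$left[k], pairs$right[k]),
                  " pitch ", p, " group ", g, ": n < 3, skipped")
          next
        }
        if (all(l == r)) {
          tt <- list(statistic = 0, p.value = 1)
        } else {
          tt <- stats::t.test(l, r, paired = TRUE)
        }
        rows[[length(rows) + 1]] <- data.frame(
          group = g, pair = pair_label(pairs$left[k], pairs$right[k]),
          pitch = p, mean_diff = mean(l - r),
          t = unname(tt$statistic), p = tt$p.value)
      }
    }
    tab <- do.call(rbind, rows)
    bh <- fdr_bh(tab$p, q)
    tab$p_adj <- bh$p_adj
    tab$significant <- bh$significant
    out[[g]] <- tab
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit amplitude-vs-pitch regression slopes
#'
#' Ordinary least squares of the mean analysis-window amplitude on the
#' pitch value (coded 1-7 with equal spacing), per subject and channel;
#' each fit uses the subject's 7 per-pitch means. Closed form.
#'
#' @param pm Array `[subjects x channels x pitches]` of half-2 pitch means.
#' @return Object of class `slope_table`: list with `slope` and `intercept`
#'   (subjects x channels matrices) and `channels`.
#' @export
fit_pitch_slopes <- function(pm) {
  stopifnot(length(dim(pm)) == 3)
  k <- dim(pm)[3]
  x <- seq_len(k)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  d <- dim(pm)
  flat <- matrix(pm, d[1] * d[2], d[3])
  slope <- matrix(flat %*% xc / sxx, d[1], d[2])
  intercept <- matrix(rowMeans(flat), d[1], d[2]) - slope * mean(x)
  channels <- dimnames(pm)[[2]]
  colnames(slope) <- channels
  colnames(intercept) <- channels
  structure(list(slope = slope, intercept = intercept, channels = channels),
            class = "slope_table")
}

#' One-sample tests of slopes against zero
#'
#' Per channel: one-sample t-test of per-subject slopes against 0, with BH
#' adjustment across channels; the sign of the group-mean slope is
#' reported.
#'
#' @param slopes A `slope_table` (>= 3 subjects).
#' @param q FDR level.
#' @return data.frame: channel, mean_slope, sign, t, p, p_adj, significant.
#' @export
test_slopes_nonzero <- function(slopes, q = 0.05) {
  stopifnot(inherits(slopes, "slope_table"), nrow(slopes$slope) >= 3)
  res <- apply(slopes$slope, 2, function(b) {
    if (stats::sd(b) == 0 && mean(b) == 0) c(0, 1)
    else { tt <- stats::t.test(b); c(unname(tt$statistic), tt$p.value) }
  })
  tab <- data.frame(channel = slopes$channels,
                    mean_slope = colMeans(slopes$slope),
                    sign = sign(colMeans(slopes$slope)),
                    t = res[1, ], p = res[2, ])
  bh <- fdr_bh(tab$p, q)
  tab$p_adj <- bh$p_adj
  tab$significant <- bh$significant
  rownames(tab) <- NULL
  tab
}

# Per-subject hemispheric asymmetry (right - left slope) for given pairs.
pair_asymmetry <- function(slopes, pairs) {
  a <- sapply(seq_len(nrow(pairs)), function(k)
    slopes$slope[, pairs$right[k]] - slopes$slope[, pairs$left[k]])
  colnames(a) <- pair_label(pairs$left, pairs$right)
  a
}

#' Frontal vs parietal asymmetry contrast
#'
#' For each coronal-plane match (F7-F8 vs P7-P8, FC5-FC6 vs CP5-CP6, F3-F4
#' vs P3-P4, FC1-FC2 vs CP1-CP2): the per-subject bilateral slope
#' difference (right minus left) of the frontal pair is compared with its
#' parietal counterpart by a Wilcoxon signed-rank test across subjects,
#' BH-adjusted over the 4 matches.
#'
#' @param slopes A `slope_table` for one group.
#' @param montage The `eeg_montage` (provides the pair sets and matching).
#' @param q FDR level.
#' @return data.frame: frontal, parietal, mean_frontal, mean_parietal, V,
#'   p, p_adj, significant.
#' @export
region_asymmetry_compare <- function(slopes, montage, q = 0.05) {
  rm_ <- montage$region_match
  rows <- lapply(seq_len(nrow(rm_)), function(k) {
    fl <- split_pair(rm_$frontal[k]); pl <- split_pair(rm_$parietal[k])
    fa <- slopes$slope[, fl[2]] - slopes$slope[, fl[1]]
    pa <- slopes$slope[, pl[2]] - slopes$slope[, pl[1]]
    if (all(fa == pa)) {
      wt <- list(statistic = NA_real_, p.value = 1)
    } else {
      wt <- suppressWarnings(stats::wilcox.test(fa, pa, paired = TRUE))
    }
    data.frame(frontal = rm_$frontal[k], parietal = rm_$parietal[k],
               mean_frontal = mean(fa), mean_parietal = mean(pa),
               V = unname(wt$statistic), p = wt$p.value)
  })
  tab <- do.call(rbind, rows)
  bh <- fdr_bh(tab$p, q)
  tab$p_adj <- bh$p_adj
  tab$significant <- bh$significant
  tab
}

#' Compare slope steepness between groups
#'
#' Per channel: Welch two-sample t-test of the absolute slope (steepness)
#' between groups, BH-adjusted across channels; the direction of the raw
#' group difference is also reported so a consistent "stiffer in one
#' group" pattern is visible even when nothing survives FDR.
#'
#' @param slopes_a,slopes_b `slope_table`s for the two groups (>= 3
#'   subjects each); conventionally a = MT, b = NT.
#' @param q FDR level.
#' @return data.frame: channel, mean_abs_a, mean_abs_b, stiffer (sign of
#'   a - b in steepness), t, p, p_adj, significant.
#' @export
compare_groups_slopes <- function(slopes_a, slopes_b, q = 0.05) {
  stopifnot(inherits(slopes_a, "slope_table"), inherits(slopes_b, "slope_table"),
            nrow(slopes_a$slope) >= 3, nrow(slopes_b$slope) >= 3)
  res <- vapply(seq_along(slopes_a$channels), function(ci) {
    a <- abs(slopes_a$slope[, ci]); b <- abs(slopes_b$slope[, ci])
    if (stats::sd(c(a, b)) == 0) return(c(0, 1))
    tt <- stats::t.test(a, b)
    c(unname(tt$statistic), tt$p.value)
  }, numeric(2))
  tab <- data.frame(channel = slopes_a$channels,
                    mean_abs_a = colMeans(abs(slopes_a$slope)),
                    mean_abs_b = colMeans(abs(slopes_b$slope)))
  tab$stiffer <- sign(tab$mean_abs_a - tab$mean_abs_b)
  tab$t <- res[1, ]
  tab$p <- res[2, ]
  bh <- fdr_bh(tab$p, q)
  tab$p_adj <- bh$p_adj
  tab$significant <- bh$significant
  rownames(tab) <- NULL
  tab
}

#' Earliest pitch-discriminative window
#'
#' Scans the sliding windows in ascending start time; in each window a
#' one-way ANOVA across pitches (per-subject pitch means, half-2 trials)
#' is run for every selected channel and BH-adjusted across those
#' channels. Returns the start (ms) of the first window in which a strict
#' majority of the selected channels is significant, or `NA` ("none") if
#' no window qualifies.
#'
#' @param pm_all Array `[subjects x channels x windows x pitches]` for one
#'   group (all windows), with channel dimnames.
#' @param selection A `channel_selection` (or character vector of
#'   channels); must be non-empty unless `allow_empty`.
#' @param starts Window start times (ms) matching the window dimension.
#' @param alpha FDR level for the per-window channel family.
#' @param allow_empty If TRUE an empty selection returns `NA` rather than
#'   erroring (a no-selection run is trivially non-discriminative).
#' @return Start time in ms, or `NA_real_` for "none".
#' @export
earliest_discriminative_window <- function(pm_all, selection,
                                           starts = seq(0, 700, 10),
                                           alpha = 0.05,
                                           allow_empty = FALSE) {
  sel <- if (inherits(selection, "channel_selection"))
    attr(selection, "selected") else selection
  if (length(sel) == 0) {
    if (allow_empty) return(NA_real_)
    stop2("empty channel selection")
  }
  channels <- dimnames(pm_all)[[2]]
  ci <- match(sel, channels)
  if (anyNA(ci)) stop2("selection channels missing from the data")
  d <- dim(pm_all)
  sub <- pm_all[, ci, , , drop = FALSE]
  # collapse (channel, window) into the cell dimension for one batch ANOVA
  pm <- array(sub, c(d[1], length(ci) * d[3], d[4]))
  an <- anova_pitch_batch(pm)
  pmat <- matrix(an$p, length(ci), d[3])           # channels x windows
  for (w in seq_len(d[3])) {
    bh <- fdr_bh(pmat[, w], q = alpha)
    if (sum(bh$significant) > length(ci) / 2) return(starts[w])
  }
  NA_real_
}

#' Exact Wilcoxon rank-sum test of behavioral counts
#'
#' Two-sample rank-sum comparison of correct-block counts. Because counts
#' are small integers, ties are ubiquitous and the usual normal
#' approximation is materially conservative at n = 10 per group; the exact
#' conditional null distribution of the rank sum (given the observed tied
#' ranks) is therefore computed by dynamic programming whenever the total
#' sample is small (`<= exact_max`), and the two-sided exact p-value
#' reported.
#'
#' @param counts_a,counts_b Integer vectors of per-subject counts (>= 3
#'   each).
#' @param exact_max Largest total n for the exact enumeration (default 40).
#' @return data.frame: n_a, n_b, mean_a, sd_a, mean_b, sd_b, W (rank sum of
#'   sample a), U, p, method.
#' @export
behavior_test <- function(counts_a, counts_b, exact_max = 40) {
  na <- length(counts_a); nb <- length(counts_b)
  stopifnot(na >= 3, nb >= 3)
  r <- rank(c(counts_a, counts_b))
  w_obs <- sum(r[seq_len(na)])
  if (na + nb <= exact_max) {
    p <- rank_sum_exact_p(r, na, w_obs)
    method <- "exact"
  } else {
    wt <- suppressWarnings(stats::wilcox.test(counts_a, counts_b))
    p <- wt$p.value
    method <- "normal approximation"
  }
  data.frame(n_a = na, n_b = nb,
             mean_a = mean(counts_a), sd_a = stats::sd(counts_a),
             mean_b = mean(counts_b), sd_b = stats::sd(counts_b),
             W = w_obs, U = w_obs - na * (na + 1) / 2, p = p,
             method = method)
}

# Exact two-sided p of the rank sum under random assignment of the
# observed (tied) ranks; DP over subsets of size na.
rank_sum_exact_p <- function(r, na, w_obs) {
  r2 <- as.integer(round(2 * r))                  # half-ranks -> integers
  n <- length(r2)
  smax <- sum(r2)
  # f[k+1, s+1] = number of k-subsets with doubled-rank sum s
  f <- matrix(0, na + 1, smax + 1)
  f[1, 1] <- 1
  for (v in r2) {
    kmax <- min(na, n)
    for (k in kmax:1) {
      nz <- which(f[k, ] > 0)
      if (length(nz)) {
        tgt <- nz + v
        f[k + 1, tgt] <- f[k + 1, tgt] + f[k, nz]
      }
    }
  }
  dist <- f[na + 1, ]
  tot <- sum(dist)
  w2 <- as.integer(round(2 * w_obs))
  p_le <- sum(dist[seq_len(w2 + 1)]) / tot
  p_ge <- sum(dist[(w2 + 1):(smax + 1)]) / tot
  min(1, 2 * min(p_le, p_ge))
}

#' Correlate behavioral counts with slopes across participants
#'
#' Pearson correlation (per channel, BH-adjusted across channels) between
#' per-subject correct-block counts and amplitude-vs-pitch slopes, pooled
#' over all participants.
#'
#' @param counts Integer vector (one per participant, both groups pooled).
#' @param slopes A `slope_table` whose rows align with `counts`.
#' @param q FDR level.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return data.frame: channel, r, p, p_adj, significant.
#' @export
correlate_behavior_slopes <- function(counts, slopes, q = 0.05,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(slopes, "slope_table"),
            length(counts) == nrow(slopes$slope))
  res <- vapply(seq_along(slopes$channels), function(ci) {
    ct <- suppressWarnings(
      stats::cor.test(counts, slopes$slope[, ci], method = method))
    c(unname(ct$estimate), ct$p.value)
  }, numeric(2))
  tab <- data.frame(channel = slopes$channels, r = res[1, ], p = res[2, ])
  bh <- fdr_bh(tab$p, q)
  tab$p_adj <- bh$p_adj
  tab$significant <- bh$significant
  rownames(tab) <- NULL
  tab
}
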