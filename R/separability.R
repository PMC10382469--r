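#' Sliding-window mean amplitudes
#'
#' Computes, for every trial and channel, the mean amplitude in each
#' 100 ms analysis window `[start, start + width)` for starts stepping by
#' 10 ms over the epoch (71 windows for a 0-700 ms start range). This is
#' the quantity all window-based statistics operate on.
#'
#' @param epochs An `erp_epochs`.
#' @param starts Window start times in ms (default `seq(0, 700, 10)`).
#' @param width Window length in ms (default 100).
#' @return Object of class `window_amps`: list with `amps` (array channels
#'   x windows x trials), `starts`, `width`, `channels`, `meta` (the epoch
#'   metadata).
#' @export
window_amplitudes <- function(epochs, starts = seq(0, 700, 10), width = 100) {
  stopifnot(inherits(epochs, "erp_epochs"))
  arr <- epochs$data
  d <- dim(arr)                        # ch, time, trials
  step_ms <- 1000 / epochs$srate
  s_idx <- match(starts, epochs$times)
  if (anyNA(s_idx)) stop2("window start(s) outside epoch time axis")
  wlen <- round(width / step_ms)
  if (max(s_idx) + wlen - 1 > d[2])
    stop2("window(s) extend beyond the epoch")

  m <- matrix(aperm(arr, c(2, 1, 3)), nrow = d[2])   # time x (ch*tr)
  g <- matrix(cumsum(m), nrow = d[2])
  off <- c(0, g[d[2], -ncol(g)])
  cs0 <- rbind(0, g - rep(off, each = d[2]))         # (time+1) x (ch*tr)
  sums <- cs0[s_idx + wlen, , drop = FALSE] - cs0[s_idx, , drop = FALSE]
  amps <- aperm(array(sums / wlen, dim = c(length(starts), d[1], d[3])),
                c(2, 1, 3))
  structure(list(amps = amps, starts = starts, width = width,
                 channels = epochs$channels, meta = epochs$meta),
            class = "window_amps")
}

#' Separability of per-pitch amplitude groups
#'
#' The cluster-separation statistic used to pick the analysis window: for
#' K groups of window-mean amplitudes (one group per pitch), the average
#' over all K(K-1)/2 group pairs of the absolute difference of group
#' medians divided by the sum of group standard deviations (sample SD,
#' denominator n - 1):
#' \deqn{S = \frac{1}{C(K,2)} \sum_{i<j} \frac{|c_i - c_j|}{\sigma_i + \sigma_j}}
#' a Davies-Bouldin-style ratio of inter-pitch distance to intra-pitch
#' dispersion. The score is invariant to common shifts and positive
#' rescalings of the amplitudes and to relabelling of the groups.
#'
#' A pair whose pooled dispersion is zero but whose medians differ has an
#' undefined ratio; such pairs are skipped with a warning and the
#' normaliser reduced accordingly.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return A single non-negative number.
#' @examples
#' separability_score(list(c(0, 1, 2), c(4, 5, 6)))  # |5-1|/(1+1) = 2
#' @export
separability_score <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(vapply(groups, length, 1L) < 2))
    stop2("every group needs at least 2 values for a sample SD")
  meds <- vapply(groups, stats::median, numeric(1))
  sds <- vapply(groups, stats::sd, numeric(1))
  k <- length(groups)
  tot <- 0
  n_valid <- 0L
  n_skip <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      d <- abs(meds[i] - meds[j])
      s <- sds[i] + sds[j]
      if (s == 0) {
        if (d == 0) { n_valid <- n_valid + 1L } else { n_skip <- n_skip + 1L }
      } else {
        tot <- tot + d / s
        n_valid <- n_valid + 1L
      }
    }
  }
  if (n_skip > 0)
    warning(n_skip, " pair(s) with zero pooled SD skipped; ",
            "normaliser reduced to ", n_valid)
  if (n_valid == 0) return(NaN)
  unname(tot) / n_valid
}

# --- vectorised batch machinery -------------------------------------------

# Row-wise medians and sample SDs for a matrix (rows = channel-window
# cells, cols = trials of one pitch).
row_med_sd <- function(x) {
  r <- nrow(x); n <- ncol(x)
  o <- order(row(x), x)
  s <- matrix(x[o], nrow = r, byrow = TRUE)
  med <- if (n %% 2 == 1) s[, (n + 1) %/% 2]
         else (s[, n %/% 2] + s[, n %/% 2 + 1]) / 2
  mu <- rowMeans(x)
  sd <- sqrt(pmax(rowSums((x - mu)^2), 0) / (n - 1))
  list(med = med, sd = sd)
}

# Per-(channel, window) separability scores for one subject.
# amps: ch x win x trials; groups: list of trial indices per pitch.
batch_separability <- function(amps, groups) {
  d <- dim(amps)
  r <- d[1] * d[2]
  k <- length(groups)
  meds <- matrix(0, r, k)
  sds <- matrix(0, r, k)
  for (g in seq_len(k)) {
    x <- matrix(amps[, , groups[[g]], drop = FALSE], nrow = r)
    ms <- row_med_sd(x)
    meds[, g] <- ms$med
    sds[, g] <- ms$sd
  }
  tot <- matrix(0, r, 1)
  nv <- matrix(0L, r, 1)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      dd <- abs(meds[, i] - meds[, j])
      ss <- sds[, i] + sds[, j]
      valid <- ss > 0 | dd == 0
      ratio <- ifelse(ss > 0, dd / ss, 0)
      tot <- tot + ifelse(valid, ratio, 0)
      nv <- nv + valid
    }
  }
  matrix(ifelse(nv > 0, tot / nv, NaN), d[1], d[2])
}

trial_groups <- function(meta, half = NULL, n_pitches = 7) {
  sel <- !meta$is_target
  if (!is.null(half)) sel <- sel & !is.na(meta$half) & meta$half == half
  lapply(seq_len(n_pitches), function(p) which(sel & meta$pitch == p))
}

#' Scan sliding windows for pitch separability
#'
#' Computes the separability curve over all window starts: per subject and
#' channel, trial window-mean amplitudes of the chosen trial half are
#' grouped by pitch and scored with [separability_score()]'s statistic
#' (vectorised); scores are averaged over channels within subject, and the
#' curve reports the across-subject mean with its standard error.
#'
#' Only half-1 (chronologically earlier) non-target trials feed the scan by
#' default, reserving half 2 for inference (anti-double-dipping split).
#'
#' @param subjects A `window_amps` object or a list of them (one per
#'   subject).
#' @param half Which trial half to use (default 1).
#' @return Object of class `separability_curve`: data.frame with columns
#'   `window_start`, `score`, `sem`; attribute `by_subject` holds the
#'   subject x window score matrix.
#' @export
scan_windows <- function(subjects, half = 1) {
  if (inherits(subjects, "window_amps")) subjects <- list(subjects)
  stopifnot(length(subjects) >= 1,
            all(vapply(subjects, inherits, TRUE, "window_amps")))
  starts <- subjects[[1]]$starts
  per_subj <- matrix(NA_real_, length(subjects), length(starts))
  for (s in seq_along(subjects)) {
    wa <- subjects[[s]]
    groups <- trial_groups(wa$meta, half = half)
    sizes <- lengths(groups)
    if (any(sizes < 2))
      stop2("pitch ", paste(which(sizes < 2), collapse = ", "),
            ": fewer than 2 half-", half, " trials for subject ", s)
    sc <- batch_separability(wa$amps, groups)
    per_subj[s, ] <- colMeans(sc)
  }
  curve <- data.frame(window_start = starts,
                      score = colMeans(per_subj),
                      sem = apply(per_subj, 2, stats::sd) /
                        sqrt(nrow(per_subj)))
  attr(curve, "by_subject") <- per_subj
  attr(curve, "width") <- subjects[[1]]$width
  class(curve) <- c("separability_curve", "data.frame")
  curve
}

#' Select the analysis window from a separability curve
#'
#' Returns the window with the maximal separability score; ties are broken
#' toward the earliest start (with a message).
#'
#' @param curve A `separability_curve`.
#' @return List with `start_ms`, `end_ms`, `index`, `score`.
#' @export
select_window <- function(curve) {
  stopifnot(nrow(curve) >= 1)
  mx <- max(curve$score)
  idx <- which(curve$score == mx)
  if (length(idx) > 1)
    message("separability tie between ", length(idx),
            " windows; earliest start selected")
  i <- idx[1]
  width <- attr(curve, "width") %||% 100
  list(start_ms = curve$window_start[i],
       end_ms = curve$window_start[i] + width,
       index = i, score = curve$score[i])
}
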