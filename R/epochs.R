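#' Epoch a continuous recording and label analysis trials
#'
#' Cuts epochs at `[-100, 800)` ms around each stimulus onset (450 samples
#' at 500 Hz, half-open convention, t = 0 at the onset sample), optionally
#' baseline-corrects each trial/channel by the mean of the `[-100, 0)` ms
#' pre-stimulus interval, marks trials whose pitch equals the block target
#' (`is_target`; these are excluded from all analyses), and assigns each
#' subject's non-target trials of each pitch a chronological half label
#' (half 1 = earliest 50%, used for window selection; half 2 = the rest,
#' used for inference).
#'
#' Trials too close to the record edge are dropped with a warning.
#'
#' @param rec An `eeg_recording` with events.
#' @param tmin,tmax Epoch limits in seconds (default -0.1, 0.8; half-open).
#' @param baseline Apply pre-stimulus baseline correction (default TRUE).
#' @return Object of class `erp_epochs`: list with `data` (array channels x
#'   time x trials, microvolts), `times` (ms), `channels`, `srate`, and
#'   `meta` (data.frame: pitch, block, target_pitch, is_target, half; half
#'   is NA for target trials).
#' @export
epoch_and_filter <- function(rec, tmin = -0.1, tmax = 0.8, baseline = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$events) > 0)
  srate <- rec$srate
  o0 <- round(tmin * srate)            # -50
  o1 <- round(tmax * srate) - 1L       # 399 (half-open upper edge)
  offsets <- o0:o1
  n_t <- length(offsets)
  n <- ncol(rec$data)

  ev <- rec$events
  ok <- ev$onset_sample + o0 >= 1 & ev$onset_sample + o1 <= n
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) too close to the record edge; dropped")
    ev <- ev[ok, , drop = FALSE]
  }
  n_tr <- nrow(ev)
  idx <- outer(offsets, ev$onset_sample, "+")      # n_t x n_tr
  dat <- rec$data[, as.vector(idx), drop = FALSE]  # ch x (n_t * n_tr)
  arr <- array(dat, dim = c(nrow(dat), n_t, n_tr))

  if (baseline) {
    nb <- sum(offsets < 0)
    bl <- arr[, seq_len(nb), , drop = FALSE]
    bl_mean <- colMeans(aperm(bl, c(2, 1, 3)))     # ch x n_tr
    ap <- aperm(arr, c(1, 3, 2))                   # ch x n_tr x n_t
    ap <- ap - as.vector(bl_mean)                  # recycled over time
    arr <- aperm(ap, c(1, 3, 2))
  }

  meta <- label_trials(ev)

  structure(list(data = arr, times = offsets / srate * 1000,
                 channels = rec$channels, srate = srate, meta = meta),
            class = "erp_epochs")
}

# Trial metadata: target marking and the chronological half split of each
# pitch's non-target trials (half 1 = earliest 50%, rounded up).
label_trials <- function(ev) {
  meta <- data.frame(pitch = ev$pitch, block = ev$block,
                     target_pitch = ev$target_pitch,
                     is_target = ev$pitch == ev$target_pitch)
  meta$half <- NA_integer_
  for (p in sort(unique(meta$pitch))) {
    sel <- which(!meta$is_target & meta$pitch == p)
    if (length(sel)) {
      h1 <- sel[seq_len(ceiling(length(sel) / 2))]
      meta$half[sel] <- 2L
      meta$half[h1] <- 1L
    }
  }
  meta
}

# Fast path equivalent to epoch_and_filter() + window_amplitudes() computed
# straight from the continuous record by channel-wise cumulative sums
# (used when no preprocessing stage is active; asserted equal to the epoch
# path in the test suite).
continuous_window_amps <- function(rec, starts = seq(0, 700, 10),
                                   width = 100, baseline = TRUE,
                                   tmin = -0.1, tmax = 0.8) {
  srate <- rec$srate
  n <- ncol(rec$data)
  o0 <- round(tmin * srate)
  o1 <- round(tmax * srate) - 1L
  nb <- -o0
  ev <- rec$events
  ok <- ev$onset_sample + o0 >= 1 & ev$onset_sample + o1 <= n
  if (!all(ok)) {
    warning(sum(!ok), " trial(s) too close to the record edge; dropped")
    ev <- ev[ok, , drop = FALSE]
  }
  n_tr <- nrow(ev)
  n_ch <- nrow(rec$data)
  xt <- t(rec$data)
  g <- matrix(cumsum(xt), n)
  off <- c(0, g[n, -n_ch])
  cs0 <- rbind(0, g - rep(off, each = n))        # cs0[k+1, c] = sum first k

  wlen <- round(width / 1000 * srate)
  s_off <- round(starts / 1000 * srate)
  a <- as.vector(outer(ev$onset_sample, s_off, "+"))   # trial-fastest
  means <- (cs0[a + wlen, , drop = FALSE] - cs0[a, , drop = FALSE]) / wlen
  if (baseline) {
    bl <- (cs0[ev$onset_sample, , drop = FALSE] -
             cs0[ev$onset_sample - nb, , drop = FALSE]) / nb
    means <- means - bl[rep(seq_len(n_tr), length(s_off)), , drop = FALSE]
  }
  amps <- aperm(array(t(means), c(n_ch, n_tr, length(s_off))), c(1, 3, 2))
  structure(list(amps = amps, starts = starts, width = width,
                 channels = rec$channels, meta = label_trials(ev)),
            class = "window_amps")
}

#' @export
print.erp_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<erp_epochs> ", d[3], " trials x ", d[1], " channels x ", d[2],
      " samples [", min(x$times), ", ", max(x$times) + 1000 / x$srate,
      ") ms\n", sep = "")
  invisible(x)
}
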