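#' Artifact subspace reconstruction (calibrated subspace variant)
#'
#' Removes high-amplitude transient artifacts by sliding-window principal
#' component analysis against calibration statistics. Calibration data are
#' chosen deterministically as the quietest 1-second chunks of the record
#' (lowest aggregate RMS, `calib_frac` of all chunks) and summarised by
#' their channel covariance. In each Hann-weighted analysis window the
#' window covariance is eigendecomposed; a component is flagged when its
#' amplitude (root eigenvalue) exceeds `cutoff` times the calibration
#' standard deviation projected onto that component's direction, and the
#' window is reconstructed from the retained subspace. Windows are
#' recombined by overlap-add, so untouched data pass through unchanged (a
#' very large `cutoff` makes the operation an identity).
#'
#' This is a simplified subspace-reconstruction variant: the method is used
#' here as a black-box burst remover with the conventional cutoff of 30,
#' and the implementation omits the Riemannian/geometric-median refinements
#' of published reference code.
#'
#' @param rec An `eeg_recording` of at least 30 s.
#' @param cutoff Threshold in calibration standard deviations (default 30).
#' @param window_sec Analysis window length in seconds (default 0.5).
#' @param calib_frac Fraction of quietest chunks used for calibration
#'   (default 0.6).
#' @return The cleaned `eeg_recording`.
#' @export
asr_clean <- function(rec, cutoff = 30, window_sec = 0.5, calib_frac = 0.6) {
  stopifnot(inherits(rec, "eeg_recording"), cutoff > 0)
  srate <- rec$srate
  n <- ncol(rec$data)
  if (n < 30 * srate)
    stop2("record shorter than 30 s: too little data to calibrate ASR; ",
          "bypass this stage instead")
  x <- rec$data
  n_ch <- nrow(x)

  # --- calibration: quietest 1 s chunks by aggregate RMS
  chunk <- srate
  n_chunks <- n %/% chunk
  idx <- seq_len(n_chunks * chunk)
  xs <- x[, idx, drop = FALSE]
  cs <- matrix(colSums(xs^2), nrow = chunk)        # per-sample, per-chunk
  chunk_rms <- sqrt(colMeans(cs))
  keep_chunks <- order(chunk_rms)[seq_len(max(2, floor(calib_frac * n_chunks)))]
  calib_idx <- as.vector(outer(seq_len(chunk), (keep_chunks - 1) * chunk, "+"))
  calib <- x[, calib_idx, drop = FALSE]
  cv <- tcrossprod(calib) / ncol(calib)

  # --- sliding Hann windows, 50% overlap, overlap-add
  win <- round(window_sec * srate)
  if (win %% 2 == 1) win <- win + 1
  hop <- win %/% 2
  w <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 0.5) / win)
  starts <- seq(1, n - win + 1, by = hop)
  if (utils::tail(starts, 1) + win - 1 < n)
    starts <- c(starts, n - win + 1)
  out <- matrix(0, n_ch, n)
  wsum <- numeric(n)
  for (s in starts) {
    cols <- s:(s + win - 1)
    xw <- x[, cols, drop = FALSE]
    eg <- eigen(tcrossprod(xw) / win, symmetric = TRUE)
    amp <- sqrt(pmax(eg$values, 0))          # per-component RMS amplitude
    calib_sd <- sqrt(pmax(colSums(eg$vectors * (cv %*% eg$vectors)), 1e-12))
    bad <- amp > cutoff * calib_sd
    if (any(bad)) {
      vk <- eg$vectors[, !bad, drop = FALSE]
      xr <- vk %*% crossprod(vk, xw)
    } else xr <- xw
    out[, cols] <- out[, cols] + xr * rep(w, each = n_ch)
    wsum[cols] <- wsum[cols] + w
  }
  ok <- wsum > 1e-12
  out[, ok] <- out[, ok] / rep(wsum[ok], each = n_ch)
  out[, !ok] <- x[, !ok]
  rec$data <- out
  rownames(rec$data) <- rec$channels
  rec
}
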