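#' Detect bad channels by pairwise correlation
#'
#' Flags a channel as bad when more than `frac_threshold` (70%) of all
#' other channels show a zero-lag Pearson correlation below
#' `corr_threshold` (0.4) with it over the whole (filtered) record. A
#' zero-variance channel has its correlations defined as 0 (with a warning)
#' and is therefore flagged.
#'
#' @param rec An `eeg_recording` (at least 3 channels).
#' @param corr_threshold Correlation cutoff (default 0.4).
#' @param frac_threshold Fraction of low-correlation partners above which a
#'   channel is flagged (default 0.7, strict inequality).
#' @return Object of class `bad_channel_report`: data.frame with columns
#'   `channel`, `low_corr_fraction`, `flagged`, plus attribute `flagged`
#'   (character vector of bad-channel labels).
#' @export
detect_bad_channels <- function(rec, corr_threshold = 0.4,
                                frac_threshold = 0.7) {
  stopifnot(inherits(rec, "eeg_recording"), nrow(rec$data) >= 3)
  sds <- apply(rec$data, 1, stats::sd)
  if (any(sds == 0))
    warning("zero-variance channel(s): ",
            paste(rec$channels[sds == 0], collapse = ", "),
            "; correlations set to 0")
  cc <- suppressWarnings(stats::cor(t(rec$data)))
  cc[!is.finite(cc)] <- 0
  n_ch <- nrow(cc)
  frac <- vapply(seq_len(n_ch), function(i)
    mean(cc[i, -i] < corr_threshold), numeric(1))
  flagged <- frac > frac_threshold
  rep <- data.frame(channel = rec$channels, low_corr_fraction = frac,
                    flagged = flagged)
  attr(rep, "flagged") <- rec$channels[flagged]
  class(rep) <- c("bad_channel_report", "data.frame")
  rep
}

#' Interpolate channels by spherical splines
#'
#' Replaces the listed channels with Perrin-style spherical-spline
#' estimates (order m = 4, 50 Legendre terms) computed from the remaining
#' good channels. Good channels are untouched.
#'
#' @param rec An `eeg_recording`.
#' @param montage The `eeg_montage` providing electrode positions.
#' @param bad Character vector of channel labels to rebuild (at least 4
#'   good channels must remain).
#' @return The `eeg_recording` with interpolated channels.
#' @export
interpolate_channels <- function(rec, montage, bad) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0) return(rec)
  if (!all(bad %in% montage$channels))
    stop2("unknown channel(s): ",
          paste(setdiff(bad, montage$channels), collapse = ", "))
  good <- setdiff(rec$channels, bad)
  if (length(good) < 4) stop2("fewer than 4 good channels remain")
  gi <- match(good, montage$channels)
  bi <- match(bad, montage$channels)
  op <- spline_interp_operator(montage$positions[gi, , drop = FALSE],
                               montage$positions[bi, , drop = FALSE])
  rec$data[match(bad, rec$channels), ] <-
    op %*% rec$data[match(good, rec$channels), , drop = FALSE]
  rec
}
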