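#' Line-noise and band filtering
#'
#' Removes 60 Hz line noise with a second-order IIR notch (quality factor
#' Q = f0 / bandwidth = 30 by default) and band-limits the signal with a
#' Butterworth high-pass (order 4) / low-pass (order 6) pair. All filters
#' are applied forward-backward (`signal::filtfilt`) for zero phase, so
#' event-locked averages acquire no group delay; the low-pass order is
#' chosen so that after the magnitude squaring of the two-pass filter the
#' passband (5-40 Hz) is still preserved within +/- 1 dB, while the 60 Hz
#' component is attenuated by more than 30 dB.
#'
#' @param rec An `eeg_recording`.
#' @param notch_freq Line frequency in Hz (default 60).
#' @param notch_bw Notch bandwidth in Hz (default 2).
#' @param band `c(low, high)` band edges in Hz (default `c(1, 50)`).
#' @return The filtered `eeg_recording`.
#' @export
filter_line_and_band <- function(rec, notch_freq = 60, notch_bw = 2,
                                 band = c(1, 50)) {
  stopifnot(inherits(rec, "eeg_recording"))
  srate <- rec$srate
  n <- ncol(rec$data)
  # the 1 Hz high-pass dominates the impulse-response length (~1 s)
  if (n < 3 * srate)
    stop2("record too short to filter: ", n / srate,
          " s (< 3x the longest filter impulse response)")

  nt <- design_notch(notch_freq, notch_bw, srate)
  hp <- signal::butter(4, band[1] / (srate / 2), type = "high")
  lp <- signal::butter(6, band[2] / (srate / 2), type = "low")

  for (i in seq_len(nrow(rec$data))) {
    x <- rec$data[i, ]
    x <- signal::filtfilt(nt$b, nt$a, x)
    x <- signal::filtfilt(hp, x)
    x <- signal::filtfilt(lp, x)
    rec$data[i, ] <- x
  }
  rec
}

# RBJ-cookbook biquad notch at f0 with bandwidth bw (Hz).
design_notch <- function(f0, bw, srate) {
  w0 <- 2 * pi * f0 / srate
  q <- f0 / bw
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}
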