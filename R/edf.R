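#' Write a recording to EDF with event and ground-truth sidecars
#'
#' Serialises a continuous recording as a standard 16-bit EDF file
#' (one 1-second data record per signal per second, physical units
#' microvolts), an events TSV sidecar (`<path>_events.tsv` with header
#' `onset_sample  pitch  block  target_pitch`), and optionally a
#' ground-truth JSON (`<path>_truth.json`). The record is zero-padded to a
#' whole number of seconds. Amplitudes round-trip within one 16-bit
#' quantisation step of the per-channel physical range.
#'
#' @param rec An `eeg_recording`.
#' @param path Output path for the EDF file (typically ending `.edf`).
#' @param truth Optional `ground_truth` to serialise alongside.
#' @return Invisibly, the EDF path.
#' @seealso [read_recording()]
#' @export
write_recording <- function(rec, path, truth = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ch <- nrow(rec$data)
  if (n_ch != length(rec$channels))
    stop2("channel count mismatch between data and channel names")
  srate <- rec$srate
  n <- ncol(rec$data)
  n_rec <- ceiling(n / srate)
  data <- rec$data
  if (n_rec * srate > n)
    data <- cbind(data, matrix(0, n_ch, n_rec * srate - n))

  pmin_ <- apply(data, 1, min)
  pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1
  pmax_[flat] <- pmax_[flat] + 1
  dmin <- -32768; dmax <- 32767

  pad <- function(x, w) formatC(as.character(x), width = w, flag = "-")
  # numeric header fields are 8 ASCII chars; use as many significant digits
  # as fit
  fmt8 <- function(x) {
    vapply(x, function(v) {
      for (d in 7:1) {
        s <- formatC(v, format = "g", digits = d)
        if (nchar(s) <= 8) return(s)
      }
      stop2("cannot format ", v, " into an 8-char EDF field")
    }, character(1))
  }
  num <- function(x, w) pad(fmt8(x), w)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad("0", 8), con, eos = NULL)
  writeChar(pad("X X X X", 80), con, eos = NULL)               # patient id
  writeChar(pad("Startdate X X X X", 80), con, eos = NULL)     # recording id
  writeChar(pad("01.01.26", 8), con, eos = NULL)
  writeChar(pad("00.00.00", 8), con, eos = NULL)
  writeChar(pad(256 * (1 + n_ch), 8), con, eos = NULL)
  writeChar(pad("", 44), con, eos = NULL)
  writeChar(pad(n_rec, 8), con, eos = NULL)
  writeChar(pad("1", 8), con, eos = NULL)                      # 1 s records
  writeChar(pad(n_ch, 4), con, eos = NULL)
  for (ch in rec$channels) writeChar(pad(ch, 16), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad("AgAgCl electrode", 80), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad("uV", 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(num(pmin_[i], 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(num(pmax_[i], 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad(dmin, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad(dmax, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad("", 80), con, eos = NULL)  # prefilter
  for (i in seq_len(n_ch)) writeChar(pad(srate, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad("", 32), con, eos = NULL)

  # re-read the headers exactly as written so scaling is lossless w.r.t.
  # the 7-significant-digit physical min/max fields
  pmin_w <- as.numeric(fmt8(pmin_))
  pmax_w <- as.numeric(fmt8(pmax_))
  gain <- (pmax_w - pmin_w) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * srate + 1):(r * srate)
    for (i in seq_len(n_ch)) {
      dig <- round((data[i, idx] - pmin_w[i]) / gain[i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }

  ev_path <- sub("\\.edf$", "", path)
  utils::write.table(rec$events, paste0(ev_path, "_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(effect_window = truth$effect_window,
           slope_map = as.list(truth$slope_map),
           noise_sd = truth$noise_sd, common_mode = truth$common_mode,
           bad_channels = truth$bad_channels),
      paste0(ev_path, "_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' Parses the EDF header and 16-bit data records back into an
#' `eeg_recording`, restoring events from the TSV sidecar (an explicit
#' error is raised if the sidecar is missing).
#'
#' @param path Path to the EDF file.
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop2("no such EDF file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  rd(8)                                   # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  channels <- vapply(seq_len(n_ch), function(i) rd(16), character(1))
  for (i in seq_len(n_ch)) rd(80)
  units <- vapply(seq_len(n_ch), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  for (i in seq_len(n_ch)) rd(80)
  ns <- as.integer(vapply(seq_len(n_ch), function(i) rd(8), character(1)))
  for (i in seq_len(n_ch)) rd(32)

  srate <- ns[1] / rec_dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, n_ch, n_rec * ns[1])
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_ch)) {
      dig <- readBin(con, integer(), n = ns[i], size = 2, signed = TRUE,
                     endian = "little")
      data[i, ((r - 1) * ns[i] + 1):(r * ns[i])] <-
        (dig - dmin[i]) * gain[i] + pmin_[i]
    }
  }
  rownames(data) <- channels

  ev_path <- paste0(sub("\\.edf$", "", path), "_events.tsv")
  if (!file.exists(ev_path))
    stop2("events sidecar not found: ", ev_path,
          " (recordings are read as EDF + events TSV)")
  events <- utils::read.delim(ev_path)
  structure(list(data = data, srate = srate, channels = channels,
                 events = events, artifact_times = numeric(0)),
            class = "eeg_recording")
}
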