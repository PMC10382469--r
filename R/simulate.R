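#' Ground-truth configuration for the EEG simulator
#'
#' Describes the pitch effect the forward model injects: which channels
#' carry it, its amplitude-per-pitch-step slope, its latency window, and the
#' noise floor. By default the effect is hemispherically anti-symmetric over
#' the frontotemporal pair set: left-hemisphere channels get slope `-slope`
#' (amplitude grows more negative as pitch rises), their right mirrors get
#' `+slope`, and all other channels zero. The effect is centred at pitch 4
#' (F4/"Fa"), so the per-trial effect amplitude at channel c is
#' `slope(c) * (pitch - 4)`.
#'
#' @param montage An `eeg_montage`.
#' @param slope Effect magnitude in microvolts per pitch step (default 0.5).
#' @param effect_pairs Character vector of `"L-R"` pair labels carrying the
#'   effect. Default: the four frontal pairs plus `T7-T8`.
#' @param effect_window Numeric `c(start_ms, end_ms)` latency of the effect
#'   relative to stimulus onset; must lie within `[0, 800]` ms.
#' @param noise_sd Total background-noise standard deviation in microvolts
#'   (pink + white, see [simulate_subject()]).
#' @param common_mode Fraction of noise variance shared across channels
#'   (default 0.5, giving healthy channels pairwise correlations around
#'   0.55 like volume-conducted EEG, so correlation-based bad-channel
#'   detection is exercised realistically).
#' @param bad_channels Channels to replace with independent white noise.
#' @param slope_map Optional named numeric vector over all channels giving
#'   per-channel slopes directly; overrides `slope`/`effect_pairs`.
#' @return Object of class `ground_truth`.
#' @export
ground_truth <- function(montage = standard_montage(), slope = 0.5,
                         effect_pairs = c(montage$frontal_pairs, "T7-T8"),
                         effect_window = c(540, 640), noise_sd = 5,
                         common_mode = 0.5, bad_channels = character(),
                         slope_map = NULL) {
  stopifnot(length(effect_window) == 2, effect_window[1] < effect_window[2])
  if (effect_window[1] < 0 || effect_window[2] > 800)
    stop2("effect_window must lie within [0, 800] ms (epoch range); got [",
          effect_window[1], ", ", effect_window[2], "]")
  if (is.null(slope_map)) {
    slope_map <- stats::setNames(rep(0, length(montage$channels)),
                                 montage$channels)
    for (pl in effect_pairs) {
      lr <- split_pair(pl)
      slope_map[lr[1]] <- -slope
      slope_map[lr[2]] <- +slope
    }
  } else {
    stopifnot(all(montage$channels %in% names(slope_map)))
    slope_map <- slope_map[montage$channels]
  }
  stopifnot(all(bad_channels %in% montage$channels))
  structure(list(slope_map = slope_map, effect_window = effect_window,
                 noise_sd = noise_sd, common_mode = common_mode,
                 bad_channels = bad_channels,
                 effect_pairs = effect_pairs, slope = slope),
            class = "ground_truth")
}

#' Evoked-response template
#'
#' The pitch-independent evoked waveform added at every stimulus onset: a
#' damped 10 Hz sinusoid enveloped over 0-500 ms with ~5 microvolt
#' magnitude. Any smooth template works for the analyses (the pitch effect
#' rides on top of it); this one is fixed for reproducibility.
#'
#' @param srate Sampling rate in Hz.
#' @param duration_s Template support in seconds (default 0.5).
#' @return Numeric vector of `srate * duration_s` samples (microvolts).
#' @export
evoked_template <- function(srate = 500, duration_s = 0.5) {
  t <- seq(0, duration_s - 1 / srate, by = 1 / srate)
  5 * exp(-t / 0.15) * sin(2 * pi * 10 * t)
}

# Smoothed unit pulse for the pitch effect: plateau exactly covering
# [start, end) so that the window mean over the effect window is exactly 1;
# 10 ms raised-cosine ramps extend outside the plateau.
effect_pulse <- function(effect_window, srate = 500, ramp_ms = 10) {
  ramp_n <- round(ramp_ms / 1000 * srate)
  plateau_n <- round(diff(effect_window) / 1000 * srate)
  up <- (1 - cos(pi * seq_len(ramp_n) / (ramp_n + 1))) / 2
  c(up, rep(1, plateau_n), rev(up))
}

# Background-noise matrix (time x columns), ~unit variance per column:
# equal-variance mix of a 1/f (pink) component and white noise. The pink
# component is spectrally shaped at 1/8 of the sampling rate and linearly
# upsampled -- its energy is concentrated at low frequencies, so the
# band-limitation (~30 Hz) is immaterial while avoiding full-rate FFTs;
# the white component carries the full bandwidth. Flat below 1 Hz.
shaped_noise_matrix <- function(n, n_cols, srate = 500) {
  ds <- 8L
  n_ds <- n %/% ds + 2L
  m <- stats::nextn(n_ds, c(2, 3))
  f <- seq(0, m - 1) / m * (srate / ds)
  f <- pmin(f, srate / ds - f)
  h <- 1 / sqrt(pmax(f, 1))
  h[1] <- 0                            # no DC in the pink part
  w <- matrix(stats::rnorm(m * n_cols), m, n_cols)
  z <- stats::mvfft(w) * h
  p <- Re(stats::mvfft(z, inverse = TRUE)) / (m * sqrt(mean(h^2)))
  i <- seq_len(n) - 1L
  k <- i %/% ds + 1L
  fr <- (i %% ds) / ds
  pink <- p[k, , drop = FALSE] * (1 - fr) + p[k + 1L, , drop = FALSE] * fr
  sqrt(0.5) * pink +
    sqrt(0.5) * matrix(stats::rnorm(n * n_cols), n, n_cols)
}

#' Simulate one subject's continuous EEG recording
#'
#' Forward model: at every trial onset a shared evoked template is added to
#' all channels, plus a per-channel effect pulse `slope(c) * (pitch - 4)`
#' smoothly gated within `truth$effect_window`; background noise is an
#' equal-variance mix of 1/f (pink) and white noise with total SD
#' `truth$noise_sd`, of which a fraction `truth$common_mode` of variance is
#' shared across channels. Channels listed in `truth$bad_channels` are
#' replaced by independent white noise. Blocks are separated by a 2 s gap;
#' the record is padded by 2 s at the start and 1 s at the end.
#'
#' @param montage An `eeg_montage`.
#' @param schedule A `trial_schedule`.
#' @param truth A `ground_truth`.
#' @param seed Integer seed; identical seeds give identical recordings.
#' @return Object of class `eeg_recording`: list with `data` (channels x
#'   samples matrix, microvolts), `srate` (500), `channels`, `events`
#'   (data.frame: onset_sample, pitch, block, target_pitch) and
#'   `artifact_times` (seconds; empty until [inject_artifacts()]).
#' @export
simulate_subject <- function(montage, schedule, truth, seed) {
  srate <- 500
  trial_n <- srate                     # 1000 ms per trial
  gap_n <- 2 * srate
  pad0 <- 2 * srate
  pad1 <- 1 * srate
  n_blocks <- length(schedule$blocks)
  tpb <- schedule$trials_per_block

  onsets <- integer(0)
  pitches <- integer(0)
  blocks <- integer(0)
  tgt <- integer(0)
  cursor <- pad0
  for (b in seq_len(n_blocks)) {
    bl <- schedule$blocks[[b]]
    on_b <- cursor + (seq_len(tpb) - 1L) * trial_n
    onsets <- c(onsets, on_b)
    pitches <- c(pitches, bl$pitches)
    blocks <- c(blocks, rep(b, tpb))
    tgt <- c(tgt, rep(bl$target, tpb))
    cursor <- cursor + tpb * trial_n + gap_n
  }
  n <- cursor - gap_n + pad1
  events <- data.frame(onset_sample = onsets + 1L,  # 1-based sample of t = 0
                       pitch = pitches, block = blocks, target_pitch = tgt)

  n_ch <- length(montage$channels)
  template <- evoked_template(srate)
  pulse <- effect_pulse(truth$effect_window, srate)
  pulse_at <- round(truth$effect_window[1] / 1000 * srate) -
    round(10 / 1000 * srate)          # pulse vector start relative to onset

  common <- numeric(n)
  eff <- numeric(n)
  it <- seq_along(template) - 1L
  ip <- seq_along(pulse) - 1L + pulse_at
  for (k in seq_along(onsets)) {
    o <- onsets[k]
    common[o + it + 1L] <- common[o + it + 1L] + template
    eff[o + ip + 1L] <- eff[o + ip + 1L] + (pitches[k] - 4) * pulse
  }

  with_seed(seed, {
    # build time x channels, transpose once at the end
    data_t <- outer(eff, unname(truth$slope_map)) + common
    if (truth$noise_sd > 0) {
      cm <- truth$common_mode
      noise <- shaped_noise_matrix(n, n_ch + 1, srate)
      data_t <- data_t + truth$noise_sd *
        (sqrt(cm) * noise[, n_ch + 1] +
           sqrt(1 - cm) * noise[, seq_len(n_ch), drop = FALSE])
    }
    for (bc in truth$bad_channels) {
      i <- match(bc, montage$channels)
      data_t[, i] <- stats::rnorm(n, sd = max(truth$noise_sd, 1))
    }
    data <- t(data_t)
    rownames(data) <- montage$channels
    structure(list(data = data, srate = srate, channels = montage$channels,
                   events = events, artifact_times = numeric(0)),
              class = "eeg_recording")
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$srate, " Hz, ", nrow(x$events), " events\n", sep = "")
  invisible(x)
}

#' Inject high-amplitude artifact bursts
#'
#' Adds short (100-300 ms) Hann-windowed high-amplitude bursts on random
#' channel subsets at Poisson-distributed times, emulating motion/muscle
#' artifacts for the artifact-subspace-reconstruction stage. Burst onset
#' times (seconds) are appended to `rec$artifact_times`.
#'
#' @param rec An `eeg_recording`.
#' @param rate_per_min Expected bursts per minute (0 returns `rec`
#'   unchanged).
#' @param amp_uV Peak burst amplitude in microvolts (> 0).
#' @param seed Integer seed.
#' @return The modified `eeg_recording`.
#' @export
inject_artifacts <- function(rec, rate_per_min, amp_uV = 500, seed = 0) {
  stopifnot(inherits(rec, "eeg_recording"), amp_uV > 0, rate_per_min >= 0)
  if (rate_per_min == 0) return(rec)
  with_seed(seed, {
    n <- ncol(rec$data)
    n_ch <- nrow(rec$data)
    dur_s <- n / rec$srate
    k <- stats::rpois(1, rate_per_min * dur_s / 60)
    if (k == 0) return(rec)
    times <- sort(stats::runif(k, 0.5, dur_s - 0.5))
    for (t0 in times) {
      len <- round(stats::runif(1, 0.1, 0.3) * rec$srate)
      i0 <- round(t0 * rec$srate)
      idx <- i0 + seq_len(len)
      idx <- idx[idx <= n]
      win <- 0.5 - 0.5 * cos(2 * pi * seq_along(idx) / (length(idx) + 1))
      chs <- sample(n_ch, sample(5:min(15, n_ch), 1))
      for (ci in chs) {
        pol <- sample(c(-1, 1), 1) * stats::runif(1, 0.6, 1)
        rec$data[ci, idx] <- rec$data[ci, idx] + amp_uV * pol * win
      }
    }
    rec$artifact_times <- c(rec$artifact_times, times)
    rec
  })
}

#' Simulate behavioral block-counting performance
#'
#' Draws per-subject counts of correctly reported blocks (0-14) from a
#' rounded normal clipped to the feasible range. Group defaults reproduce
#' the published summary of the pitch-counting task: musically-trained
#' (MT) subjects 12.5 +/- 1.5 correct blocks, non-trained (NT)
#' 3.3 +/- 2.03. Because clipping at the block count bound would otherwise
#' shift the realised mean (the MT centre sits close to the maximum of
#' 14), the latent normal centre is solved numerically so that the
#' expected clipped, rounded count equals the nominal group mean.
#'
#' @param group `"MT"` or `"NT"` (sets default mean/sd).
#' @param n Number of subjects (>= 1).
#' @param seed Integer seed.
#' @param mean,sd Override the group mean / SD.
#' @param n_blocks Maximum count (default 14).
#' @return Integer vector of length `n` in `[0, n_blocks]`.
#' @export
simulate_behavior <- function(group = c("MT", "NT"), n, seed = 0,
                              mean = NULL, sd = NULL, n_blocks = 14) {
  group <- match.arg(group)
  stopifnot(n >= 1)
  mean <- mean %||% switch(group, MT = 12.5, NT = 3.3)
  sd <- sd %||% switch(group, MT = 1.5, NT = 2.03)
  stopifnot(mean >= 0, mean <= n_blocks)
  mu <- latent_count_mean(mean, sd, n_blocks)
  with_seed(seed, {
    x <- round(stats::rnorm(n, mu, sd))
    as.integer(pmin(pmax(x, 0), n_blocks))
  })
}

# Latent normal centre whose rounded, clipped expectation equals `target`.
latent_count_mean <- function(target, sd, n_blocks) {
  if (sd == 0) return(target)
  expected <- function(mu) {
    k <- 0:n_blocks
    upper <- stats::pnorm(k + 0.5, mu, sd)
    lower <- stats::pnorm(k - 0.5, mu, sd)
    p <- upper - lower
    p[1] <- upper[1]                       # everything below rounds up to 0
    p[n_blocks + 1] <- 1 - lower[n_blocks + 1]
    sum(k * p)
  }
  stats::uniroot(function(mu) expected(mu) - target,
                 interval = c(target - 4 * sd, target + 4 * sd),
                 tol = 1e-10)$root
}
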