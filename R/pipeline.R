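#' Configuration for a full simulated experiment run
#'
#' Collects every knob of the simulate -> preprocess -> window-selection ->
#' statistics pipeline into one validated object so a run is reproducible
#' from its manifest. All randomness is derived from `seed` via fixed
#' substreams (schedule, noise, behavior), so stages are independently
#' reproducible.
#'
#' @param seed Root seed (non-negative integer).
#' @param n_per_group Subjects per group (MT and NT; default 10).
#' @param n_blocks Blocks per subject (default 14).
#' @param trials_per_block Trials per block (default 50).
#' @param slope Effect magnitude, microvolts per pitch step, for the MT
#'   group (default 0.5).
#' @param nt_slope_scale NT effect magnitude relative to MT (default 0.7:
#'   directionally weaker but not dramatically so).
#' @param subject_slope_sd Between-subject SD of the effect magnitude
#'   (default 0.1 uV/step).
#' @param noise_sd Background noise SD in microvolts (default 5).
#' @param common_mode Shared-noise variance fraction (default 0.5).
#' @param effect_window Effect latency window in ms (default c(540, 640)).
#' @param effect_pairs Pair labels carrying the effect (default frontal
#'   pairs + T7-T8).
#' @param bad_channels Channels replaced by noise in every subject.
#' @param artifact_rate Artifact bursts per minute (default 0 = none).
#' @param artifact_amp Burst amplitude in microvolts.
#' @param filter,detect_bad,laplacian,asr,baseline Stage toggles (all TRUE
#'   by default; the preprocessing order is fixed: filters -> bad-channel
#'   detection/interpolation -> surface Laplacian -> ASR -> epoching).
#' @param asr_cutoff ASR threshold in calibration SDs (default 30).
#' @param alpha,q Significance and FDR levels (default 0.05).
#' @param window_starts,window_width Sliding-window grid (ms).
#' @return Object of class `run_config` (a validated list).
#' @export
run_config <- function(seed = 1, n_per_group = 10, n_blocks = 14,
                       trials_per_block = 50, slope = 0.5,
                       nt_slope_scale = 0.7, subject_slope_sd = 0.1,
                       noise_sd = 5, common_mode = 0.5,
                       effect_window = c(540, 640),
                       effect_pairs = NULL, bad_channels = character(),
                       artifact_rate = 0, artifact_amp = 500,
                       filter = TRUE, detect_bad = TRUE, laplacian = TRUE,
                       asr = TRUE, baseline = TRUE, asr_cutoff = 30,
                       alpha = 0.05, q = 0.05,
                       window_starts = seq(0, 700, 10), window_width = 100) {
  if (n_per_group < 1) stop2("n_per_group must be at least 1")
  if (n_blocks < 1) stop2("n_blocks must be at least 1")
  if (noise_sd < 0) stop2("noise_sd must be non-negative")
  montage <- standard_montage()
  effect_pairs <- effect_pairs %||% c(montage$frontal_pairs, "T7-T8")
  cfg <- list(seed = seed, n_per_group = n_per_group, n_blocks = n_blocks,
              trials_per_block = trials_per_block, slope = slope,
              nt_slope_scale = nt_slope_scale,
              subject_slope_sd = subject_slope_sd, noise_sd = noise_sd,
              common_mode = common_mode, effect_window = effect_window,
              effect_pairs = effect_pairs, bad_channels = bad_channels,
              artifact_rate = artifact_rate, artifact_amp = artifact_amp,
              filter = filter, detect_bad = detect_bad,
              laplacian = laplacian, asr = asr, baseline = baseline,
              asr_cutoff = asr_cutoff, alpha = alpha, q = q,
              window_starts = window_starts, window_width = window_width)
  structure(cfg, class = "run_config")
}

# Per-subject effect magnitude for a group under a config.
subject_slope <- function(config, group, subj_seed) {
  base <- config$slope * if (group == "NT") config$nt_slope_scale else 1
  if (config$subject_slope_sd > 0)
    base <- base + with_seed(subj_seed, stats::rnorm(1, 0, config$subject_slope_sd))
  base
}

#' Preprocess a continuous recording
#'
#' Applies the preprocessing chain in its fixed order -- temporal filters,
#' correlation-based bad-channel detection and spherical-spline
#' interpolation, surface-Laplacian re-referencing, artifact subspace
#' reconstruction -- honouring the stage toggles in `config`, then epochs
#' and labels trials.
#'
#' @param rec An `eeg_recording`.
#' @param montage The `eeg_montage`.
#' @param config A `run_config`.
#' @return An `erp_epochs`.
#' @export
preprocess_recording <- function(rec, montage, config = run_config()) {
  if (config$filter) rec <- filter_line_and_band(rec)
  if (config$detect_bad) {
    rep <- detect_bad_channels(rec)
    bad <- attr(rep, "flagged")
    if (length(bad)) rec <- interpolate_channels(rec, montage, bad)
  }
  if (config$laplacian) rec <- surface_laplacian(rec, montage)
  if (config$asr) rec <- asr_clean(rec, cutoff = config$asr_cutoff)
  epoch_and_filter(rec, baseline = config$baseline)
}

#' Simulate a full two-group experiment
#'
#' Generates every subject of both groups under the configured conditions
#' (schedule, continuous EEG, optional artifacts), preprocesses each
#' recording according to the config toggles, and reduces it to sliding
#' window trial amplitudes. Behavioral correct-block counts are simulated
#' per group.
#'
#' @param config A `run_config`.
#' @param keep_erps Accumulate per-pitch grand-average ERPs (default TRUE).
#' @return Object of class `erp_experiment`: list with `config`, `montage`,
#'   `subjects` (each: `group`, `id`, `wa` window amplitudes, `true_slope`),
#'   `behavior` (list MT/NT), and optionally `grand_avg` (list per group:
#'   channels x time x pitch arrays) with `times`.
#' @export
simulate_experiment <- function(config = run_config(), keep_erps = TRUE) {
  montage <- standard_montage()
  subjects <- list()
  grand <- list()
  times <- NULL
  k <- 0
  for (group in c("MT", "NT")) {
    g_off <- if (group == "MT") 0 else config$n_per_group
    acc <- NULL
    cnt <- NULL
    for (s in seq_len(config$n_per_group)) {
      k <- k + 1
      sidx <- g_off + s
      sch <- generate_schedule(substream(config$seed, sidx),
                               n_blocks = config$n_blocks,
                               trials_per_block = config$trials_per_block)
      sl <- subject_slope(config, group, substream(config$seed, 1000 + sidx))
      truth <- ground_truth(montage, slope = sl,
                            effect_pairs = config$effect_pairs,
                            effect_window = config$effect_window,
                            noise_sd = config$noise_sd,
                            common_mode = config$common_mode,
                            bad_channels = config$bad_channels)
      rec <- simulate_subject(montage, sch, truth,
                              substream(config$seed, 2000 + sidx))
      if (config$artifact_rate > 0)
        rec <- inject_artifacts(rec, config$artifact_rate,
                                config$artifact_amp,
                                substream(config$seed, 3000 + sidx))
      fast <- !keep_erps && !config$filter && !config$detect_bad &&
        !config$laplacian && !config$asr
      if (fast) {
        wa <- continuous_window_amps(rec, starts = config$window_starts,
                                     width = config$window_width,
                                     baseline = config$baseline)
        ep <- NULL
      } else {
        ep <- preprocess_recording(rec, montage, config)
        wa <- window_amplitudes(ep, starts = config$window_starts,
                                width = config$window_width)
      }
      if (keep_erps) {
        times <- ep$times
        pa <- pitch_erp_average(ep)
        acc <- if (is.null(acc)) pa else acc + pa
        cnt <- if (is.null(cnt)) 1 else cnt + 1
      }
      subjects[[k]] <- list(group = group, id = sidx, wa = wa,
                            true_slope = sl)
    }
    if (keep_erps) grand[[group]] <- acc / cnt
  }
  behavior <- list(
    MT = simulate_behavior("MT", config$n_per_group,
                           substream(config$seed, 4001)),
    NT = simulate_behavior("NT", config$n_per_group,
                           substream(config$seed, 4002)))
  structure(list(config = config, montage = montage, subjects = subjects,
                 behavior = behavior,
                 grand_avg = if (keep_erps) grand else NULL,
                 times = times),
            class = "erp_experiment")
}

# Per-pitch average ERP for one subject: channels x time x pitch.
pitch_erp_average <- function(ep, n_pitches = 7) {
  d <- dim(ep$data)
  out <- array(0, c(d[1], d[2], n_pitches))
  groups <- trial_groups(ep$meta, half = NULL, n_pitches = n_pitches)
  for (p in seq_len(n_pitches)) {
    g <- groups[[p]]
    if (length(g))
      out[, , p] <- rowMeans(ep$data[, , g, drop = FALSE], dims = 2)
  }
  out
}

#' Analyse a simulated (or loaded) experiment
#'
#' Runs the complete inference chain: separability scan on half-1 trials
#' and window selection; half-2 per-pitch window amplitudes; ANOVA channel
#' selection with bilateral completion; paired left-right tests per pitch;
#' slope fits and one-sample tests; frontal-parietal asymmetry contrast;
#' group slope comparison; earliest discriminative window per group;
#' behavioral rank-sum test; behavior-slope correlations. FDR families
#' follow the declared scheme (channels within group; pair x pitch within
#' group; 4 region matches within group).
#'
#' @param exp An `erp_experiment`.
#' @return Object of class `erp_analysis` (a list of all result tables,
#'   the separability curve and the selected window).
#' @export
analyze_experiment <- function(exp) {
  stopifnot(inherits(exp, "erp_experiment"))
  cfg <- exp$config
  montage <- exp$montage
  was <- lapply(exp$subjects, `[[`, "wa")
  groups <- vapply(exp$subjects, `[[`, character(1), "group")

  curve <- scan_windows(was, half = 1)
  win <- select_window(curve)

  pm_all <- list()
  for (g in c("MT", "NT")) {
    pml <- lapply(was[groups == g], pitch_window_means, half = 2)
    pm_all[[g]] <- stack_pitch_means(pml)      # subj x ch x win x pitch
  }
  pm_win <- lapply(pm_all, function(a) {
    out <- a[, , win$index, , drop = FALSE]
    array(out, dim(out)[-3], dimnames = list(NULL, dimnames(a)[[2]], NULL))
  })

  selection <- select_channels(pm_win, montage, alpha = cfg$alpha)
  sel_pairs <- attr(selection, "pairs")
  asym <- if (nrow(sel_pairs))
    paired_asymmetry_tests(pm_win, sel_pairs, q = cfg$q) else NULL

  slopes <- lapply(pm_win, fit_pitch_slopes)
  enough <- all(vapply(slopes, function(s) nrow(s$slope) >= 3, TRUE))
  if (!enough)
    message("fewer than 3 subjects per group: ",
            "slope, region and group tests skipped")
  slope_tests <- if (enough) lapply(slopes, test_slopes_nonzero, q = cfg$q)
  region <- if (enough) lapply(slopes, region_asymmetry_compare,
                               montage = montage, q = cfg$q)
  group_cmp <- if (enough)
    compare_groups_slopes(slopes$MT, slopes$NT, q = cfg$q)
  earliest <- lapply(c(MT = "MT", NT = "NT"), function(g)
    earliest_discriminative_window(pm_all[[g]], selection,
                                   starts = cfg$window_starts,
                                   alpha = cfg$alpha, allow_empty = TRUE))

  behavior <- if (min(lengths(exp$behavior)) >= 3)
    behavior_test(exp$behavior$MT, exp$behavior$NT)
  pooled_counts <- c(exp$behavior$MT, exp$behavior$NT)
  pooled_slopes <- structure(
    list(slope = rbind(slopes$MT$slope, slopes$NT$slope),
         intercept = rbind(slopes$MT$intercept, slopes$NT$intercept),
         channels = slopes$MT$channels), class = "slope_table")
  correlations <- if (length(pooled_counts) == nrow(pooled_slopes$slope))
    correlate_behavior_slopes(pooled_counts, pooled_slopes, q = cfg$q)

  structure(list(config = cfg, curve = curve, window = win,
                 selection = selection, asymmetry = asym, slopes = slopes,
                 slope_tests = slope_tests, region = region,
                 group_comparison = group_cmp, earliest = earliest,
                 behavior = behavior, correlations = correlations),
            class = "erp_analysis")
}

#' @export
print.erp_analysis <- function(x, ...) {
  cat("<erp_analysis>\n")
  cat("  selected window: [", x$window$start_ms, ", ", x$window$end_ms,
      ") ms\n", sep = "")
  cat("  selected channels: ",
      paste(attr(x$selection, "selected"), collapse = ", "), "\n", sep = "")
  for (g in names(x$slope_tests %||% list())) {
    st <- x$slope_tests[[g]]
    cat("  ", g, ": ", sum(st$significant), " channels with nonzero slope; ",
        sum(x$region[[g]]$significant),
        "/4 frontal>parietal contrasts significant\n", sep = "")
  }
  if (!is.null(x$behavior))
    cat("  behavior: ", sprintf("%.1f +/- %.2f vs %.1f +/- %.2f, p = %.2g",
        x$behavior$mean_a, x$behavior$sd_a, x$behavior$mean_b,
        x$behavior$sd_b, x$behavior$p), "\n", sep = "")
  invisible(x)
}

#' Run the full pipeline and write a report directory
#'
#' Simulates the experiment, analyses it, and (optionally) writes the
#' report files: the separability curve, all statistics tables as TSV,
#' per-pitch grand-average ERPs, a JSON manifest with the full config and
#' selected window, and a plain-text summary of the headline checks.
#' A rerun with the same config reproduces every output.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if missing); `NULL` skips
#'   writing.
#' @return The `erp_analysis`, invisibly when writing.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  exp <- simulate_experiment(config, keep_erps = !is.null(out_dir))
  res <- analyze_experiment(exp)
  if (is.null(out_dir)) return(res)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(data.frame(window_start_ms = res$curve$window_start,
                score = res$curve$score, sem = res$curve$sem),
     "separability_curve.tsv")
  wt(as.data.frame(res$selection), "channel_selection.tsv")
  if (!is.null(res$asymmetry)) wt(res$asymmetry, "asymmetry_tests.tsv")
  sl <- do.call(rbind, lapply(names(res$slopes), function(g) {
    m <- res$slopes[[g]]$slope
    data.frame(group = g, subject = rep(seq_len(nrow(m)), ncol(m)),
               channel = rep(colnames(m), each = nrow(m)),
               slope = as.vector(m),
               intercept = as.vector(res$slopes[[g]]$intercept))
  }))
  wt(sl, "slopes.tsv")
  if (!is.null(res$slope_tests))
    wt(do.call(rbind, lapply(names(res$slope_tests), function(g)
      cbind(group = g, res$slope_tests[[g]]))), "slope_tests.tsv")
  if (!is.null(res$region))
    wt(do.call(rbind, lapply(names(res$region), function(g)
      cbind(group = g, res$region[[g]]))), "region_compare.tsv")
  if (!is.null(res$group_comparison))
    wt(res$group_comparison, "group_compare.tsv")
  if (!is.null(res$behavior)) wt(res$behavior, "behavior.tsv")
  if (!is.null(res$correlations)) wt(res$correlations, "correlations.tsv")
  for (g in names(exp$grand_avg)) {
    ga <- exp$grand_avg[[g]]
    d <- dim(ga)
    wt(data.frame(time_ms = rep(exp$times, each = d[1]),
                  channel = rep(exp$montage$channels, d[2] * d[3]),
                  pitch = rep(seq_len(d[3]), each = d[1] * d[2]),
                  amplitude = as.vector(ga)),
       paste0("erp_grand_average_", g, ".tsv"))
  }
  manifest <- list(
    config = unclass(config),
    selected_window = list(start_ms = res$window$start_ms,
                           end_ms = res$window$end_ms),
    selected_channels = attr(res$selection, "selected"),
    fdr_families = list(
      selection = "channels within group",
      asymmetry = "pair x pitch within group",
      region = "4 coronal-plane matches within group",
      slopes = "channels within group",
      group_comparison = "channels",
      correlations = "channels"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  summary_lines <- c(
    sprintf("Selected window: [%d, %d) ms",
            res$window$start_ms, res$window$end_ms),
    sprintf("Selected channels: %s",
            paste(attr(res$selection, "selected"), collapse = ", ")),
    vapply(names(res$slope_tests %||% list()), function(g) {
      st <- res$slope_tests[[g]]
      neg_left <- st$channel %in% exp$montage$pairs$left & st$sign < 0 &
        st$significant
      pos_right <- st$channel %in% exp$montage$pairs$right & st$sign > 0 &
        st$significant
      sprintf("%s: %d significant-negative left, %d significant-positive right slopes",
              g, sum(neg_left), sum(pos_right))
    }, character(1)),
    vapply(names(res$region %||% list()), function(g)
      sprintf("%s: %d/4 frontal-vs-parietal asymmetry contrasts significant",
              g, sum(res$region[[g]]$significant)), character(1)),
    if (!is.null(res$group_comparison))
      sprintf("Group slope direction: MT stiffer at %d/%d channels (%d significant after FDR)",
              sum(res$group_comparison$stiffer > 0),
              nrow(res$group_comparison),
              sum(res$group_comparison$significant)),
    if (!is.null(res$behavior))
      sprintf("Behavior: MT %.1f +/- %.2f vs NT %.1f +/- %.2f correct blocks, exact rank-sum p = %.3g",
              res$behavior$mean_a, res$behavior$sd_a,
              res$behavior$mean_b, res$behavior$sd_b, res$behavior$p))
  writeLines(summary_lines, file.path(out_dir, "summary.txt"))
  invisible(res)
}

#' Write the small seeded fixture set
#'
#' Generates the reduced test fixtures (2 subjects per group, 4 blocks)
#' as EDF + events TSV + ground-truth JSON, for exercising the file
#' readers.
#'
#' @param out_dir Output directory.
#' @param seed Seed for the fixture experiment.
#' @return Character vector of the EDF paths, invisibly.
#' @export
make_fixtures <- function(out_dir, seed = 42) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  montage <- standard_montage()
  paths <- character(0)
  k <- 0
  for (group in c("MT", "NT")) {
    for (s in 1:2) {
      k <- k + 1
      sch <- generate_schedule(substream(seed, k), n_blocks = 4)
      truth <- ground_truth(montage,
                            slope = if (group == "MT") 0.5 else 0.35)
      rec <- simulate_subject(montage, sch, truth, substream(seed, 100 + k))
      p <- file.path(out_dir, sprintf("sub-%s%02d.edf", group, s))
      write_recording(rec, p, truth = truth)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
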