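# Independent oracles used by the tests. These deliberately re-derive the
# statistics by the most literal route (double loops, enumeration) and are
# kept free of any package internals.

# Literal double-loop evaluation of the separability statistic.
naive_separability <- function(groups) {
  k <- length(groups)
  meds <- sapply(groups, median)
  sds <- sapply(groups, sd)
  tot <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j != i) tot <- tot + abs(meds[i] - meds[j]) / (sds[i] + sds[j])
  }
  tot / 2 / choose(k, 2)   # i<j pairs counted twice in the full double sum
}

# Benjamini-Hochberg step-up by its definition.
bh_reject_bruteforce <- function(p, q = 0.05) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Exact two-sided Wilcoxon signed-rank p-value by enumeration of all sign
# assignments (no ties, no zeros assumed).
signed_rank_enum_p <- function(x, y) {
  d <- x - y
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  n <- length(d)
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(mask, 2^(0:(n - 1))) > 0
    sum(r[signs])
  }, numeric(1))
  p_le <- mean(vs <= v_obs)
  p_ge <- mean(vs >= v_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided rank-sum p-value by enumeration of group assignments.
rank_sum_enum_p <- function(x, y) {
  all_v <- c(x, y)
  r <- rank(all_v)
  n <- length(all_v)
  w_obs <- sum(r[seq_along(x)])
  combos <- combn(n, length(x))
  ws <- apply(combos, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Minimal continuous-recording constructor for filter/channel tests.
make_recording <- function(data, srate = 500, channels = NULL,
                           events = NULL) {
  channels <- channels %||% rownames(data) %||%
    paste0("ch", seq_len(nrow(data)))
  rownames(data) <- channels
  structure(list(
    data = data, srate = srate, channels = channels,
    events = events %||% data.frame(onset_sample = integer(0),
                                    pitch = integer(0), block = integer(0),
                                    target_pitch = integer(0)),
    artifact_times = numeric(0)), class = "eeg_recording")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One small shared noisy subject, built once per test run.
small_subject <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      m <- standard_montage()
      sch <- generate_schedule(5, n_blocks = 2)
      tr <- ground_truth(m, slope = 0.5, noise_sd = 5)
      cache <<- list(montage = m, schedule = sch, truth = tr,
                     rec = simulate_subject(m, sch, tr, seed = 17))
    }
    cache
  }
})
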