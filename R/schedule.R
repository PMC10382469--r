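#' Generate a balanced trial schedule
#'
#' Builds the block/trial schedule of the pitch-counting task: `n_blocks`
#' blocks of `trials_per_block` tone presentations drawn from `n_pitches`
#' pitch classes (1 = C4 ... 7 = B4), with one target pitch per block.
#' Presentation order is pseudo-randomised under the constraint that every
#' pitch is presented equally often across all main blocks (exactly 100
#' times in the default 14 x 50 design) and every pitch serves as the block
#' target equally often (exactly twice in the default design).
#'
#' Randomisation is stratified by block: each block receives a near-equal
#' share of every pitch (within one presentation), which implies the exact
#' global balance and keeps per-pitch trial counts usable even in reduced
#' designs. For non-default block counts the same rules apply in their
#' divisible form: per-pitch presentation counts and per-pitch target counts
#' each differ by at most one.
#'
#' @param seed Non-negative integer seed; the same seed reproduces the same
#'   schedule.
#' @param n_blocks Number of main blocks (default 14).
#' @param trials_per_block Trials per block (default 50).
#' @param n_pitches Number of pitch classes (default 7).
#' @return An object of class `trial_schedule`: list with `blocks` (a list
#'   of lists, each `target` and `pitches`), `seed`, `n_pitches`.
#' @examples
#' sch <- generate_schedule(seed = 1)
#' table(unlist(lapply(sch$blocks, `[[`, "pitches")))  # 100 each
#' @export
generate_schedule <- function(seed, n_blocks = 14, trials_per_block = 50,
                              n_pitches = 7) {
  stopifnot(length(seed) == 1, is.numeric(seed), seed >= 0,
            n_blocks >= 1, trials_per_block >= 1, n_pitches >= 2)
  with_seed(seed, {
    total <- n_blocks * trials_per_block
    base <- total %/% n_pitches
    rem <- total %% n_pitches
    # per-pitch totals: as equal as possible (exactly equal when divisible)
    tot_p <- rep(base, n_pitches)
    if (rem > 0) tot_p[sample(n_pitches, rem)] <- base + 1
    # deal the pool round-robin into blocks, pitch runs kept contiguous, so
    # each block also receives a near-equal share of every pitch
    pool <- unlist(lapply(sample(n_pitches), function(p) rep(p, tot_p[p])))
    offset <- sample(n_blocks, 1)
    block_of <- ((seq_len(total) - 1 + offset) %% n_blocks) + 1

    t_base <- n_blocks %/% n_pitches
    t_rem <- n_blocks %% n_pitches
    targets <- rep(seq_len(n_pitches), t_base)
    if (t_rem > 0) targets <- c(targets, sample(n_pitches, t_rem))
    targets <- sample(targets)[seq_len(n_blocks)]

    blocks <- vector("list", n_blocks)
    for (b in seq_len(n_blocks)) {
      blocks[[b]] <- list(target = targets[b],
                          pitches = sample(pool[block_of == b]))
    }
    structure(list(blocks = blocks, seed = seed, n_pitches = n_pitches,
                   trials_per_block = trials_per_block),
              class = "trial_schedule")
  })
}

#' @export
print.trial_schedule <- function(x, ...) {
  cat("<trial_schedule> ", length(x$blocks), " blocks x ",
      x$trials_per_block, " trials, ", x$n_pitches, " pitches (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}

schedule_pitches <- function(schedule) {
  unlist(lapply(schedule$blocks, `[[`, "pitches"), use.names = FALSE)
}

schedule_targets <- function(schedule) {
  vapply(schedule$blocks, `[[`, numeric(1), "target")
}
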