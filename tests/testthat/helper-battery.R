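# Shared 50-seed simulation batteries for the acceptance-level checks.
# Built lazily on first use and reused across test blocks; base seeds are
# fixed constants.
battery <- local({
  cache <- new.env(parent = emptyenv())
  function(kind = c("effect", "null")) {
    kind <- match.arg(kind)
    if (is.null(cache[[kind]])) {
      cache[[kind]] <- if (kind == "effect")
        recovery_study(n_seeds = 50, base_seed = 1)
      else
        recovery_study(n_seeds = 50, base_seed = 2, null = TRUE)
    }
    cache[[kind]]
  }
})
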