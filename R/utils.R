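# Internal helpers shared across modules.

# Derive a reproducible sub-seed (< 2^31 - 1) from a master seed and a
# stream index, so every stochastic stage of a run draws from its own
# deterministic stream.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) %% 2147483647) * 48271 %% 2147483647 +
               stream * 7919) %% 2147483646L + 1L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(..., call. = FALSE)
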