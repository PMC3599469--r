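`%||%` <- function(a, b) if (is.null(a)) b else a

## round-half-up; base round() is round-half-even which would make planted
## read counts depend on parity of the target
round_half_up <- function(x) floor(x + 0.5)

## Deterministic 31-bit seed derived from a user seed plus an arbitrary
## sequence of labels/indices.  Keyed streams mean that, e.g., adding a sample
## to a simulated cohort does not reshuffle the reads of earlier samples.
derive_seed <- function(seed, ...) {
  parts <- list(...)
  m <- 2147483629
  h <- as.double(as.integer(seed)) %% m
  for (p in parts) {
    if (is.character(p)) {
      v <- utf8ToInt(p)
      p <- sum(v * seq_along(v))
    }
    h <- (h * 48271 + as.double(p) + 1) %% m
  }
  as.integer(h)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

favr_version <- function() {
  as.character(utils::packageVersion("favr"))
}

variant_key <- function(x) {
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}
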