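## Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
## RNG state is restored afterwards so library code never perturbs a user's
## random stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Write a data.frame as TSV with round-trip float formatting ("%.17g"), no
## quoting, no row names. Used for every pipeline output so reruns are
## byte-comparable.
writeTsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## Derive a child seed from a base seed and a stream index, kept inside the
## 32-bit integer range.
deriveSeed <- function(seed, stream) {
  as.integer((as.double(seed) * 1000 + stream) %% .Machine$integer.max)
}
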