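# internal helpers shared across modules

# Evaluate `expr` under a private RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Seed NULL means "use the current stream".
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
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
  eval.parent(substitute(expr))
}

# key string for a junction; single canonical form used by index and counting
junctionKey <- function(chrom, start, end, strand) {
  paste(chrom, start, end, strand, sep = ":")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# write a data.frame as TSV with stable formatting (used by exports/pipeline)
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
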