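## Boltzmann constant in kcal/(mol K)
.kB <- 0.0019872041

## Run code under a local RNG state seeded with `seed`, restoring the global
## state afterwards. All generator functions route randomness through this.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

## Derive a sub-seed deterministically; kept within 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(k)) %% 2147483647L)
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

## Fixed-format numbers for deterministic text output.
.fmt <- function(x, digits = 6) formatC(x, format = "f", digits = digits)

## Write a data.frame as TSV with '#'-prefixed header lines (parameters echo).
writeCommentedTSV <- function(df, path, header = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col) && !is.integer(col)) .fmt(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}
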