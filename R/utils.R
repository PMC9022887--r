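# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# L2-normalize matrix rows; errors on all-zero rows (cosine undefined).
normalize_rows <- function(m, context = "vector") {
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0))
    stopf("cosine similarity undefined for all-zero %s: %s",
          context, paste(rownames(m)[nrm == 0], collapse = ", "))
  m / nrm
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a data.frame as TSV with doubles at full (round-trip) precision.
write_tsv_full <- function(df, path) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
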