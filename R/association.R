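#' Association Score between two genes
#'
#' The Association Score of a gene pair is the cosine similarity of the two
#' genes' embedding vectors: symmetric, in \[-1, 1\], and 1 for a gene with
#' itself. Negative scores are reported as-is.
#'
#' @param emb an `embedded_network`.
#' @param a,b gene symbols.
#' @return Cosine similarity, a single number in \[-1, 1\].
#' @export
association_score <- function(emb, a, b) {
  v <- emb$vectors
  miss <- setdiff(c(a, b), rownames(v))
  if (length(miss)) stopf("gene(s) not embedded: %s", paste(miss, collapse = ", "))
  x <- v[a, ]; y <- v[b, ]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    stopf("cosine similarity undefined for all-zero vector (%s)",
          if (nx == 0) a else b)
  s <- sum(x * y) / (nx * ny)
  min(1, max(-1, s))
}

#' Number of unordered gene pairs
#'
#' `choose(n, 2)` -- e.g. 14,707 embedded genes give 108,140,571 pairs.
#'
#' @param n universe size (>= 2).
#' @return The pair count.
#' @export
all_pair_count <- function(n) {
  if (n < 2) stopf("need at least 2 genes (got %g)", n)
  choose(n, 2)
}

#' Association Scores for a list of gene pairs, blockwise
#'
#' Evaluates cosine similarity for each requested pair in blocks of
#' `block_size`, so the peak working set stays bounded regardless of how
#' many pairs are requested; a full dense gene-by-gene matrix is never
#' materialized.
#'
#' @param emb an `embedded_network`.
#' @param pairs two-column matrix or data.frame of gene symbols.
#' @param block_size pairs evaluated per block (default 10000).
#' @return data.frame `gene_a`, `gene_b`, `score`.
#' @export
score_many <- function(emb, pairs, block_size = 10000) {
  pairs <- as.matrix(pairs)
  if (!nrow(pairs))
    return(data.frame(gene_a = character(), gene_b = character(),
                      score = numeric()))
  v <- emb$vectors
  miss <- setdiff(unique(c(pairs)), rownames(v))
  if (length(miss)) stopf("gene(s) not embedded: %s", paste(miss, collapse = ", "))
  vn <- normalize_rows(v, "embedding")
  n <- nrow(pairs)
  score <- numeric(n)
  for (start in seq(1, n, by = block_size)) {
    idx <- start:min(n, start + block_size - 1)
    a <- vn[pairs[idx, 1], , drop = FALSE]
    b <- vn[pairs[idx, 2], , drop = FALSE]
    score[idx] <- pmin(1, pmax(-1, rowSums(a * b)))
  }
  data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2], score = score,
             stringsAsFactors = FALSE)
}

#' Association Scores between two gene sets as a matrix
#'
#' Computes the cosine block `genes_a` x `genes_b` (the shape the profile
#' and subnetwork stages consume: disease genes by cytokines).
#'
#' @param emb an `embedded_network`.
#' @param genes_a,genes_b gene symbol vectors.
#' @return Numeric matrix of cosine similarities.
#' @export
score_block <- function(emb, genes_a, genes_b) {
  v <- emb$vectors
  miss <- setdiff(unique(c(genes_a, genes_b)), rownames(v))
  if (length(miss)) stopf("gene(s) not embedded: %s", paste(miss, collapse = ", "))
  a <- normalize_rows(v[genes_a, , drop = FALSE], "embedding")
  b <- normalize_rows(v[genes_b, , drop = FALSE], "embedding")
  m <- a %*% t(b)
  m[m > 1] <- 1; m[m < -1] <- -1
  dimnames(m) <- list(genes_a, genes_b)
  m
}

#' Agreement between Association Scores and known edge confidences
#'
#' Summarizes, per Association-Score bin, the distribution of known
#' confidences (quartiles and mean) and the fraction of pairs at or above a
#' confidence threshold -- the tabular form of the score-vs-confidence
#' boxplot analysis. Empty bins are reported with `NA` summaries, not zeros.
#'
#' @param scores numeric Association Scores.
#' @param confidences numeric confidences aligned with `scores`.
#' @param score_bin_edges breaks over \[-1, 1\]; default
#'   `c(-1, 0.4, 0.6, 0.8, 1)`, the four-bin presentation.
#' @param conf_threshold confidence cutoff for the per-bin fraction
#'   (default 800).
#' @return data.frame, one row per `(lo, hi]` bin: `lo`, `hi`, `n`, `mean`,
#'   `q1`, `median`, `q3`, `frac_ge_threshold`.
#' @export
confidence_agreement <- function(scores, confidences,
                                 score_bin_edges = c(-1, 0.4, 0.6, 0.8, 1),
                                 conf_threshold = 800) {
  if (length(scores) != length(confidences))
    stopf("scores and confidences must be aligned")
  bin <- cut(scores, breaks = score_bin_edges, include.lowest = TRUE)
  out <- data.frame(lo = score_bin_edges[-length(score_bin_edges)],
                    hi = score_bin_edges[-1])
  stats <- lapply(levels(bin), function(lv) {
    x <- confidences[which(bin == lv)]
    if (!length(x))
      return(c(n = 0, mean = NA, q1 = NA, median = NA, q3 = NA,
               frac_ge_threshold = NA))
    q <- quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    c(n = length(x), mean = mean(x), q1 = q[1], median = q[2], q3 = q[3],
      frac_ge_threshold = mean(x >= conf_threshold))
  })
  cbind(out, do.call(rbind, stats))
}
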