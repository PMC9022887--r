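#' Number of non-cytokine genes in the universe
#'
#' e.g. 14,707 embedded genes minus 126 catalog cytokines leaves 14,581
#' non-cytokine genes.
#'
#' @param universe_size embedded gene count.
#' @param n_cytokines catalog cytokine count (must not exceed
#'   `universe_size`).
#' @return `universe_size - n_cytokines`.
#' @export
non_cytokine_count <- function(universe_size, n_cytokines) {
  if (n_cytokines > universe_size)
    stopf("n_cytokines exceeds universe size (%g > %g)",
          n_cytokines, universe_size)
  universe_size - n_cytokines
}

#' Disease-size bin assignment
#'
#' Diseases are grouped by gene-set size into the four standard bins:
#' 2--9, 10--19, 20--49, >49. Sets of fewer than two genes are rejected.
#'
#' @param n_genes integer vector of disease gene-set sizes.
#' @return Factor with levels `"2-9"`, `"10-19"`, `"20-49"`, `">49"`.
#' @export
assign_bin <- function(n_genes) {
  if (any(n_genes < 2))
    stopf("disease gene sets must have >= 2 genes")
  cut(n_genes, breaks = c(2, 10, 20, 50, Inf), right = FALSE,
      labels = c("2-9", "10-19", "20-49", ">49"))
}

#' Raw disease-by-cytokine profiles (average Association Scores)
#'
#' For each disease, the mean Association Score between its gene set and
#' each catalog cytokine. When a cytokine belongs to its own disease set,
#' the self pair (cosine 1 by construction) is excluded from that
#' cytokine's average (`exclude_self`, on by default and logged; disable to
#' average over the literal set).
#'
#' @param emb an `embedded_network`.
#' @param sets a `disease_sets` list (all genes embedded).
#' @param catalog a [cytokine_catalog()].
#' @param exclude_self drop the cytokine-with-itself pair from its own
#'   average.
#' @return Object of class `raw_profiles`: `avg` (diseases x cytokines
#'   matrix), `n_genes` (named vector), `bin` (factor from
#'   [assign_bin()]).
#' @export
raw_profiles <- function(emb, sets, catalog, exclude_self = TRUE) {
  cyto <- catalog$cytokines
  all_genes <- sort(unique(unlist(sets)))
  blk <- score_block(emb, all_genes, cyto)
  avg <- matrix(NA_real_, length(sets), length(cyto),
                dimnames = list(names(sets), cyto))
  n_self <- 0L
  for (d in seq_along(sets)) {
    g <- sets[[d]]
    m <- colMeans(blk[g, , drop = FALSE])
    if (exclude_self) {
      own <- intersect(g, cyto)
      if (length(own)) {
        n <- length(g)
        m[own] <- (m[own] * n - blk[cbind(own, own)]) / (n - 1)
        n_self <- n_self + length(own)
      }
    }
    avg[d, ] <- m
  }
  if (n_self > 0)
    message(sprintf("excluded %d cytokine self-pair(s) from raw averages",
                    n_self))
  structure(list(avg = avg,
                 n_genes = setNames(lengths(sets), names(sets)),
                 bin = assign_bin(lengths(sets))),
            class = "raw_profiles")
}

#' Normalize raw profiles to NAAS (within-bin empirical CDF)
#'
#' The normalized average Association Score of disease `d` for cytokine `c`
#' is the fraction of diseases in `d`'s size bin whose raw average for `c`
#' is *strictly* smaller than `d`'s:
#' `NAAS = #\{e in bin: avg(e, c) < avg(d, c)\} / bin size`.
#' This is a per-cytokine empirical CDF computed within each bin, so values
#' lie in `[0, (m - 1) / m]` for bin size `m`, ties score 0 against each
#' other, and the result is invariant under any strictly increasing
#' transform of the raw averages. `pooled = TRUE` instead ranks each raw
#' average against all cytokine averages of the bin pooled together.
#'
#' @param raw a `raw_profiles` object.
#' @param pooled pool all cytokines within a bin into one reference
#'   distribution (default `FALSE`: per-cytokine normalization).
#' @return Object of class `cytokine_profiles`: `naas` (diseases x
#'   cytokines matrix in \[0, 1\]), `bin`, `n_genes`.
#' @export
naas_normalize <- function(raw, pooled = FALSE) {
  avg <- raw$avg
  naas <- avg * NA_real_
  for (lv in levels(raw$bin)) {
    rows <- which(raw$bin == lv)
    if (!length(rows)) next
    m <- length(rows)
    sub <- avg[rows, , drop = FALSE]
    if (pooled) {
      pool <- sort(as.vector(sub))
      naas[rows, ] <- findInterval(sub, pool, left.open = TRUE) /
        length(pool)
    } else {
      naas[rows, ] <- apply(sub, 2, function(x)
        (rank(x, ties.method = "min") - 1) / m)
    }
  }
  structure(list(naas = naas, bin = raw$bin, n_genes = raw$n_genes),
            class = "cytokine_profiles")
}

#' Immune Scores: category-level profile summaries
#'
#' Averages each disease's NAAS over the four cytokine categories
#' (inflammation-related, chemokines, growth factors, other), condensing a
#' full profile into four numbers. An empty category yields `NA` and a
#' message.
#'
#' @param profiles a `cytokine_profiles` object.
#' @param catalog a [cytokine_catalog()].
#' @return data.frame, one row per disease: `inflammation`, `chemokine`,
#'   `growth_factor`, `other`.
#' @export
immune_scores <- function(profiles, catalog) {
  naas <- profiles$naas
  cats <- c("inflammation", "chemokine", "growth_factor", "other")
  out <- matrix(NA_real_, nrow(naas), length(cats),
                dimnames = list(rownames(naas), cats))
  for (cc in cats) {
    members <- intersect(names(catalog$category)[catalog$category == cc],
                         colnames(naas))
    if (!length(members)) {
      message(sprintf("category '%s' empty; score absent", cc))
      next
    }
    out[, cc] <- rowMeans(naas[, members, drop = FALSE])
  }
  as.data.frame(out)
}

#' Hierarchically cluster cytokines by their association vectors
#'
#' Each cytokine is described by its Association-Score vector over all
#' non-cytokine genes; cytokines are clustered hierarchically (default:
#' average linkage on correlation distance) and the tree is cut into `k`
#' clusters. Every non-cytokine gene is then assigned to the cluster with
#' which its mean association is highest, provided that mean exceeds the
#' runner-up by `signature_margin` and exceeds `signature_floor`
#' (otherwise the gene lands in the `unassigned` class) -- these per-cluster
#' gene sets are the cluster signatures.
#'
#' @param emb an `embedded_network`.
#' @param catalog a [cytokine_catalog()].
#' @param k number of clusters (default 6).
#' @param linkage `hclust` method (default "average").
#' @param distance "correlation" (default), "cosine" or "euclidean".
#' @param signature_margin required lead of the best cluster mean over the
#'   second best (default 0: plain argmax).
#' @param signature_floor minimum best mean association for assignment
#'   (default 0.4).
#' @param universe optional gene universe; defaults to all embedded genes.
#' @return Object of class `cytokine_clustering`: `tree` (hclust),
#'   `labels` (named cluster ids), `signatures` (list of gene sets, one per
#'   cluster plus `unassigned`), `cluster_means` (k x genes matrix).
#' @export
cluster_cytokines <- function(emb, catalog, k = 6, linkage = "average",
                              distance = c("correlation", "cosine",
                                           "euclidean"),
                              signature_margin = 0, signature_floor = 0.4,
                              universe = NULL) {
  distance <- match.arg(distance)
  universe <- universe %||% rownames(emb$vectors)
  cyto <- intersect(catalog$cytokines, universe)
  if (k < 1 || k > length(cyto))
    stopf("k must be in [1, %d]", length(cyto))
  non_cyto <- setdiff(universe, catalog$cytokines)
  M <- score_block(emb, cyto, non_cyto)

  d <- switch(distance,
    correlation = {
      cm <- suppressWarnings(cor(t(M)))
      # constant association vectors have no defined correlation; identical
      # rows get distance 0, anything else the maximum (2)
      if (anyNA(cm)) {
        bad <- which(is.na(cm), arr.ind = TRUE)
        eq <- vapply(seq_len(nrow(bad)), function(r)
          isTRUE(all.equal(M[bad[r, 1], ], M[bad[r, 2], ])), TRUE)
        cm[bad] <- ifelse(eq, 1, -1)
      }
      stats::as.dist(1 - cm)
    },
    cosine = {
      mn <- normalize_rows(M, "association vector")
      stats::as.dist(1 - mn %*% t(mn))
    },
    euclidean = dist(M))

  tree <- hclust(d, method = linkage)
  labels <- cutree(tree, k = k)
  sizes <- tabulate(labels, nbins = k)
  cluster_means <- rowsum(M, labels) / sizes
  rownames(cluster_means) <- paste0("CLU", seq_len(k))

  if (k == 1) {
    best <- rep(1L, ncol(M)); lead <- rep(Inf, ncol(M))
    best_val <- cluster_means[1, ]
  } else {
    ord <- apply(cluster_means, 2, order, decreasing = TRUE)
    best <- ord[1, ]
    best_val <- cluster_means[cbind(best, seq_len(ncol(M)))]
    second_val <- cluster_means[cbind(ord[2, ], seq_len(ncol(M)))]
    lead <- best_val - second_val
  }
  assigned <- lead >= signature_margin & best_val >= signature_floor
  signatures <- lapply(seq_len(k), function(j)
    sort(colnames(M)[assigned & best == j]))
  names(signatures) <- paste0("SIG", seq_len(k))
  signatures$unassigned <- sort(colnames(M)[!assigned])

  structure(list(tree = tree, labels = labels, signatures = signatures,
                 cluster_means = cluster_means, k = k),
            class = "cytokine_clustering")
}

#' Export a cytokine dendrogram as Newick
#'
#' @param clustering a `cytokine_clustering`.
#' @param path output Newick path.
#' @export
export_dendrogram_newick <- function(clustering, path) {
  ape::write.tree(ape::as.phylo(clustering$tree), file = path)
  invisible(path)
}

#' Write a NAAS matrix to TSV
#'
#' @param profiles a `cytokine_profiles`.
#' @param path output path; diseases as rows, cytokines as columns, with a
#'   leading `disease_id` column and a trailing `bin` column.
#' @export
write_profiles <- function(profiles, path) {
  df <- data.frame(disease_id = rownames(profiles$naas), profiles$naas,
                   bin = as.character(profiles$bin),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_full(df, path)
}
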