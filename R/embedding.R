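#' Sample second-order random walks over a network
#'
#' Generates a node2vec-style walk corpus: every gene in the network is used
#' as the source of `num_walks` walks of length `walk_length`. Transitions
#' are second-order with return parameter `p` and in-out parameter `q`
#' (`p = q = 1` gives unbiased first-order walks, the default). Neighbor
#' choice is uniform -- edge confidences are not used as transition weights,
#' since the input is expected to be the already high-confidence subgraph
#' (`weighted = TRUE` switches to confidence-proportional transitions).
#' A gene with no neighbors yields a single-node walk (dead-end rule).
#'
#' @param net a [weighted_network()] (typically high-confidence filtered).
#' @param num_walks walks per source node (default 10).
#' @param walk_length nodes per walk (default 30).
#' @param p,q node2vec return / in-out parameters (default 1).
#' @param seed integer seed for the walk sampler.
#' @param weighted use confidence-proportional first-order transitions
#'   (forces `p = q = 1`).
#' @return Object of class `walk_corpus`: `walks` (list of integer vectors,
#'   1-based gene indices), `genes` (the index-to-symbol map), `params`.
#' @export
generate_walks <- function(net, num_walks = 10, walk_length = 30,
                           p = 1.0, q = 1.0, seed = 1, weighted = FALSE) {
  genes <- net$genes
  if (!length(genes)) stopf("empty universe: network has no genes")
  if (num_walks < 1 || walk_length < 1)
    stopf("num_walks and walk_length must be >= 1")
  ia <- match(net$edges$gene_a, genes)
  ib <- match(net$edges$gene_b, genes)
  n <- length(genes)
  adj <- vector("list", n)
  nb <- split(c(ib, ia), c(ia, ib))
  adj[as.integer(names(nb))] <- lapply(nb, function(v) sort(unique(v)) - 1L)
  empty <- vapply(adj, is.null, TRUE)
  adj[empty] <- list(integer())
  if (weighted) {
    if (p != 1 || q != 1)
      stopf("weighted transitions support only p = q = 1")
    walks <- weighted_walks_r(net, genes, num_walks, walk_length, seed)
  } else {
    walks <- cpp_node2vec_walks(adj, as.integer(num_walks),
                                as.integer(walk_length), p, q,
                                as.integer(seed))
    walks <- lapply(walks, function(w) w + 1L)
  }
  structure(list(walks = walks, genes = genes,
                 params = list(num_walks = num_walks,
                               walk_length = walk_length, p = p, q = q,
                               weighted = weighted, seed = seed)),
            class = "walk_corpus")
}

# Confidence-weighted first-order walks, plain R (config option; the
# default pipeline uses the unweighted C++ sampler).
weighted_walks_r <- function(net, genes, num_walks, walk_length, seed) {
  n <- length(genes)
  ia <- match(net$edges$gene_a, genes)
  ib <- match(net$edges$gene_b, genes)
  wts <- net$edges$confidence
  adj <- vector("list", n); wt <- vector("list", n)
  ends <- c(ib, ia); from <- c(ia, ib); ww <- c(wts, wts)
  sp <- split(seq_along(from), from)
  for (k in names(sp)) {
    i <- as.integer(k)
    adj[[i]] <- ends[sp[[k]]]
    wt[[i]] <- ww[sp[[k]]]
  }
  with_seed(seed, {
    out <- vector("list", num_walks * n)
    idx <- 1L
    for (r in seq_len(num_walks)) {
      for (s in seq_len(n)) {
        walk <- integer(walk_length); walk[1] <- s; len <- 1L
        while (len < walk_length) {
          cur <- walk[len]
          if (is.null(adj[[cur]]) || !length(adj[[cur]])) break
          len <- len + 1L
          walk[len] <- if (length(adj[[cur]]) == 1L) adj[[cur]] else
            sample(adj[[cur]], 1, prob = wt[[cur]])
        }
        out[[idx]] <- walk[seq_len(len)]; idx <- idx + 1L
      }
    }
    out
  })
}

#' Train gene embeddings from a walk corpus
#'
#' Skip-gram with negative sampling over the walk sentences, single-threaded
#' and seeded so training is exactly reproducible. With `min_count = 1`
#' every gene appearing in the corpus receives a vector; since every gene
#' sources its own walks, the whole universe is embedded.
#'
#' @param corpus a `walk_corpus` from [generate_walks()].
#' @param dim embedding dimension (default 64).
#' @param window skip-gram context half-window (default 10).
#' @param min_count minimum corpus frequency for inclusion (default 1).
#' @param epochs training passes over the corpus (default 5).
#' @param negative negative samples per positive pair (default 5).
#' @param alpha,min_alpha initial / floor learning rate.
#' @param seed integer seed for initialization and sampling.
#' @return Object of class `embedded_network`: `vectors` (genes x dim
#'   matrix with gene rownames), `params`.
#' @export
train_embedding <- function(corpus, dim = 64, window = 10, min_count = 1,
                            epochs = 5, negative = 5, alpha = 0.025,
                            min_alpha = 1e-4, seed = 1) {
  if (dim < 1 || window < 1) stopf("dim and window must be >= 1")
  if (!length(corpus$walks)) stopf("empty walk corpus")
  genes <- corpus$genes
  counts <- tabulate(unlist(corpus$walks), nbins = length(genes))
  keep <- counts >= min_count
  vocab <- genes[keep]
  remap <- match(seq_along(genes), which(keep))
  walks0 <- lapply(corpus$walks, function(w) {
    w <- remap[w]
    as.integer(w[!is.na(w)] - 1L)
  })
  vec <- cpp_sgns_train(walks0, length(vocab), as.integer(dim),
                        as.integer(window), as.integer(negative),
                        as.integer(epochs), alpha, min_alpha,
                        as.integer(seed))
  rownames(vec) <- vocab
  structure(list(vectors = vec,
                 params = c(corpus$params,
                            list(dim = dim, window = window,
                               min_count = min_count, epochs = epochs,
                               negative = negative, alpha = alpha,
                               min_alpha = min_alpha, train_seed = seed))),
            class = "embedded_network")
}

#' @export
print.embedded_network <- function(x, ...) {
  cat(sprintf("<embedded_network> %d genes x %d dims\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' Embed a high-confidence network end to end
#'
#' Composes [generate_walks()] and [train_embedding()] with the standard
#' hyperparameters (10 walks of length 30 per node, 64 dimensions, window
#' 10, min_count 1) and keeps the full parameter manifest on the result.
#'
#' @param net a high-confidence [weighted_network()].
#' @param dim,num_walks,walk_length,window,p,q,epochs hyperparameters; see
#'   [generate_walks()] and [train_embedding()].
#' @param seed integer seed shared by walk sampling and training.
#' @return An `embedded_network`.
#' @export
embed_network <- function(net, dim = 64, num_walks = 10, walk_length = 30,
                          window = 10, p = 1.0, q = 1.0, epochs = 5,
                          seed = 1) {
  if (!length(net$genes)) stopf("empty universe: nothing to embed")
  corpus <- generate_walks(net, num_walks = num_walks,
                           walk_length = walk_length, p = p, q = q,
                           seed = seed)
  train_embedding(corpus, dim = dim, window = window, epochs = epochs,
                  seed = seed)
}

#' Write an embedding to TSV plus a JSON parameter manifest
#'
#' @param emb an `embedded_network`.
#' @param path output TSV path (`gene` column followed by the coordinates);
#'   the manifest is written next to it as `<path>.manifest.json`.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(gene = rownames(emb$vectors), emb$vectors,
                   stringsAsFactors = FALSE)
  names(df) <- c("gene", sprintf("v%03d", seq_len(ncol(emb$vectors))))
  write_tsv_full(df, path)
  jsonlite::write_json(emb$params, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an embedding written by [write_embedding()]
#'
#' @param path TSV path.
#' @return An `embedded_network` (params restored from the manifest when
#'   present).
#' @export
read_embedding <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  vec <- as.matrix(df[, -1, drop = FALSE])
  dimnames(vec) <- list(df$gene, NULL)
  manifest <- paste0(path, ".manifest.json")
  params <- if (file.exists(manifest)) jsonlite::read_json(manifest,
                                                           simplifyVector = TRUE)
            else list()
  structure(list(vectors = vec, params = params),
            class = "embedded_network")
}
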