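#' Build a disease pathogenesis-cytokine subnetwork
#'
#' Connects a disease's pathogenesis genes to catalog cytokines wherever
#' the Association Score strictly exceeds `cutoff` (default 0.8), keeping
#' only nodes with at least one retained edge. The graph is bipartite by
#' construction: cytokine-cytokine and pathogenesis-pathogenesis edges are
#' never included. Disease genes that are themselves catalog cytokines sit
#' on the cytokine side only (logged), so they are not double-counted in
#' `Np`/`Ni`; pathogenesis genes are labeled `receptor` when on the
#' catalog's receptor list, else `disease_specific`.
#'
#' @param emb an `embedded_network`.
#' @param genes the disease's gene set (symbols, all embedded).
#' @param catalog a [cytokine_catalog()].
#' @param cutoff strict Association-Score threshold (default 0.8).
#' @return Object of class `disease_subnetwork`: `edges` (`pathogenesis`,
#'   `cytokine`, `score`), `pathogenesis` (data.frame `gene`, `label`),
#'   `cytokines`, `Np`, `Ni`, `cutoff`.
#' @export
build_subnetwork <- function(emb, genes, catalog, cutoff = 0.8) {
  genes <- unique(genes)
  own_cyto <- intersect(genes, catalog$cytokines)
  if (length(own_cyto))
    message(sprintf("%d disease gene(s) are catalog cytokines; placed on the cytokine side",
                    length(own_cyto)))
  path_genes <- setdiff(genes, catalog$cytokines)
  cyto <- intersect(catalog$cytokines, rownames(emb$vectors))
  empty <- structure(list(edges = data.frame(pathogenesis = character(),
                                             cytokine = character(),
                                             score = numeric()),
                          pathogenesis = data.frame(gene = character(),
                                                    label = character()),
                          cytokines = character(), Np = 0L, Ni = 0L,
                          cutoff = cutoff),
                     class = "disease_subnetwork")
  if (!length(path_genes) || !length(cyto)) return(empty)
  blk <- score_block(emb, path_genes, cyto)
  hit <- which(blk > cutoff, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  edges <- data.frame(pathogenesis = path_genes[hit[, 1]],
                      cytokine = cyto[hit[, 2]],
                      score = blk[hit], stringsAsFactors = FALSE)
  edges <- edges[order(edges$pathogenesis, edges$cytokine), ]
  rownames(edges) <- NULL
  p_nodes <- sort(unique(edges$pathogenesis))
  c_nodes <- sort(unique(edges$cytokine))
  structure(list(
    edges = edges,
    pathogenesis = data.frame(
      gene = p_nodes,
      label = ifelse(p_nodes %in% catalog$receptors, "receptor",
                     "disease_specific"),
      stringsAsFactors = FALSE),
    cytokines = c_nodes,
    Np = length(p_nodes), Ni = length(c_nodes), cutoff = cutoff),
    class = "disease_subnetwork")
}

#' @export
print.disease_subnetwork <- function(x, ...) {
  cat(sprintf("<disease_subnetwork> Np = %d, Ni = %d, %d edges (cutoff %g)\n",
              x$Np, x$Ni, nrow(x$edges), x$cutoff))
  invisible(x)
}

#' Immune Connection Density
#'
#' `L = (1 / (Np * Ni)) * sum(d_pi)` over the retained pathogenesis-to-
#' cytokine edges; only cross-type edges enter the sum. In the default
#' `weighted` mode `d_pi` is the edge's Association Score; `count` mode
#' scores each retained edge as 1 (plain edge counting). An empty
#' subnetwork has density 0.
#'
#' @param sub a `disease_subnetwork`.
#' @param mode `"weighted"` (default) or `"count"`.
#' @return The density, a non-negative number.
#' @export
icd <- function(sub, mode = c("weighted", "count")) {
  mode <- match.arg(mode)
  if (sub$Np == 0 || sub$Ni == 0) return(0)
  tot <- if (mode == "weighted") sum(sub$edges$score) else nrow(sub$edges)
  tot / (sub$Np * sub$Ni)
}

#' Recall of a disease's known cytokines in its subnetwork
#'
#' Known cytokines are the catalog cytokines appearing in the disease's
#' own gene set; recognized are those that made it into the subnetwork as
#' cytokine nodes.
#'
#' @param genes the disease's gene set.
#' @param sub a `disease_subnetwork`.
#' @param catalog a [cytokine_catalog()].
#' @return List: `recognized`, `known`, `recall` (`NA` flagged when no
#'   known cytokines).
#' @export
cytokine_recall <- function(genes, sub, catalog) {
  known <- intersect(unique(genes), catalog$cytokines)
  recognized <- intersect(known, sub$cytokines)
  list(recognized = length(recognized), known = length(known),
       recall = if (length(known) == 0) NA_real_
                else length(recognized) / length(known),
       undefined = length(known) == 0)
}

#' Fiedler sign-cut spectral partition
#'
#' Partitions a graph by the sign pattern of its Fiedler vector: the
#' eigenvector of the graph Laplacian at the algebraic connectivity (the
#' smallest eigenvalue after the trivial constant mode). Nodes with
#' `w > +tol` form the well-connected class, `w < -tol` the poorly
#' connected class, and `|w| <= tol` the articulation class. The sign is
#' oriented so the well-connected class carries the larger total degree
#' (larger entry sign on ties), making the output deterministic under the
#' eigensolver's global sign ambiguity. For a disconnected graph the
#' algebraic connectivity is 0 and the cut separates components.
#'
#' For a `disease_subnetwork` the Laplacian is unweighted by default
#' (adjacency of retained edges; `weighted = TRUE` uses the Association
#' Scores as weights) and `key_genes` reports the pathogenesis nodes in
#' the well-connected class. A symmetric adjacency matrix can be supplied
#' directly.
#'
#' @param x a `disease_subnetwork` or symmetric adjacency matrix with
#'   dimnames.
#' @param articulation_tol articulation threshold on `|w|`; default
#'   `1e-6 * max(abs(w))`.
#' @param weighted use edge weights in the Laplacian (subnetwork input
#'   only).
#' @return Object of class `partition_result`: `fiedler_value`,
#'   `fiedler_vector` (named unit vector), `classes` (named factor with
#'   levels well_connected / poorly_connected / articulation),
#'   `key_genes`, `key_receptors` (both `NULL` for plain matrix input).
#' @export
fiedler_partition <- function(x, articulation_tol = NULL, weighted = FALSE) {
  sub <- NULL
  if (inherits(x, "disease_subnetwork")) {
    sub <- x
    nodes <- c(sub$pathogenesis$gene, sub$cytokines)
    if (length(nodes) < 2) stopf("subnetwork has fewer than 2 nodes")
    A <- matrix(0, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
    w <- if (weighted) sub$edges$score else 1
    A[cbind(sub$edges$pathogenesis, sub$edges$cytokine)] <- w
    A[cbind(sub$edges$cytokine, sub$edges$pathogenesis)] <- w
  } else {
    A <- as.matrix(x)
    if (nrow(A) < 2) stopf("graph has fewer than 2 nodes")
    if (!isTRUE(all.equal(A, t(A)))) stopf("adjacency must be symmetric")
    if (is.null(rownames(A)))
      rownames(A) <- colnames(A) <- paste0("n", seq_len(nrow(A)))
  }
  n <- nrow(A)
  deg <- rowSums(A)
  comp <- graph_components(A)
  if (max(comp) > 1) {
    # Disconnected: algebraic connectivity is 0 and any zero-sum vector
    # constant on components is a Laplacian null vector orthogonal to the
    # trivial mode. Use the canonical two-level choice that contrasts the
    # largest-total-degree component against the rest, so the sign cut
    # separates components deterministically.
    cd <- tapply(deg, comp, sum)
    cs <- tabulate(comp)
    pick <- order(-cd, -cs)[1]
    inC <- comp == pick
    m <- sum(inC)
    w <- ifelse(inC, (n - m) / n, -m / n)
    w <- w / sqrt(sum(w^2))
    names(w) <- rownames(A)
    fiedler_value <- 0
  } else {
    L <- diag(deg) - A
    # Deflate the trivial constant mode: eigenvalues of L + c * J
    # (J = 1 1'/n) are those of L with the constant mode shifted from 0 up
    # to c, so the minimum of the shifted problem is the algebraic
    # connectivity and its eigenvector the Fiedler vector.
    c_shift <- 2 * max(deg) + 1
    Ls <- L + c_shift / n
    es <- eigen(Ls, symmetric = TRUE)
    k <- which.min(es$values)
    fiedler_value <- max(0, es$values[k])
    w <- es$vectors[, k]
    names(w) <- rownames(A)
  }

  tol <- articulation_tol %||% (1e-6 * max(abs(w)))
  pos_deg <- sum(deg[w > tol]); neg_deg <- sum(deg[w < -tol])
  flip <- (neg_deg > pos_deg) ||
    (neg_deg == pos_deg && w[which.max(abs(w))] < 0)
  if (flip) w <- -w
  cls <- factor(ifelse(w > tol, "well_connected",
                       ifelse(w < -tol, "poorly_connected", "articulation")),
                levels = c("well_connected", "poorly_connected",
                           "articulation"))
  names(cls) <- names(w)

  key_genes <- key_receptors <- NULL
  if (!is.null(sub)) {
    well <- names(cls)[cls == "well_connected"]
    pg <- sub$pathogenesis
    key_genes <- sort(intersect(well, pg$gene[pg$label == "disease_specific"]))
    key_receptors <- sort(intersect(well, pg$gene[pg$label == "receptor"]))
  }
  structure(list(fiedler_value = fiedler_value, fiedler_vector = w,
                 classes = cls, key_genes = key_genes,
                 key_receptors = key_receptors),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat(sprintf("<partition_result> Fiedler value %.4g; classes: %s\n",
              x$fiedler_value,
              paste(sprintf("%s = %d", levels(x$classes),
                            tabulate(x$classes, 3)), collapse = ", ")))
  invisible(x)
}

# Connected components of a symmetric adjacency matrix (BFS), returned as
# an integer component id per node.
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] != 0 & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Summarize spectral partitions across diseases
#'
#' One row per disease: receptors and disease-specific genes in the
#' well-connected module, the input gene-set size, and the percentage of
#' input genes retained in the module (one decimal place, the Table-style
#' presentation: 36 of 1,340 genes is 2.7%).
#'
#' @param partitions named list of `partition_result`s.
#' @param sets the matching `disease_sets` list.
#' @return data.frame: `disease_id`, `n_receptors_well`,
#'   `n_disease_genes_well`, `n_input_genes`, `pct_retained`.
#' @export
partition_summary <- function(partitions, sets) {
  rows <- lapply(names(partitions), function(d) {
    p <- partitions[[d]]
    n_r <- length(p$key_receptors %||% character())
    n_g <- length(p$key_genes %||% character())
    n_in <- length(sets[[d]])
    data.frame(disease_id = d, n_receptors_well = n_r,
               n_disease_genes_well = n_g, n_input_genes = n_in,
               pct_retained = round(100 * n_g / n_in, 1),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a disease subnetwork as edge-list TSV and GraphML
#'
#' The edge list carries the Association-Score weights; the GraphML file
#' adds a `type` node attribute (`receptor`, `disease_specific`,
#' `cytokine`) for downstream visualization tools.
#'
#' @param sub a `disease_subnetwork`.
#' @param path output stem; writes `<path>.tsv` and `<path>.graphml`.
#' @export
write_subnetwork <- function(sub, path) {
  write.table(sub$edges, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  nodes <- rbind(
    data.frame(id = sub$pathogenesis$gene, type = sub$pathogenesis$label,
               stringsAsFactors = FALSE),
    data.frame(id = sub$cytokines, type = "cytokine",
               stringsAsFactors = FALSE))
  con <- file(paste0(path, ".graphml"), "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="type" for="node" attr.name="type" attr.type="string"/>',
    '  <key id="score" for="edge" attr.name="score" attr.type="double"/>',
    '  <graph edgedefault="undirected">'), con)
  writeLines(sprintf('    <node id="%s"><data key="type">%s</data></node>',
                     nodes$id, nodes$type), con)
  if (nrow(sub$edges))
    writeLines(sprintf(
      '    <edge source="%s" target="%s"><data key="score">%.10g</data></edge>',
      sub$edges$pathogenesis, sub$edges$cytokine, sub$edges$score), con)
  writeLines(c('  </graph>', '</graphml>'), con)
  invisible(path)
}
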