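#' Weighted undirected gene network
#'
#' Container for a STRING-style interaction network: opaque gene symbols and
#' undirected edges carrying an integer confidence on the 0--1000 scale.
#' Edges are canonicalized so each unordered pair is stored once
#' (`gene_a < gene_b` lexicographically), self-loops are dropped with a
#' warning, and duplicate pairs collapse to their maximum confidence.
#'
#' @param edges data.frame with columns `gene_a`, `gene_b`, `confidence`.
#' @return An object of class `weighted_network` with elements `edges`
#'   (canonical edge table) and `genes` (sorted union of endpoint symbols).
#' @export
weighted_network <- function(edges = data.frame(gene_a = character(),
                                                gene_b = character(),
                                                confidence = integer())) {
  stopifnot(all(c("gene_a", "gene_b", "confidence") %in% names(edges)))
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  conf <- as.numeric(edges$confidence)
  if (any(!is.finite(conf)))
    stopf("non-numeric confidence value in edge table")
  if (any(conf < 0 | conf > 1000))
    stopf("confidence outside [0, 1000]: %s",
          paste(utils::head(conf[conf < 0 | conf > 1000], 3), collapse = ", "))

  loops <- a == b
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(loops)), call. = FALSE)
    a <- a[!loops]; b <- b[!loops]; conf <- conf[!loops]
  }
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp

  if (length(a)) {
    key <- paste(a, b, sep = "\r")
    keep <- tapply(conf, key, max)
    ord <- order(names(keep))
    keep <- keep[ord]
    parts <- strsplit(names(keep), "\r", fixed = TRUE)
    a <- vapply(parts, `[`, "", 1L)
    b <- vapply(parts, `[`, "", 2L)
    conf <- as.numeric(keep)
  }
  structure(
    list(edges = data.frame(gene_a = a, gene_b = b,
                            confidence = as.integer(round(conf)),
                            stringsAsFactors = FALSE),
         genes = sort(unique(c(a, b)))),
    class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat(sprintf("<weighted_network> %d genes, %d edges\n",
              length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Read a STRING-style edge list
#'
#' Parses a whitespace/tab-delimited file of `gene1 gene2 combined_score`
#' triples. A single header line is auto-detected (non-numeric score field)
#' and skipped. Duplicate pairs keep the maximum confidence; self-loops are
#' dropped with a warning.
#'
#' @param path file path.
#' @param score_scale maximum admissible confidence (default 1000).
#' @return A [weighted_network()].
#' @export
read_edge_list <- function(path, score_scale = 1000) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(weighted_network())
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  start <- 1L
  f1 <- fields[[1]]
  if (length(f1) >= 3L && is.na(suppressWarnings(as.numeric(f1[3]))))
    start <- 2L
  if (start > length(fields)) return(weighted_network())
  fields <- fields[start:length(fields)]
  nf <- lengths(fields)
  bad <- which(nf < 3L)
  if (length(bad))
    stopf("unparseable edge-list line %d in %s (need 3 fields)",
          bad[1] + start - 1L, path)
  a <- vapply(fields, `[`, "", 1L)
  b <- vapply(fields, `[`, "", 2L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  if (anyNA(s))
    stopf("unparseable confidence on line %d in %s",
          which(is.na(s))[1] + start - 1L, path)
  if (any(s < 0 | s > score_scale))
    stopf("confidence outside [0, %d] on line %d in %s", score_scale,
          which(s < 0 | s > score_scale)[1] + start - 1L, path)
  weighted_network(data.frame(gene_a = a, gene_b = b, confidence = s,
                              stringsAsFactors = FALSE))
}

#' Write an edge list to TSV
#'
#' @param net a [weighted_network()].
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  df <- net$edges
  names(df) <- c("gene1", "gene2", "combined_score")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Retain high-confidence edges
#'
#' Keeps edges with confidence at or above `cutoff` (the canonical
#' STRING-style high-confidence filter; edges *below* the cutoff are the
#' ones excluded). Idempotent and monotone in `cutoff`.
#'
#' @param net a [weighted_network()].
#' @param cutoff inclusive confidence threshold, default 800.
#' @return A filtered [weighted_network()].
#' @export
filter_high_confidence <- function(net, cutoff = 800) {
  weighted_network(net$edges[net$edges$confidence >= cutoff, , drop = FALSE])
}

#' Gene universe of a filtered network
#'
#' Genes incident to at least one retained edge, in deterministic
#' (lexicographic) order.
#'
#' @param net a [weighted_network()] (typically already high-confidence
#'   filtered).
#' @return Character vector of gene symbols.
#' @export
select_universe <- function(net) {
  sort(unique(c(net$edges$gene_a, net$edges$gene_b)))
}

#' Read a disease-to-gene table
#'
#' Parses a TSV of `disease_id<TAB>gene` rows (optional header
#' auto-detected by the literal column name "disease_id"), intersects each
#' gene set with `universe`, and drops diseases left with fewer than two
#' genes (the minimum set size the profile statistics require), reporting
#' the dropped count.
#'
#' @param path file path.
#' @param universe character vector of admissible gene symbols.
#' @return Named list of character gene vectors, class `disease_sets`.
#' @export
read_disease_sets <- function(path, universe) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   col.names = c("disease_id", "gene"),
                   colClasses = "character", fill = FALSE)
  if (nrow(df) && df$disease_id[1] == "disease_id")
    df <- df[-1, , drop = FALSE]
  if (any(!nzchar(df$disease_id)) || any(!nzchar(df$gene)))
    stopf("malformed disease table row in %s", path)
  sets <- lapply(split(df$gene, df$disease_id),
                 function(g) sort(unique(g)))
  disease_sets(sets, universe)
}

#' Construct disease gene sets against a universe
#'
#' @param sets named list of character gene vectors.
#' @param universe admissible gene symbols; sets are intersected with it.
#' @param min_size minimum surviving set size (default 2).
#' @return Named list of gene vectors, class `disease_sets`.
#' @export
disease_sets <- function(sets, universe, min_size = 2) {
  sets <- lapply(sets, function(g) sort(intersect(unique(g), universe)))
  keep <- lengths(sets) >= min_size
  if (any(!keep))
    message(sprintf("dropped %d disease(s) with < %d genes in universe",
                    sum(!keep), min_size))
  structure(sets[keep], class = "disease_sets")
}

#' Write a disease-to-gene table to TSV
#'
#' @param sets a `disease_sets` list.
#' @param path output path.
#' @export
write_disease_sets <- function(sets, path) {
  df <- data.frame(
    disease_id = rep(names(sets), lengths(sets)),
    gene = unlist(sets, use.names = FALSE),
    stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cytokine catalog
#'
#' The fixed list of essential cytokines, their category labels
#' (`inflammation`, `chemokine`, `growth_factor`, `other`) and the separate
#' cytokine-receptor gene list. Categories partition the cytokine list;
#' receptors must be disjoint from cytokines.
#'
#' @param cytokines ordered character vector of cytokine gene symbols.
#' @param category named character vector mapping each cytokine to its
#'   category.
#' @param receptors character vector of receptor gene symbols.
#' @return Object of class `cytokine_catalog`.
#' @export
cytokine_catalog <- function(cytokines, category, receptors = character()) {
  cytokines <- as.character(cytokines)
  if (anyDuplicated(cytokines)) stopf("duplicated cytokine symbols")
  if (!all(cytokines %in% names(category)))
    stopf("category missing for: %s",
          paste(setdiff(cytokines, names(category)), collapse = ", "))
  category <- category[cytokines]
  valid <- c("inflammation", "chemokine", "growth_factor", "other")
  if (!all(category %in% valid))
    stopf("unknown category: %s",
          paste(setdiff(category, valid), collapse = ", "))
  receptors <- sort(unique(as.character(receptors)))
  if (length(intersect(receptors, cytokines)))
    stopf("receptors must be disjoint from cytokines")
  structure(list(cytokines = cytokines,
                 category = setNames(as.character(category), cytokines),
                 receptors = receptors),
            class = "cytokine_catalog")
}

#' @export
print.cytokine_catalog <- function(x, ...) {
  cat(sprintf("<cytokine_catalog> %d cytokines (%s), %d receptors\n",
              length(x$cytokines),
              paste(sprintf("%s: %d", names(table(x$category)),
                            table(x$category)), collapse = ", "),
              length(x$receptors)))
  invisible(x)
}

#' Read a cytokine catalog from TSV
#'
#' Expects columns `gene<TAB>category<TAB>receptor` where `receptor` is 0/1;
#' receptor rows carry category `receptor` weight 1 in the flag column and
#' are excluded from the cytokine list. An optional header is auto-detected.
#'
#' @param path file path.
#' @return A [cytokine_catalog()].
#' @export
read_catalog <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   col.names = c("gene", "category", "receptor"),
                   colClasses = "character")
  if (nrow(df) && df$gene[1] == "gene") df <- df[-1, , drop = FALSE]
  flag <- df$receptor == "1"
  cyto <- df[!flag, , drop = FALSE]
  cytokine_catalog(cyto$gene, setNames(cyto$category, cyto$gene),
                   df$gene[flag])
}

#' Write a cytokine catalog to TSV
#'
#' @param catalog a [cytokine_catalog()].
#' @param path output path.
#' @export
write_catalog <- function(catalog, path) {
  df <- rbind(
    data.frame(gene = catalog$cytokines,
               category = unname(catalog$category),
               receptor = 0L, stringsAsFactors = FALSE),
    data.frame(gene = catalog$receptors,
               category = "receptor",
               receptor = 1L, stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a literature co-occurrence frequency table
#'
#' TSV of `disease_id<TAB>cytokine<TAB>frequency` rows with frequencies in
#' \[0, 1\]; only sampled (present) entries appear. Optional header
#' auto-detected by a non-numeric frequency field.
#'
#' @param path file path.
#' @return data.frame with columns `disease_id`, `cytokine`, `frequency`.
#' @export
read_literature_freq <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.table(path, sep = "\t", header = FALSE, quote = "",
                   col.names = c("disease_id", "cytokine", "frequency"),
                   colClasses = "character")
  if (nrow(df) && is.na(suppressWarnings(as.numeric(df$frequency[1]))))
    df <- df[-1, , drop = FALSE]
  df$frequency <- as.numeric(df$frequency)
  if (anyNA(df$frequency) || any(df$frequency < 0 | df$frequency > 1))
    stopf("frequency outside [0, 1] in %s", path)
  rownames(df) <- NULL
  df
}

#' Write a literature frequency table to TSV
#'
#' @param freq data.frame with `disease_id`, `cytokine`, `frequency`.
#' @param path output path.
#' @export
write_literature_freq <- function(freq, path) {
  write_tsv_full(freq[, c("disease_id", "cytokine", "frequency")], path)
}
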