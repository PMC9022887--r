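#' Generate a planted-partition gene network with STRING-like confidences
#'
#' Builds an undirected planted-partition (stochastic-block-model) graph:
#' genes are split into modules, pairs within a module are connected with
#' probability `p_in` and pairs across modules with `p_out < p_in`. Each
#' edge carries an integer confidence drawn from `confidence_model`:
#' within-module edges from the high-confidence range (default
#' Uniform\{800..1000\}), between-module edges from the low range (default
#' Uniform\{150..799\}), reproducing the high/low confidence dichotomy at
#' the usual cutoff of 800.
#'
#' @param module_sizes integer vector of module sizes (each >= 2); the
#'   number of modules is its length.
#' @param p_in,p_out within/between-module edge probabilities; `p_in` must
#'   exceed `p_out` or the planted structure is unrecoverable.
#' @param confidence_model list with integer ranges `within` and `between`
#'   (each `c(lo, hi)` on the 0--1000 scale).
#' @param seed integer seed; the same seed reproduces the network exactly.
#' @param gene_prefix prefix for generated gene symbols.
#' @return List with `network` (a [weighted_network()]) and `modules`
#'   (named integer vector: gene -> module id).
#' @export
make_modular_network <- function(module_sizes, p_in, p_out,
                                 confidence_model = list(within = c(800, 1000),
                                                         between = c(150, 799)),
                                 seed = 1, gene_prefix = "G") {
  if (any(module_sizes < 2)) stopf("every module size must be >= 2")
  if (!(p_in > p_out)) stopf("p_in must exceed p_out (got %g <= %g)", p_in, p_out)
  n <- sum(module_sizes)
  genes <- sprintf("%s%04d", gene_prefix, seq_len(n))
  modules <- setNames(rep(seq_along(module_sizes), module_sizes), genes)

  with_seed(seed, {
    idx <- utils::combn(n, 2)
    i <- idx[1, ]; j <- idx[2, ]
    same <- modules[i] == modules[j]
    keep <- runif(length(i)) < ifelse(same, p_in, p_out)
    i <- i[keep]; j <- j[keep]; same <- same[keep]
    conf <- integer(length(i))
    w <- confidence_model$within; b <- confidence_model$between
    # draw uniformly on the closed integer range (sample(seq(x, x)) would
    # fall into sample()'s scalar expansion)
    runif_int <- function(n, lo, hi) lo + sample.int(hi - lo + 1L, n,
                                                     replace = TRUE) - 1L
    conf[same]  <- runif_int(sum(same), w[1], w[2])
    conf[!same] <- runif_int(sum(!same), b[1], b[2])
    net <- weighted_network(data.frame(gene_a = genes[i], gene_b = genes[j],
                                       confidence = conf,
                                       stringsAsFactors = FALSE))
    # isolated genes still belong to the universe of symbols
    net$genes <- genes
    list(network = net, modules = modules)
  })
}

#' Designate planted cytokine families in a modular network
#'
#' Marks the first `n_families` modules as cytokine families and samples
#' `per_family` member genes of each as cytokines; families are mapped
#' round-robin onto the four catalog categories. Receptors are sampled from
#' the remaining (non-cytokine) genes of the cytokine modules, mimicking
#' receptors co-functioning with their ligands.
#'
#' @param modules named integer vector (gene -> module id).
#' @param n_families number of cytokine families (planted clusters).
#' @param per_family cytokines sampled per family.
#' @param n_receptors receptor genes sampled overall.
#' @param seed integer seed.
#' @return List with `catalog` (a [cytokine_catalog()]) and `family`
#'   (named integer vector: cytokine -> module id of its planted family).
#' @export
make_cytokine_catalog <- function(modules, n_families = 4, per_family = 10,
                                  n_receptors = 20, seed = 1) {
  mod_ids <- sort(unique(modules))
  if (n_families > length(mod_ids))
    stopf("n_families exceeds the number of modules")
  fams <- mod_ids[seq_len(n_families)]
  cats <- rep(c("inflammation", "chemokine", "growth_factor", "other"),
              length.out = n_families)
  with_seed(seed, {
    cyto <- character(); fam <- integer(); cat_of <- character()
    for (k in seq_along(fams)) {
      members <- names(modules)[modules == fams[k]]
      if (per_family > length(members))
        stopf("per_family exceeds module size")
      pick <- sort(sample(members, per_family))
      cyto <- c(cyto, pick)
      fam <- c(fam, rep(fams[k], per_family))
      cat_of <- c(cat_of, rep(cats[k], per_family))
    }
    pool <- setdiff(names(modules)[modules %in% fams], cyto)
    receptors <- sort(sample(pool, min(n_receptors, length(pool))))
    list(catalog = cytokine_catalog(cyto, setNames(cat_of, cyto), receptors),
         family = setNames(fam, cyto))
  })
}

#' Generate disease gene sets with a planted size-bin structure
#'
#' Samples `n_diseases` gene sets whose sizes follow the four standard
#' disease-size bins (2--9, 10--19, 20--49, >49) in the proportions
#' `bin_mix`. A fraction `enriched_fraction` of diseases is *enriched*:
#' their genes are preferentially drawn from one planted cytokine family's
#' module (probability mass `enrichment` on that module), which plants a
#' true disease-cytokine affinity the downstream profile statistics should
#' recover. The remaining diseases draw genes uniformly (null diseases).
#'
#' @param n_diseases number of diseases.
#' @param bin_mix length-4 proportions over the size bins; must sum to 1.
#' @param gene_universe admissible gene symbols.
#' @param seed integer seed.
#' @param enriched_fraction fraction of diseases with planted affinity.
#' @param modules named module assignment (required when
#'   `enriched_fraction > 0`).
#' @param families module ids usable as enrichment targets (the cytokine
#'   families).
#' @param enrichment probability mass an enriched disease puts on its
#'   target module.
#' @param max_size upper bound for the >49 bin (default 80).
#' @return A `disease_sets` list with attributes `target_family` (named
#'   vector, `NA` for null diseases).
#' @export
make_disease_sets <- function(n_diseases, bin_mix, gene_universe, seed = 1,
                              enriched_fraction = 0, modules = NULL,
                              families = NULL, enrichment = 0.8,
                              max_size = 80) {
  if (abs(sum(bin_mix) - 1) > 1e-8 || length(bin_mix) != 4)
    stopf("bin_mix must be 4 proportions summing to 1")
  lo <- c(2, 10, 20, 50)
  hi <- c(9, 19, 49, max_size)
  if (max(hi) > length(gene_universe))
    stopf("requested set size exceeds the gene universe (%d > %d)",
          max(hi), length(gene_universe))
  with_seed(seed, {
    n_enr <- round(n_diseases * enriched_fraction)
    if (n_enr > 0 && (is.null(modules) || is.null(families)))
      stopf("modules and families are required for enriched diseases")
    ids <- sprintf("D%04d", seq_len(n_diseases))
    bins <- sample(1:4, n_diseases, replace = TRUE, prob = bin_mix)
    target <- rep(NA_integer_, n_diseases)
    if (n_enr > 0)
      target[seq_len(n_enr)] <- sample(rep(families, length.out = n_enr))
    in_univ <- gene_universe
    sets <- vector("list", n_diseases)
    for (d in seq_len(n_diseases)) {
      size <- sample(seq(lo[bins[d]], hi[bins[d]]), 1)
      if (is.na(target[d])) {
        sets[[d]] <- sort(sample(in_univ, size))
      } else {
        inside <- modules[in_univ] == target[d]
        w <- ifelse(inside, enrichment / sum(inside),
                    (1 - enrichment) / sum(!inside))
        sets[[d]] <- sort(sample(in_univ, size, prob = w))
      }
    }
    names(sets) <- names(target) <- ids
    out <- structure(sets, class = "disease_sets")
    attr(out, "target_family") <- target
    out
  })
}

#' Planted disease-by-cytokine affinity
#'
#' The ground-truth affinity is planted by design, not read off the
#' realized gene draws: an enriched disease has affinity `enrichment` for
#' every cytokine of its target family and the residual mass
#' `(1 - enrichment) / (k - 1)` for the other families' cytokines; a null
#' disease (no target) has the flat value `1 / k` for all cytokines, so
#' after the literature noise model its frequencies carry no rank signal.
#'
#' @param target_family named vector disease -> target family module id
#'   (`NA` for null diseases).
#' @param cytokine_family named vector cytokine -> family module id.
#' @param enrichment the planted affinity of an enriched disease for its
#'   target family's cytokines.
#' @return Numeric matrix (diseases x cytokines) in \[0, 1\].
#' @export
planted_affinity <- function(target_family, cytokine_family,
                             enrichment = 0.8) {
  cyto <- names(cytokine_family)
  k <- length(unique(cytokine_family))
  base_enr <- if (k > 1) (1 - enrichment) / (k - 1) else enrichment
  aff <- matrix(1 / k, length(target_family), length(cyto),
                dimnames = list(names(target_family), cyto))
  for (d in which(!is.na(target_family))) {
    aff[d, ] <- ifelse(cytokine_family == target_family[d],
                       enrichment, base_enr)
  }
  aff
}

#' Generate a literature co-occurrence frequency table from planted affinity
#'
#' Emulates a literature-mining frequency resource: frequencies are a
#' monotone transform of the true affinity (identity, the simplest
#' rank-preserving choice) plus Gaussian noise, clipped to \[0, 1\]; a
#' `dropout` fraction of entries is marked unsampled and omitted from the
#' output, mirroring the partial coverage of real literature resources.
#'
#' @param affinity numeric matrix (diseases x cytokines) in \[0, 1\].
#' @param noise_sd standard deviation of additive Gaussian noise (>= 0).
#' @param dropout fraction of entries left unsampled, in \[0, 1).
#' @param seed integer seed.
#' @return Long data.frame `disease_id`, `cytokine`, `frequency` containing
#'   only sampled entries.
#' @export
make_literature_freq <- function(affinity, noise_sd = 0.05, dropout = 0,
                                 seed = 1) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  with_seed(seed, {
    freq <- affinity + rnorm(length(affinity), sd = noise_sd)
    freq <- pmin(1, pmax(0, freq))
    sampled <- runif(length(freq)) >= dropout
    df <- data.frame(
      disease_id = rep(rownames(affinity), ncol(affinity)),
      cytokine = rep(colnames(affinity), each = nrow(affinity)),
      frequency = as.vector(freq),
      stringsAsFactors = FALSE)[as.vector(sampled), ]
    df <- df[order(df$disease_id, df$cytokine), ]
    rownames(df) <- NULL
    df
  })
}

#' Generate a complete synthetic world
#'
#' One call produces every input artifact the pipeline consumes: a modular
#' gene network with STRING-like confidences, a cytokine catalog with
#' planted families, disease gene sets (a mix of affinity-enriched and null
#' diseases), the planted true affinity, and a noisy literature frequency
#' table. Pure function of `seed` and its parameters. The defaults are the
#' demonstration scale: 500 genes in 10 modules, 40 cytokines in 4 planted
#' families, 60 diseases (half enriched).
#'
#' @param module_sizes module sizes for [make_modular_network()].
#' @param p_in,p_out within/between-module edge probabilities.
#' @param n_cytokine_families,cytokines_per_family,n_receptors catalog shape.
#' @param n_diseases,bin_mix,enriched_fraction,enrichment disease-set shape.
#' @param noise_sd,dropout literature-frequency noise model.
#' @param seed master seed; stage seeds are derived from it.
#' @return Object of class `synthetic_world`: `network`, `modules`,
#'   `catalog`, `cytokine_family`, `diseases`, `target_family`, `affinity`,
#'   `literature`, `seed`, `params`.
#' @export
make_world <- function(module_sizes = rep(50, 10), p_in = 0.6, p_out = 0.02,
                       n_cytokine_families = 4, cytokines_per_family = 10,
                       n_receptors = 20, n_diseases = 60,
                       bin_mix = c(0.42, 0.25, 0.20, 0.13),
                       enriched_fraction = 0.5, enrichment = 0.8,
                       noise_sd = 0.05, dropout = 0, seed = 1) {
  params <- list(module_sizes = module_sizes, p_in = p_in, p_out = p_out,
                 n_cytokine_families = n_cytokine_families,
                 cytokines_per_family = cytokines_per_family,
                 n_receptors = n_receptors, n_diseases = n_diseases,
                 bin_mix = bin_mix, enriched_fraction = enriched_fraction,
                 enrichment = enrichment, noise_sd = noise_sd,
                 dropout = dropout, seed = seed)
  net <- make_modular_network(module_sizes, p_in, p_out, seed = seed)
  cat <- make_cytokine_catalog(net$modules, n_cytokine_families,
                               cytokines_per_family, n_receptors,
                               seed = seed + 1L)
  universe <- select_universe(filter_high_confidence(net$network))
  dis <- make_disease_sets(n_diseases, bin_mix, universe, seed = seed + 2L,
                           enriched_fraction = enriched_fraction,
                           modules = net$modules,
                           families = sort(unique(cat$family)),
                           enrichment = enrichment)
  aff <- planted_affinity(attr(dis, "target_family"), cat$family,
                          enrichment = enrichment)
  lit <- make_literature_freq(aff, noise_sd = noise_sd, dropout = dropout,
                              seed = seed + 3L)
  structure(list(network = net$network, modules = net$modules,
                 catalog = cat$catalog, cytokine_family = cat$family,
                 diseases = dis, target_family = attr(dis, "target_family"),
                 affinity = aff, literature = lit,
                 seed = seed, params = params),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d genes, %d edges, %d cytokines,",
                     " %d diseases (seed %d)\n"),
              length(x$network$genes), nrow(x$network$edges),
              length(x$catalog$cytokines), length(x$diseases), x$seed))
  invisible(x)
}

#' Write a synthetic world to a directory
#'
#' Emits the four standard input tables (`edges.tsv`, `diseases.tsv`,
#' `catalog.tsv`, `literature_freq.tsv`) plus `manifest.json` recording the
#' generator parameters and seed, so a world directory is a complete,
#' re-readable pipeline input.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_edge_list(world$network, file.path(dir, "edges.tsv"))
  write_disease_sets(world$diseases, file.path(dir, "diseases.tsv"))
  write_catalog(world$catalog, file.path(dir, "catalog.tsv"))
  write_literature_freq(world$literature, file.path(dir, "literature_freq.tsv"))
  jsonlite::write_json(world$params, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
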