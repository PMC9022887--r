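#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults at the
#' standard values: confidence cutoff 800, 10 walks of length 30 per node,
#' 64 embedding dimensions, window 10, Association-Score cutoff 0.8 for
#' subnetworks, Bonferroni alpha 0.05. The configuration is serialized
#' verbatim into the run manifest.
#'
#' @param confidence_cutoff high-confidence edge threshold (default 800).
#' @param dim,num_walks,walk_length,window,p,q,epochs embedding
#'   hyperparameters.
#' @param score_cutoff subnetwork Association-Score threshold (default 0.8).
#' @param alpha family-wise error level (default 0.05).
#' @param validation_mode p-value mode for [validate_profiles()].
#' @param n_perm Monte-Carlo permutations when applicable.
#' @param k_clusters cytokine cluster count (default 6).
#' @param naas_recall_cutoff NAAS threshold for recall reporting.
#' @param freq_cutoff literature frequency threshold for known flags.
#' @param seed master seed.
#' @return Named list of class `run_config`.
#' @export
run_config <- function(confidence_cutoff = 800, dim = 64, num_walks = 10,
                       walk_length = 30, window = 10, p = 1.0, q = 1.0,
                       epochs = 5, score_cutoff = 0.8, alpha = 0.05,
                       validation_mode = "asymptotic", n_perm = 1e5,
                       k_clusters = 6, naas_recall_cutoff = 0.8,
                       freq_cutoff = 0.005, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline on a world directory
#'
#' Executes every stage in order -- read + confidence filter, embedding,
#' profiles (raw averages, NAAS, Immune Scores), cytokine clustering,
#' literature validation, subnetworks with density and recall, spectral
#' partition -- writing each stage's output as a plain file under
#' `out_dir` and recording counts, parameters and output MD5 hashes in
#' `manifest.json`. Reruns with an identical configuration and inputs
#' reproduce identical hashes.
#'
#' @param world_dir directory holding `edges.tsv`, `diseases.tsv`,
#'   `catalog.tsv` and (optionally) `literature_freq.tsv` (see
#'   [write_world()] for the formats).
#' @param out_dir output directory (created).
#' @param config a [run_config()].
#' @return Invisibly, a list with all in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(world_dir, out_dir, config = run_config()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_line <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  need <- file.path(world_dir, c("edges.tsv", "diseases.tsv", "catalog.tsv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stopf("stage netio: input file not found: %s", missing[1])

  # -- netio ---------------------------------------------------------------
  net <- read_edge_list(file.path(world_dir, "edges.tsv"))
  high <- filter_high_confidence(net, config$confidence_cutoff)
  universe <- select_universe(high)
  high$genes <- universe
  catalog <- read_catalog(file.path(world_dir, "catalog.tsv"))
  diseases <- read_disease_sets(file.path(world_dir, "diseases.tsv"),
                                universe)
  log_line("netio", "%d genes, %d high-confidence edges (cutoff %d), %d diseases",
           length(universe), nrow(high$edges), config$confidence_cutoff,
           length(diseases))

  # -- embedding -----------------------------------------------------------
  emb <- embed_network(high, dim = config$dim, num_walks = config$num_walks,
                       walk_length = config$walk_length,
                       window = config$window, p = config$p, q = config$q,
                       epochs = config$epochs, seed = config$seed)
  write_embedding(emb, file.path(out_dir, "embedding.tsv"))
  log_line("embedding", "%d genes embedded in %d dimensions",
           nrow(emb$vectors), ncol(emb$vectors))

  # -- profiles ------------------------------------------------------------
  raw <- raw_profiles(emb, diseases, catalog)
  profiles <- naas_normalize(raw)
  write_profiles(profiles, file.path(out_dir, "naas.tsv"))
  scores4 <- immune_scores(profiles, catalog)
  write.table(data.frame(disease_id = rownames(scores4), scores4),
              file.path(out_dir, "immune_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  clustering <- cluster_cytokines(emb, catalog, k = config$k_clusters,
                                  universe = universe)
  write.table(data.frame(cytokine = names(clustering$labels),
                         cluster = unname(clustering$labels)),
              file.path(out_dir, "cytokine_clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  export_dendrogram_newick(clustering,
                           file.path(out_dir, "cytokine_dendrogram.nwk"))
  log_line("profiles", "%d disease profiles over %d cytokines; %d clusters",
           nrow(profiles$naas), ncol(profiles$naas), config$k_clusters)

  # -- validation ----------------------------------------------------------
  validation <- NULL
  lit_path <- file.path(world_dir, "literature_freq.tsv")
  if (file.exists(lit_path)) {
    lit <- read_literature_freq(lit_path)
    validation <- validate_profiles(profiles, lit,
                                    mode = config$validation_mode,
                                    n_perm = config$n_perm,
                                    seed = config$seed)
    cutoff <- corrected_cutoff(config$alpha, nrow(validation))
    validation$validated <- !is.na(validation$p_value) &
      validation$p_value < cutoff & validation$rho > 0
    write.table(validation, file.path(out_dir, "validation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    log_line("validation", "%d of %d diseases validated at p < %.3g",
             sum(validation$validated), nrow(validation), cutoff)
  }

  # -- subnetworks + partition ---------------------------------------------
  subnets <- lapply(diseases, function(g)
    suppressMessages(build_subnetwork(emb, g, catalog,
                                      cutoff = config$score_cutoff)))
  summary_rows <- lapply(names(subnets), function(d) {
    s <- subnets[[d]]
    rec <- cytokine_recall(diseases[[d]], s, catalog)
    data.frame(disease_id = d, Np = s$Np, Ni = s$Ni,
               n_receptors = sum(s$pathogenesis$label == "receptor"),
               n_disease_genes = sum(s$pathogenesis$label ==
                                       "disease_specific"),
               icd = icd(s), recognized = rec$recognized,
               known = rec$known, recall = rec$recall,
               stringsAsFactors = FALSE)
  })
  subnet_summary <- do.call(rbind, summary_rows)
  write.table(subnet_summary, file.path(out_dir, "subnetworks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  partitions <- list()
  for (d in names(subnets)) {
    s <- subnets[[d]]
    if (s$Np + s$Ni >= 2)
      partitions[[d]] <- fiedler_partition(s)
  }
  part_summary <- if (length(partitions))
    partition_summary(partitions, diseases)
  else data.frame()
  write.table(part_summary, file.path(out_dir, "partition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  log_line("subnetwork", "%d non-empty subnetworks, %d partitioned",
           sum(subnet_summary$Np > 0), length(partitions))

  # -- manifest ------------------------------------------------------------
  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    config = unclass(config),
    counts = list(genes = length(universe),
                  high_confidence_edges = nrow(high$edges),
                  all_pairs = all_pair_count(length(universe)),
                  cytokines = length(catalog$cytokines),
                  non_cytokine_genes = non_cytokine_count(
                    length(universe), length(intersect(catalog$cytokines,
                                                       universe))),
                  diseases = length(diseases)),
    outputs = as.list(setNames(unname(tools::md5sum(sort(outputs))),
                               basename(sort(outputs)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(network = net, high = high, universe = universe,
                 catalog = catalog, diseases = diseases, embedding = emb,
                 raw = raw, profiles = profiles, immune_scores = scores4,
                 clustering = clustering, validation = validation,
                 subnetworks = subnets, subnet_summary = subnet_summary,
                 partitions = partitions, partition_summary = part_summary,
                 manifest = manifest))
}

#' One-command synthetic demonstration
#'
#' Generates a synthetic world at the demonstration scale (500 genes, 40
#' cytokines in 4 planted families, 60 diseases), writes it under
#' `dir/world`, and runs the full pipeline into `dir/out`.
#'
#' @param dir working directory for the demo.
#' @param seed master seed.
#' @param config a [run_config()]; its `k_clusters` defaults to the
#'   planted family count here.
#' @param ... passed to [make_world()].
#' @return The [run_pipeline()] result, with the generating `world`
#'   attached.
#' @export
run_demo <- function(dir = tempfile("cytonet_demo"), seed = 1,
                     config = run_config(seed = seed, k_clusters = 4), ...) {
  world <- make_world(seed = seed, ...)
  write_world(world, file.path(dir, "world"))
  res <- run_pipeline(file.path(dir, "world"), file.path(dir, "out"),
                      config = config)
  res$world <- world
  invisible(res)
}
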