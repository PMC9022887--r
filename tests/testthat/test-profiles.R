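test_that("non-cytokine gene counting enforces its bounds", {
  expect_equal(non_cytokine_count(14707, 126), 14581)
  expect_equal(non_cytokine_count(10, 10), 0)
  expect_error(non_cytokine_count(5, 6), "exceeds")
})

test_that("bin assignment matches the canonical boundaries", {
  expect_equal(as.character(assign_bin(c(2, 9, 10, 19, 20, 49, 50, 2000))),
               c("2-9", "2-9", "10-19", "10-19", "20-49", "20-49",
                 ">49", ">49"))
  expect_error(assign_bin(1), ">= 2")
})

test_that("raw profiles average pairwise scores with cytokine self-exclusion", {
  ang <- setNames(c(0, acos(0.2), -acos(0.6), acos(0.3)),
                  c("cy", "A", "B", "C"))
  emb <- angle_embedding(ang)
  catalog <- toy_catalog("cy")
  sets <- structure(list(d1 = c("A", "B"), d2 = c("A", "B", "C")),
                    class = "disease_sets")
  raw <- raw_profiles(emb, sets, catalog)
  expect_equal(unname(raw$avg["d1", "cy"]), 0.4, tolerance = 1e-12)

  # the cytokine inside its own set contributes no self-pair
  sets2 <- structure(list(d = c("cy", "C")), class = "disease_sets")
  raw2 <- suppressMessages(raw_profiles(emb, sets2, catalog))
  expect_equal(unname(raw2$avg["d", "cy"]), 0.3, tolerance = 1e-12)
  raw3 <- raw_profiles(emb, sets2, catalog, exclude_self = FALSE)
  expect_equal(unname(raw3$avg["d", "cy"]), (1 + 0.3) / 2, tolerance = 1e-12)
})

make_raw <- function(avg, n_genes) {
  structure(list(avg = avg,
                 n_genes = setNames(n_genes, rownames(avg)),
                 bin = assign_bin(n_genes)),
            class = "raw_profiles")
}

test_that("NAAS is the strict within-bin per-cytokine empirical CDF", {
  avg <- matrix(c(0.1, 0.2, 0.3), 3, 1,
                dimnames = list(c("d1", "d2", "d3"), "cy"))
  prof <- naas_normalize(make_raw(avg, c(3, 3, 3)))
  expect_equal(unname(prof$naas[, "cy"]), c(0, 1, 2) / 3)

  tied <- matrix(0.5, 3, 1, dimnames = list(c("d1", "d2", "d3"), "cy"))
  expect_equal(unname(naas_normalize(make_raw(tied, c(3, 3, 3)))$naas[, "cy"]),
               c(0, 0, 0))
})

test_that("NAAS satisfies its empirical-CDF contract on random fixtures", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(6:20, 1); k <- sample(3:8, 1)
    avg <- matrix(runif(n * k, -1, 1), n, k,
                  dimnames = list(sprintf("d%02d", 1:n),
                                  sprintf("c%02d", 1:k)))
    sizes <- sample(c(2:9, 10:19, 20:49, 50:60), n, replace = TRUE)
    raw <- make_raw(avg, sizes)
    prof <- naas_normalize(raw)
    for (lv in levels(raw$bin)) {
      rows <- which(raw$bin == lv)
      if (!length(rows)) next
      m <- length(rows)
      expect_true(all(prof$naas[rows, ] >= 0 &
                        prof$naas[rows, ] <= (m - 1) / m))
      # monotone in the raw average within bin, per cytokine
      for (j in seq_len(k)) {
        o <- order(avg[rows, j])
        expect_true(all(diff(prof$naas[rows[o], j]) >= 0))
      }
    }
    # invariant under strictly increasing transforms of the raw averages
    raw_t <- make_raw(exp(3 * avg), sizes)
    expect_equal(naas_normalize(raw_t)$naas, prof$naas)
  }
})

test_that("immune scores are category means of NAAS", {
  cyto <- c("i1", "i2", "ch", "gf", "ot")
  catalog <- toy_catalog(cyto, setNames(c("inflammation", "inflammation",
                                          "chemokine", "growth_factor",
                                          "other"), cyto))
  naas <- matrix(0.5, 2, 5, dimnames = list(c("d1", "d2"), cyto))
  prof <- structure(list(naas = naas), class = "cytokine_profiles")
  sc <- immune_scores(prof, catalog)
  expect_equal(unname(unlist(sc["d1", ])), rep(0.5, 4))

  naas2 <- naas; naas2[1, ] <- c(0, 0, 1, 0, 0)
  sc2 <- immune_scores(structure(list(naas = naas2),
                                 class = "cytokine_profiles"), catalog)
  expect_equal(unname(unlist(sc2["d1", ])), c(0, 1, 0, 0))

  singleton <- toy_catalog(c("a", "b", "c", "d"),
                           setNames(c("inflammation", "chemokine",
                                      "growth_factor", "other"),
                                    c("a", "b", "c", "d")))
  naas3 <- matrix(c(0.2, 0.4, 0.6, 0.8), 1, 4,
                  dimnames = list("d", c("a", "b", "c", "d")))
  sc3 <- immune_scores(structure(list(naas = naas3),
                                 class = "cytokine_profiles"), singleton)
  expect_equal(unname(unlist(sc3)), c(0.2, 0.4, 0.6, 0.8))

  # NAAS bounds the scores
  expect_true(all(sc >= 0 & sc <= 1))
})

test_that("planted affinity pairs receive higher NAAS than null pairs", {
  res <- demo_result()
  w <- res$world
  naas <- res$profiles$naas
  enr <- names(w$target_family)[!is.na(w$target_family)]
  enr <- intersect(enr, rownames(naas))
  fam_of <- w$cytokine_family[colnames(naas)]
  affine <- nonaffine <- c()
  for (d in enr) {
    hit <- fam_of == w$target_family[d]
    affine <- c(affine, naas[d, hit])
    nonaffine <- c(nonaffine, naas[d, !hit])
  }
  expect_gt(mean(affine), mean(nonaffine))
})

test_that("cytokine clustering recovers planted families and handles edge cases", {
  emb <- small_embedding()
  w <- small_world()
  cl <- cluster_cytokines(emb, w$catalog, k = 3)
  fam <- w$cytokine_family[names(cl$labels)]
  tab <- table(cl$labels, fam)
  # perfect recovery: each cluster maps to exactly one family
  expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))

  one <- cluster_cytokines(emb, w$catalog, k = 1)
  expect_equal(length(unique(one$labels)), 1)

  expect_error(cluster_cytokines(emb, w$catalog, k = 999), "k must be")

  # signatures partition the non-cytokine genes
  non_cyto <- setdiff(rownames(emb$vectors), w$catalog$cytokines)
  expect_setequal(unlist(cl$signatures), non_cyto)
})

test_that("identical association vectors cluster without crashing, all merges at height zero", {
  v <- matrix(rep(c(1, 2, 0.5, 3), 6), 6, 4, byrow = TRUE)
  rownames(v) <- c(sprintf("cy%d", 1:3), sprintf("g%d", 1:3))
  emb <- structure(list(vectors = v), class = "embedded_network")
  catalog <- toy_catalog(sprintf("cy%d", 1:3))
  cl <- cluster_cytokines(emb, catalog, k = 2)
  expect_equal(max(abs(cl$tree$height)), 0)
  expect_length(cl$labels, 3)
})

test_that("the dendrogram exports as parseable Newick with one tip per cytokine", {
  emb <- small_embedding()
  w <- small_world()
  cl <- cluster_cytokines(emb, w$catalog, k = 3)
  path <- withr::local_tempfile()
  export_dendrogram_newick(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, names(cl$labels))
})
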