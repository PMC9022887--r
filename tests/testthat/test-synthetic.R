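test_that("a forced single module yields the complete graph with forced confidences", {
  out <- make_modular_network(module_sizes = 3, p_in = 1, p_out = 0.5,
                              confidence_model = list(within = c(1000, 1000),
                                                      between = c(150, 799)),
                              seed = 1)
  expect_equal(nrow(out$network$edges), 3)
  expect_true(all(out$network$edges$confidence == 1000))
})

test_that("planted-partition edge counts match the binomial law", {
  out <- make_modular_network(module_sizes = c(50, 50), p_in = 0.3,
                              p_out = 0.01, seed = 7)
  e <- out$network$edges
  same <- out$modules[e$gene_a] == out$modules[e$gene_b]
  n_pairs_in <- 2 * choose(50, 2)
  expected <- n_pairs_in * 0.3
  sd_in <- sqrt(n_pairs_in * 0.3 * 0.7)
  expect_lt(abs(sum(same) - expected), 4 * sd_in)
  # confidence dichotomy: within >= 800, between < 800
  expect_true(all(e$confidence[same] >= 800))
  expect_true(all(e$confidence[!same] < 800))
})

test_that("generators are pure functions of seed and parameters", {
  a <- make_modular_network(c(20, 20), 0.5, 0.02, seed = 11)
  b <- make_modular_network(c(20, 20), 0.5, 0.02, seed = 11)
  expect_identical(a, b)
  expect_false(identical(
    a$network$edges,
    make_modular_network(c(20, 20), 0.5, 0.02, seed = 12)$network$edges))
  w1 <- make_world(module_sizes = rep(20, 4), n_cytokine_families = 2,
                   cytokines_per_family = 4, n_receptors = 4,
                   n_diseases = 8, seed = 3)
  w2 <- make_world(module_sizes = rep(20, 4), n_cytokine_families = 2,
                   cytokines_per_family = 4, n_receptors = 4,
                   n_diseases = 8, seed = 3)
  expect_identical(w1, w2)
})

test_that("unrecoverable planted structure is rejected", {
  expect_error(make_modular_network(c(10, 10), 0.1, 0.1, seed = 1), "p_in")
  expect_error(make_modular_network(c(1, 10), 0.5, 0.1, seed = 1),
               "module size")
})

test_that("disease set sizes follow the requested bin mix", {
  univ <- sprintf("G%04d", 1:200)
  sets <- make_disease_sets(4, c(1, 0, 0, 0), univ, seed = 2)
  expect_true(all(lengths(sets) >= 2 & lengths(sets) <= 9))

  mix <- c(0.42, 0.25, 0.20, 0.13)
  sets <- make_disease_sets(1000, mix, univ, seed = 5)
  frac1 <- mean(lengths(sets) <= 9)
  expect_lt(abs(frac1 - 0.42), 3 * sqrt(0.42 * 0.58 / 1000))
  expect_true(all(unlist(sets) %in% univ))

  expect_error(make_disease_sets(3, c(0, 0, 0, 1), sprintf("G%d", 1:30),
                                 seed = 1),
               "exceeds the gene universe")
})

test_that("noise-free literature frequencies preserve affinity ranks exactly", {
  tf <- setNames(c(1L, 2L, NA), c("d1", "d2", "d3"))
  cf <- setNames(rep(c(1L, 2L), each = 4), sprintf("C%d", 1:8))
  aff <- planted_affinity(tf, cf, enrichment = 0.8)
  lit <- make_literature_freq(aff, noise_sd = 0, dropout = 0, seed = 1)
  for (d in c("d1", "d2")) {
    sub <- lit[lit$disease_id == d, ]
    expect_equal(cor(sub$frequency, aff[d, sub$cytokine],
                     method = "spearman"), 1.0)
  }
})

test_that("overwhelming noise destroys the planted ranks", {
  set.seed(1)
  aff <- matrix(runif(100 * 79), 100, 79,
                dimnames = list(sprintf("d%03d", 1:100),
                                sprintf("c%02d", 1:79)))
  lit <- make_literature_freq(aff, noise_sd = 10, dropout = 0, seed = 2)
  rhos <- vapply(rownames(aff), function(d) {
    sub <- lit[lit$disease_id == d, ]
    suppressWarnings(cor(sub$frequency, aff[d, sub$cytokine],
                         method = "spearman"))
  }, 0)
  expect_lt(mean(abs(rhos), na.rm = TRUE), 0.2)
})

test_that("dropout removes the expected fraction of entries", {
  aff <- matrix(0.5, 50, 40, dimnames = list(sprintf("d%02d", 1:50),
                                             sprintf("c%02d", 1:40)))
  lit <- make_literature_freq(aff, noise_sd = 0, dropout = 0.5, seed = 3)
  n <- 50 * 40
  expect_lt(abs(nrow(lit) - 0.5 * n), 4 * sqrt(n * 0.25))
  expect_error(make_literature_freq(aff, dropout = 1), "dropout")
  expect_error(make_literature_freq(aff, noise_sd = -1), "noise_sd")
})

test_that("planted affinity is flat for null diseases and peaked for enriched ones", {
  tf <- setNames(c(1L, NA), c("enr", "null"))
  cf <- setNames(c(1L, 1L, 2L, 2L), c("a", "b", "c", "d"))
  aff <- planted_affinity(tf, cf, enrichment = 0.9)
  expect_equal(unname(aff["enr", ]), c(0.9, 0.9, 0.1, 0.1))
  expect_equal(unname(aff["null", ]), rep(0.5, 4))
})

test_that("every disease-set gene exists in the world's network universe", {
  w <- small_world()
  expect_true(all(unlist(w$diseases) %in% w$network$genes))
  expect_true(all(unlist(w$diseases) %in%
                    select_universe(filter_high_confidence(w$network))))
})
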