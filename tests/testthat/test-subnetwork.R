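# Embedding with exact pairwise cosines via planar angles: gene g1 close to
# cytokines cy1/cy2, g2 close to cy2 only, g3 far from everything.
toy_sub_embedding <- function() {
  deg <- pi / 180
  angle_embedding(setNames(
    c(0, 30 * deg, 10 * deg, 22 * deg, 120 * deg),
    c("cy1", "cy2", "g1", "g2", "g3")))
}

test_that("subnetwork construction applies the strict cutoff and labels nodes", {
  emb <- toy_sub_embedding()
  catalog <- toy_catalog(c("cy1", "cy2"), receptors = "g2")
  # cos(10deg)=.985 cy1-g1; cos(20deg)=.940 cy2-g1; cos(22deg)=.927 cy1-g2;
  # cos(8deg)=.990 cy2-g2; g3 at >90deg from both cytokines
  sub <- build_subnetwork(emb, c("g1", "g2", "g3"), catalog, cutoff = 0.8)
  expect_equal(sub$Np, 2)
  expect_equal(sub$Ni, 2)
  expect_equal(nrow(sub$edges), 4)
  expect_equal(sub$pathogenesis$label[sub$pathogenesis$gene == "g2"],
               "receptor")
  expect_equal(sub$pathogenesis$label[sub$pathogenesis$gene == "g1"],
               "disease_specific")

  # everything below the cutoff: empty subnetwork, valid with ICD 0
  none <- build_subnetwork(emb, "g3", catalog, cutoff = 0.8)
  expect_equal(none$Np, 0)
  expect_equal(icd(none), 0)

  # a disease gene that is a cytokine moves to the cytokine side
  expect_message(both <- build_subnetwork(emb, c("cy1", "g1"), catalog),
                 "cytokine side")
  expect_false("cy1" %in% both$pathogenesis$gene)
})

fake_sub <- function(edges, Np, Ni) {
  structure(list(edges = edges, Np = Np, Ni = Ni,
                 pathogenesis = data.frame(
                   gene = unique(edges$pathogenesis),
                   label = rep("disease_specific",
                               length(unique(edges$pathogenesis)))),
                 cytokines = unique(edges$cytokine), cutoff = 0.8),
            class = "disease_subnetwork")
}

test_that("ICD evaluates its formula exactly", {
  full <- fake_sub(data.frame(pathogenesis = rep(c("p1", "p2"), each = 3),
                              cytokine = rep(c("c1", "c2", "c3"), 2),
                              score = 1.0), 2, 3)
  expect_equal(icd(full), 1.0, tolerance = 1e-12)

  sparse <- fake_sub(data.frame(pathogenesis = c("p1", "p2"),
                                cytokine = c("c1", "c2"),
                                score = c(0.9, 0.8)), 2, 3)
  expect_equal(icd(sparse), 1.7 / 6, tolerance = 1e-12)
  expect_equal(icd(sparse, mode = "count"), 2 / 6, tolerance = 1e-12)

  # linear in a uniform weight multiplier, bounded by max d_pi
  scaled <- sparse; scaled$edges$score <- sparse$edges$score * 0.5
  expect_equal(icd(scaled), icd(sparse) * 0.5, tolerance = 1e-12)
  expect_lte(icd(sparse), max(sparse$edges$score))

  # invariant to node relabeling
  relab <- sparse
  relab$edges$pathogenesis <- c("x9", "x1")
  expect_equal(icd(relab), icd(sparse), tolerance = 1e-12)
})

test_that("cytokine recall counts catalog cytokines recognized by the subnetwork", {
  catalog <- toy_catalog(c("cy1", "cy2"))
  sub <- fake_sub(data.frame(pathogenesis = "p1", cytokine = "cy1",
                             score = 0.9), 1, 1)
  r <- cytokine_recall(c("cy1", "cy2", "p1"), sub, catalog)
  expect_equal(r[c("recognized", "known", "recall")],
               list(recognized = 1L, known = 2L, recall = 0.5))
  r2 <- cytokine_recall("p1", sub, catalog)
  expect_true(r2$undefined)
  sub0 <- fake_sub(data.frame(pathogenesis = character(),
                              cytokine = character(), score = numeric()),
                   0, 0)
  expect_equal(cytokine_recall(c("cy1", "p1"), sub0, catalog)$recall, 0)
})

test_that("Fiedler partition reproduces closed-form spectra for K2 and P3", {
  A2 <- matrix(c(0, 1, 1, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- fiedler_partition(A2)
  expect_equal(p2$fiedler_value, 2, tolerance = 1e-10)
  expect_equal(sort(abs(p2$fiedler_vector)), c(a = 1, b = 1) / sqrt(2),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(p2$classes == "well_connected"), 1)
  expect_equal(sum(p2$classes == "poorly_connected"), 1)

  A3 <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A3["a", "b"] <- A3["b", "a"] <- A3["b", "c"] <- A3["c", "b"] <- 1
  p3 <- fiedler_partition(A3)
  expect_equal(p3$fiedler_value, 1, tolerance = 1e-10)
  expect_equal(unname(p3$classes["b"]), factor("articulation",
    levels = c("well_connected", "poorly_connected", "articulation")))
  expect_equal(abs(p3$fiedler_vector[["a"]]), 1 / sqrt(2), tolerance = 1e-8)

  expect_error(fiedler_partition(matrix(0, 1, 1)), "fewer than 2")
})

test_that("the sign cut separates two bipartite blocks joined by a weak edge", {
  # two 2x2 complete bipartite blocks + one cross edge
  nodes <- c("a1", "a2", "a3", "a4", "b1", "b2", "b3", "b4")
  A <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  for (e in list(c("a1", "a3"), c("a1", "a4"), c("a2", "a3"), c("a2", "a4"),
                 c("b1", "b3"), c("b1", "b4"), c("b2", "b3"), c("b2", "b4"),
                 c("a1", "b1")))
    A[e[1], e[2]] <- A[e[2], e[1]] <- 1
  p <- fiedler_partition(A)
  side <- p$classes[paste0("a", 1:4)]
  other <- p$classes[paste0("b", 1:4)]
  expect_equal(length(unique(side)), 1)
  expect_equal(length(unique(other)), 1)
  expect_false(unique(as.character(side)) == unique(as.character(other)))
})

test_that("disconnected graphs are split exactly along components", {
  nodes <- c("x1", "x2", "x3", "y1", "y2")
  A <- matrix(0, 5, 5, dimnames = list(nodes, nodes))
  A["x1", "x2"] <- A["x2", "x1"] <- 1
  A["x2", "x3"] <- A["x3", "x2"] <- 1
  A["x1", "x3"] <- A["x3", "x1"] <- 1
  A["y1", "y2"] <- A["y2", "y1"] <- 1
  p <- fiedler_partition(A)
  expect_equal(p$fiedler_value, 0)
  expect_equal(unname(p$classes[c("x1", "x2", "x3")]),
               rep(factor("well_connected",
                          levels = levels(p$classes)), 3))
  expect_equal(unname(p$classes[c("y1", "y2")]),
               rep(factor("poorly_connected",
                          levels = levels(p$classes)), 2))
})

test_that("orientation is deterministic: the well-connected class has the larger degree", {
  set.seed(13)
  for (rep in 1:10) {
    n <- sample(4:9, 1)
    A <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (runif(1) < 0.5) A[i, j] <- A[j, i] <- 1
    A[1, 2] <- A[2, 1] <- 1  # keep at least one edge
    p <- fiedler_partition(A)
    deg <- rowSums(A)
    dw <- sum(deg[p$classes == "well_connected"])
    dp <- sum(deg[p$classes == "poorly_connected"])
    expect_gte(dw, dp)
  }
})

test_that("partition of a disease subnetwork reports pathogenesis key genes", {
  emb <- toy_sub_embedding()
  catalog <- toy_catalog(c("cy1", "cy2"), receptors = "g2")
  sub <- build_subnetwork(emb, c("g1", "g2", "g3"), catalog, cutoff = 0.8)
  part <- fiedler_partition(sub)
  expect_true(all(c(part$key_genes, part$key_receptors) %in%
                    sub$pathogenesis$gene))
  summ <- partition_summary(list(d1 = part),
                            list(d1 = c("g1", "g2", "g3")))
  expect_equal(summ$n_input_genes, 3)
  expect_equal(summ$pct_retained,
               round(100 * length(part$key_genes) / 3, 1))
})

test_that("partition summary reproduces the percentage presentation", {
  fake_part <- function(k) structure(
    list(key_genes = sprintf("g%d", seq_len(k)), key_receptors = character()),
    class = "partition_result")
  sets <- list(ra = sprintf("g%d", 1:1340), none = c("a", "b"),
               all = c("g1", "g2"))
  summ <- partition_summary(list(ra = fake_part(36), none = fake_part(0),
                                 all = fake_part(2)), sets)
  expect_equal(summ$pct_retained, c(2.7, 0, 100))
})

test_that("subnetworks export to edge-list TSV and GraphML", {
  emb <- toy_sub_embedding()
  catalog <- toy_catalog(c("cy1", "cy2"), receptors = "g2")
  sub <- build_subnetwork(emb, c("g1", "g2"), catalog, cutoff = 0.8)
  stem <- withr::local_tempfile()
  write_subnetwork(sub, stem)
  tsv <- read.table(paste0(stem, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(nrow(tsv), nrow(sub$edges))
  xml <- xml2::read_xml(paste0(stem, ".graphml"))
  expect_equal(length(xml2::xml_find_all(xml, ".//d1:node",
                                         xml2::xml_ns(xml))),
               sub$Np + sub$Ni)
})
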