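# Shared fixtures, built in code and cached for the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small synthetic world + embedding: 6 modules of 30 genes, 3 cytokine
# families of 6, 30 diseases. Big enough for planted-signal checks, small
# enough to embed in a couple of seconds.
small_world <- function() cached("small_world", {
  make_world(module_sizes = rep(30, 6), n_cytokine_families = 3,
             cytokines_per_family = 6, n_receptors = 9, n_diseases = 30,
             seed = 401)
})

small_embedding <- function() cached("small_embedding", {
  w <- small_world()
  high <- filter_high_confidence(w$network)
  high$genes <- select_universe(high)
  embed_network(high, seed = 401)
})

# Demo-scale world + embedding (500 genes, 40 cytokines, 60 diseases),
# shared by the end-to-end checks.
demo_result <- function() cached("demo_result", {
  suppressMessages(run_demo(dir = tempfile("cytonet_demo"), seed = 701))
})

# Hand-made embedding with known geometry: unit vectors at chosen angles in
# the plane, padded with zeros, so pairwise cosines are exact by
# construction.
angle_embedding <- function(angles, dim = 4) {
  v <- cbind(cos(angles), sin(angles),
             matrix(0, length(angles), dim - 2))
  rownames(v) <- names(angles)
  structure(list(vectors = v, params = list(dim = dim)),
            class = "embedded_network")
}

# Minimal catalog builder for unit tests.
toy_catalog <- function(cytokines, categories = NULL, receptors = character()) {
  categories <- categories %||%
    setNames(rep(c("inflammation", "chemokine", "growth_factor", "other"),
                 length.out = length(cytokines)), cytokines)
  cytokine_catalog(cytokines, categories, receptors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
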