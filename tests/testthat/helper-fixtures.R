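# small fixtures shared across test files

# a tiny trained-by-hand "som" with explicit weights
make_toy_map <- function(weights, rows, cols, disrupted = FALSE) {
  structure(list(rows = rows, cols = cols, dim = ncol(weights),
                 weights = weights, disrupted = disrupted),
            class = "som")
}

# a perfect two-category lexical model: one neuron per category on each map,
# weights equal to the centroids, identity bridge
make_perfect_model <- function(voc) {
  ncat <- voc$n_categories
  aud <- make_toy_map(voc$aud_centroids, rows = 1, cols = ncat)
  vis <- make_toy_map(voc$vis_centroids, rows = 1, cols = ncat)
  bridge <- diag(ncat)
  cfg <- model_config("perfect", aud_grid = c(1, ncat),
                      vis_grid = c(1, ncat), n_epochs = 0L)
  structure(list(aud_map = aud, vis_map = vis, bridge = bridge,
                 config = cfg, vocabulary = voc),
            class = "lexical_model")
}

# small vocabulary for fast end-to-end runs
small_vocabulary <- function(seed = 1, ncat = 4, nex = 4, dim = 6,
                             sigma_aud = 0.05, sigma_vis = 0.25) {
  set.seed(seed)
  make_vocabulary(ncat, nex, dim, sigma_aud, sigma_vis)
}
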