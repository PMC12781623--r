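test_that("model initialisation sizes maps and bridge from the config", {
  voc <- small_vocabulary(seed = 1, dim = 10)
  set.seed(2)
  m <- init_model(reference_config(), voc)
  expect_equal(dim(m$bridge), c(144, 144))
  expect_true(all(m$bridge == 0))
  set.seed(2)
  w <- init_model(ws_config(), voc)
  expect_equal(dim(w$bridge), c(81, 81))
  expect_true(w$vis_map$disrupted)
  expect_false(w$aud_map$disrupted)
})

test_that("hebbian updates increment co-activations and keep rows sub-normalised", {
  b <- matrix(0, 3, 4)
  # eta = 0 leaves the bridge unchanged
  expect_equal(hebbian_update(b, c(1, 0, 0), c(0, 1, 0, 0), 0), b)
  # one-hot co-activation increments exactly one cell
  b1 <- hebbian_update(b, c(0, 1, 0), c(0, 0, 1, 0), 0.1)
  expect_equal(b1[2, 3], 0.1)
  expect_equal(sum(b1), 0.1)
  # repeated pairing concentrates the BMU row on the paired neuron and the
  # row mass stays at most 1
  set.seed(1)
  b2 <- matrix(0, 2, 2)
  for (i in 1:100) {
    b2 <- hebbian_update(b2, c(0.9, 0.1), c(0.8, 0.2), 0.3)
  }
  expect_lte(max(rowSums(b2)), 1 + 1e-12)
  expect_gt(b2[1, 1], b2[1, 2])
  expect_gt(b2[1, 1], b2[2, 1])
  expect_error(hebbian_update(b, c(1, 0), c(1, 0, 0, 0), 0.1), "dimensions")
})

test_that("two-category pairing oracle: bridge mass concentrates correctly", {
  # hand simulation: category 1 always pairs aud neuron 1 with vis neuron 1,
  # category 2 pairs neuron 2 with neuron 2, with graded fields
  b <- matrix(0, 2, 2)
  a1 <- c(0.95, 0.05); v1 <- c(0.9, 0.1)
  a2 <- c(0.05, 0.95); v2 <- c(0.1, 0.9)
  for (i in 1:50) {
    b <- hebbian_update(b, a1, v1, 0.1)
    b <- hebbian_update(b, a2, v2, 0.1)
  }
  expect_gt(b[1, 1], b[1, 2])
  expect_gt(b[2, 2], b[2, 1])
  # propagation recovers the paired side
  expect_equal(which.max(propagate(b, c(1, 0), "aud2vis")), 1)
  expect_equal(which.max(propagate(b, c(0, 1), "aud2vis")), 2)
})

test_that("propagate matches a direct matrix-vector oracle and normalises", {
  set.seed(6)
  for (rep in 1:20) {
    b <- matrix(runif(25), 5, 5)
    act <- runif(5); act <- act / sum(act)
    fwd <- propagate(b, act, "aud2vis")
    want <- as.numeric(t(b) %*% act)
    expect_equal(fwd, want / sum(want), tolerance = 1e-12)
    bwd <- propagate(b, act, "vis2aud")
    want2 <- as.numeric(b %*% act)
    expect_equal(bwd, want2 / sum(want2), tolerance = 1e-12)
    expect_equal(sum(fwd), 1, tolerance = 1e-12)
  }
  # identity bridge routes one-hot fields through unchanged
  expect_equal(propagate(diag(4), c(0, 0, 1, 0), "aud2vis"),
               c(0, 0, 1, 0))
  # zero bridge yields an uninformative all-zero field
  expect_equal(propagate(matrix(0, 3, 3), c(1, 0, 0), "aud2vis"),
               rep(0, 3))
})

test_that("category decoding reads one-hot fields correctly under every rule", {
  voc <- small_vocabulary(seed = 3)
  map <- make_toy_map(voc$vis_centroids, 1, voc$n_categories)
  for (method in c("mass", "region", "winner")) {
    for (c in seq_len(voc$n_categories)) {
      field <- as.numeric(seq_len(voc$n_categories) == c)
      expect_equal(decode_category(map, field, voc, "vis", method), c)
    }
    expect_true(is.na(decode_category(map, rep(0.25, 4), voc, "vis",
                                      method)))
  }
  # centre-of-mass rule follows the dominant component of a mixed field
  mixed <- c(0.6, 0.3, 0.05, 0.05)
  expect_equal(decode_category(map, mixed, voc, "vis", "mass"), 1)
})

test_that("untrained models score zero; a perfect hand-built model scores full marks", {
  voc <- small_vocabulary(seed = 4)
  set.seed(5)
  m0 <- init_model(model_config("u", aud_grid = c(3, 3), vis_grid = c(3, 3)),
                   voc)
  expect_equal(test_comprehension(m0, voc), 0)
  expect_equal(test_production(m0, voc), 0)
  perfect <- make_perfect_model(voc)
  expect_equal(test_comprehension(perfect, voc), voc$n_categories)
  expect_equal(test_production(perfect, voc), voc$n_categories)
})

test_that("training traces are deterministic, bounded and empty at zero epochs", {
  voc <- small_vocabulary(seed = 6)
  cfg <- model_config("t", aud_grid = c(5, 5), vis_grid = c(5, 5),
                      n_epochs = 15)
  a <- train_model(cfg, voc, seed = 9)
  b <- train_model(cfg, voc, seed = 9)
  expect_identical(a$trace, b$trace)
  expect_identical(a$model$bridge, b$model$bridge)
  expect_true(all(a$trace$comp >= 0 & a$trace$comp <= voc$n_categories))
  expect_true(all(a$trace$prod >= 0 & a$trace$prod <= voc$n_categories))
  expect_equal(nrow(a$trace), 15)

  empty <- train_model(model_config("z", n_epochs = 0), voc, seed = 1)
  expect_equal(nrow(empty$trace), 0)
})

test_that("the compiled engine and the pure-R reference engine agree bit-for-bit", {
  voc <- small_vocabulary(seed = 7, ncat = 3, nex = 3, dim = 5)
  cfgs <- list(
    model_config("plain", aud_grid = c(4, 4), vis_grid = c(4, 4),
                 n_epochs = 5),
    model_config("noisy-disrupted", aud_grid = c(4, 4), vis_grid = c(3, 3),
                 noise_aud = 0.1, noise_vis = 0.2, disrupt_vis = TRUE,
                 decode = "region", n_epochs = 5),
    model_config("linear-decay", aud_grid = c(3, 4), vis_grid = c(4, 3),
                 decay = "linear", decode = "winner", n_epochs = 5))
  for (cfg in cfgs) {
    fast <- train_model(cfg, voc, seed = 13, engine = "cpp")
    slow <- train_model(cfg, voc, seed = 13, engine = "r")
    expect_identical(fast$trace, slow$trace)
    expect_identical(fast$model$aud_map$weights, slow$model$aud_map$weights)
    expect_identical(fast$model$vis_map$weights, slow$model$vis_map$weights)
    expect_identical(fast$model$bridge, slow$model$bridge)
    expect_identical(fast$bmu_aud, slow$bmu_aud)
    expect_identical(fast$bmu_vis, slow$bmu_vis)
  }
})

test_that("trace CSV round-trips through the writer", {
  voc <- small_vocabulary(seed = 8)
  cfg <- model_config("t", aud_grid = c(3, 3), vis_grid = c(3, 3),
                      n_epochs = 4)
  res <- train_model(cfg, voc, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trace_csv(res, path, run_id = 3)
  back <- utils::read.csv(path)
  expect_equal(back$run_id, rep(3, 4))
  expect_equal(back$comp, res$trace$comp)
  expect_equal(back$qe_vis, res$trace$qe_vis, tolerance = 1e-12)
})
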