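test_that("map initialisation is uniform in [0,1], shaped and seeded", {
  set.seed(1)
  m <- init_map(12, 12, 10)
  expect_equal(nrow(m$weights), 144)
  expect_true(all(m$weights >= 0 & m$weights <= 1))
  set.seed(1)
  m9 <- init_map(9, 9, 10)
  expect_equal(nrow(m9$weights), 81)
  set.seed(2)
  expect_equal(nrow(init_map(1, 1, 3)$weights), 1)
  expect_error(init_map(0, 3, 2), "positive")
})

test_that("find_bmu matches an exhaustive brute-force scan", {
  # oracle: loop over neurons, recompute distances with plain arithmetic
  brute <- function(map, x) {
    best <- 1; bestd <- Inf
    for (i in seq_len(nrow(map$weights))) {
      d <- sqrt(sum((x - map$weights[i, ])^2))
      if (d < bestd) { bestd <- d; best <- i }
    }
    list(index = best, distance = bestd)
  }
  set.seed(10)
  for (rep in 1:200) {
    rows <- sample(1:6, 1); cols <- sample(1:6, 1); dim <- sample(1:8, 1)
    map <- init_map(rows, cols, dim)
    x <- runif(dim)
    got <- find_bmu(map, x)
    want <- brute(map, x)
    expect_identical(got$index, want$index)
    expect_equal(got$distance, want$distance, tolerance = 1e-12)
  }
})

test_that("find_bmu returns exact matches and breaks ties row-major", {
  w <- matrix(c(0.2, 0.2,
                0.8, 0.8,
                0.2, 0.2), nrow = 3, byrow = TRUE)
  map <- make_toy_map(w, rows = 1, cols = 3)
  hit <- find_bmu(map, c(0.8, 0.8))
  expect_equal(hit$index, 2)
  expect_equal(hit$distance, 0)
  tie <- find_bmu(map, c(0.2, 0.2))
  expect_equal(tie$index, 1)  # neurons 1 and 3 tie; lowest index wins
  expect_error(find_bmu(map, c(1, 2, 3)), "dimension")
})

test_that("neighbourhood kernel is 1 at the BMU, flat in the wide limit, and BMU-only when disrupted", {
  set.seed(3)
  map <- init_map(5, 4, 3)
  bmu <- list(index = 7)
  h <- neighbourhood_kernel(map, bmu, 1.5)
  expect_equal(h[7], 1)
  expect_true(all(h > 0 & h <= 1))
  hwide <- neighbourhood_kernel(map, bmu, 1e6)
  expect_true(all(hwide > 0.999999))
  mapd <- init_map(5, 4, 3, disrupted = TRUE)
  hd <- neighbourhood_kernel(mapd, bmu, 1.5)
  expect_equal(sum(hd != 0), 1)
  expect_equal(hd[7], 1)
  expect_error(neighbourhood_kernel(map, bmu, 0), "positive")
})

test_that("weight updates move toward the input and keep weights in [0,1]", {
  set.seed(4)
  map <- init_map(4, 4, 5)
  x <- runif(5)
  bmu <- find_bmu(map, x)
  h <- neighbourhood_kernel(map, bmu, 2)
  # full step at the BMU makes its weight exactly x
  m1 <- update_weights(map, x, as.numeric(seq_len(16) == bmu$index), 1)
  expect_equal(unname(m1$weights[bmu$index, ]), unname(x))
  # near-zero alpha leaves the map essentially unchanged
  m2 <- update_weights(map, x, h, 1e-12)
  expect_equal(m2$weights, map$weights, tolerance = 1e-9)
  # geometric convergence under repeated presentation: after k half steps
  # the BMU error shrinks by 2^-k
  m3 <- map
  d0 <- find_bmu(map, x)$distance
  for (k in 1:20) {
    b <- find_bmu(m3, x)
    m3 <- update_weights(m3, x, as.numeric(seq_len(16) == b$index), 0.5)
  }
  expect_equal(find_bmu(m3, x)$distance, d0 * 2^-20, tolerance = 1e-6)
  expect_true(all(m3$weights >= 0 & m3$weights <= 1))
  expect_error(update_weights(map, x, h, 0), "alpha")
  expect_error(update_weights(map, x, h, 1.5), "alpha")
})

test_that("quantisation error matches direct computation and its edge cases", {
  w <- matrix(c(0.5, 0.5), 1, 2)
  map <- make_toy_map(w, 1, 1)
  ex <- matrix(c(0, 0, 1, 1, 0.5, 0.5), ncol = 2, byrow = TRUE)
  # single-neuron oracle: mean distance to the lone weight
  want <- mean(c(sqrt(0.5), sqrt(0.5), 0))
  expect_equal(quantisation_error(map, ex), want)
  # one neuron per exemplar, weights equal to exemplars -> zero error
  map3 <- make_toy_map(ex, 1, 3)
  expect_equal(quantisation_error(map3, ex), 0)
  expect_error(quantisation_error(map, ex[0, , drop = FALSE]), "non-empty")
})

test_that("activation fields normalise, peak at the BMU and sharpen as kappa shrinks", {
  set.seed(5)
  map <- init_map(6, 6, 4)
  x <- runif(4)
  a <- activation_pattern(map, x, 0.3)
  expect_equal(sum(a), 1)
  expect_equal(which.max(a), find_bmu(map, x)$index)
  a_tiny <- activation_pattern(map, x, 1e-4)
  expect_gt(max(a_tiny), 1 - 1e-10)  # one-hot limit
  expect_error(activation_pattern(map, x, 0), "positive")
})

test_that("training preserves the weight-range invariant and organises topographically", {
  voc <- small_vocabulary(seed = 2)
  cfg <- model_config("t", aud_grid = c(6, 6), vis_grid = c(6, 6),
                      n_epochs = 60, n_runs = 1)
  res <- train_model(cfg, voc, seed = 11)
  expect_true(all(res$model$aud_map$weights >= 0 &
                    res$model$aud_map$weights <= 1))
  expect_true(all(res$model$vis_map$weights >= 0 &
                    res$model$vis_map$weights <= 1))
  # same-category exemplars land closer on the grid than different-category
  coords <- cbind((res$bmu_aud - 1) %/% 6, (res$bmu_aud - 1) %% 6)
  gd <- as.matrix(stats::dist(coords))
  same <- outer(voc$category, voc$category, "==") & upper.tri(gd)
  diff <- outer(voc$category, voc$category, "!=") & upper.tri(gd)
  expect_lt(mean(gd[same]), mean(gd[diff]))
})
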