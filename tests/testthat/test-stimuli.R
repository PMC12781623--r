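test_that("prototype generation is bounded, shaped and seed-deterministic", {
  set.seed(1)
  p <- generate_prototypes(20, 10)
  expect_equal(dim(p), c(20, 10))
  expect_true(all(p >= 0 & p <= 1))

  set.seed(7)
  a <- generate_prototypes(3, 2)
  set.seed(7)
  b <- generate_prototypes(3, 2)
  expect_identical(a, b)

  set.seed(2)
  expect_equal(dim(generate_prototypes(1, 1)), c(1, 1))
  expect_error(generate_prototypes(0, 10), "positive")
})

test_that("zero-sigma exemplars equal their prototypes", {
  set.seed(3)
  p <- generate_prototypes(5, 4)
  e <- generate_exemplars(p, 3, 0)
  for (c in 1:5)
    for (j in 1:3)
      expect_equal(unname(e[(c - 1) * 3 + j, ]), unname(p[c, ]))
  expect_error(generate_exemplars(p, 3, -0.1), "non-negative")
})

test_that("exemplar dispersion matches a Monte-Carlo clipped-Gaussian oracle", {
  # oracle: mean distance of clip(proto + N(0, sigma^2)) from a fixed
  # prototype, estimated from 1e5 independent draws
  set.seed(42)
  proto <- matrix(runif(10), 1, 10)
  sigma <- 0.25
  z <- matrix(stats::rnorm(1e5 * 10, 0, sigma), ncol = 10)
  clipped <- pmin(pmax(sweep(z, 2, proto[1, ], "+"), 0), 1)
  oracle_mean <- mean(sqrt(rowSums(sweep(clipped, 2, proto[1, ])^2)))

  set.seed(43)
  e <- generate_exemplars(proto, 4000, sigma)
  d <- sqrt(rowSums(sweep(e, 2, proto[1, ])^2))
  expect_lt(abs(mean(d) - oracle_mean) / oracle_mean, 0.02)
})

test_that("interior-prototype exemplars reproduce the generating SD", {
  proto <- matrix(0.5, 1, 10)
  set.seed(2)
  e <- generate_exemplars(proto, 2000, 0.05)
  expect_lt(abs(sd(e[, 1] - 0.5) - 0.05) / 0.05, 0.05)
})

test_that("vocabulary has paired modalities with the right shapes", {
  set.seed(1)
  voc <- make_vocabulary()
  expect_equal(nrow(voc$aud_exemplars), 160)
  expect_equal(nrow(voc$vis_exemplars), 160)
  expect_equal(voc$category, rep(1:20, each = 8))
  expect_equal(dim(voc$aud_centroids), c(20, 10))

  set.seed(1)
  v0 <- make_vocabulary(sigma_aud = 0, sigma_vis = 0)
  expect_equal(v0$aud_exemplars[1, ], v0$aud_prototypes[1, ])
  expect_equal(v0$vis_centroids, v0$vis_prototypes, ignore_attr = TRUE)

  set.seed(1); va <- make_vocabulary()
  set.seed(2); vb <- make_vocabulary()
  expect_false(isTRUE(all.equal(va$aud_prototypes, vb$aud_prototypes)))
  expect_equal(dim(va$aud_prototypes), dim(vb$aud_prototypes))
})

test_that("exemplar clouds are separable and modality dispersions ordered", {
  for (s in 1:3) {
    set.seed(s)
    voc <- make_vocabulary()
    d2all <- as.matrix(stats::dist(rbind(voc$aud_exemplars,
                                         voc$aud_prototypes)))
    to_proto <- d2all[1:160, 161:180]
    own <- to_proto[cbind(1:160, voc$category)]
    nearest <- apply(to_proto, 1, min)
    expect_gte(mean(own == nearest), 0.95)

    disp <- function(ex, ce) vapply(1:20, function(c)
      mean(sqrt(rowSums(sweep(ex[voc$category == c, ], 2, ce[c, ])^2))),
      numeric(1))
    expect_true(all(disp(voc$vis_exemplars, voc$vis_centroids) >
                      disp(voc$aud_exemplars, voc$aud_centroids)))
  }
})

test_that("presentation noise clips, preserves zero-noise input and reproduces", {
  x <- runif(10)
  expect_identical(apply_input_noise(x, 0), x)
  set.seed(5)
  y <- apply_input_noise(rep(0, 10), 0.15)
  expect_true(all(y >= 0 & y <= 1))
  set.seed(9); a <- apply_input_noise(x, 0.15)
  set.seed(9); b <- apply_input_noise(x, 0.15)
  expect_identical(a, b)
  expect_error(apply_input_noise(x, -1), "non-negative")
})

test_that("vocabulary CSV round-trips exemplars, prototypes and centroids", {
  set.seed(4)
  voc <- make_vocabulary(5, 3, 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_vocabulary_csv(voc, path)
  back <- read_vocabulary_csv(path)
  expect_equal(back$aud_prototypes, voc$aud_prototypes, tolerance = 1e-12)
  expect_equal(unname(back$vis_exemplars[, ]),
               unname(voc$vis_exemplars[, ]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$vis_centroids, voc$vis_centroids, tolerance = 1e-12)
  expect_equal(back$n_categories, 5)
  expect_equal(back$n_exemplars, 3)
})
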