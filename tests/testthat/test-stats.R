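test_that("sign test reproduces the printed cohort statistics from counts", {
  # comparisons at the precision the statistics are reported to (3 d.p.)
  ws <- exact_binomial_sign_test(47, 67)
  expect_equal(round(ws$proportion, 3), 0.701)
  expect_equal(round(ws$ci_lower, 3), 0.596)
  expect_lt(ws$p, 0.001)

  ds <- exact_binomial_sign_test(9, 27)
  expect_equal(round(ds$p, 3), 0.974)
  expect_equal(round(ds$proportion, 2), 0.33)

  fxs <- exact_binomial_sign_test(4, 15)
  expect_equal(round(fxs$p, 3), 0.982)
  expect_equal(round(fxs$ci_lower, 3), 0.097)

  boundary <- exact_binomial_sign_test(0, 10)
  expect_equal(boundary$proportion, 0)
  expect_equal(boundary$p, 1)
  expect_error(exact_binomial_sign_test(5, 4), "n_above")
})

test_that("sign-test p equals exhaustive enumeration over all sign patterns", {
  # oracle: enumerate all 2^n equally likely sign vectors and count those
  # with at least k positives
  enum_p <- function(k, n) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    mean(rowSums(signs) >= k)
  }
  for (n in c(1, 4, 7, 10, 12)) {
    for (k in 0:n) {
      expect_equal(exact_binomial_sign_test(k, n)$p, enum_p(k, n),
                   tolerance = 1e-12)
    }
  }
})

test_that("Clopper-Pearson lower bound satisfies its tail-probability contract", {
  for (n in c(10, 67, 100)) {
    for (k in c(1, floor(n / 3), n - 1, n)) {
      lo <- exact_binomial_sign_test(k, n)$ci_lower
      # at the bound, P(X >= k | n, lo) = 0.05
      expect_equal(stats::pbinom(k - 1, n, lo, lower.tail = FALSE), 0.05,
                   tolerance = 1e-9)
    }
  }
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(rep(0.2, 4)), rep(0.2, 4))
  # hand computation: sorted p * n / rank, cumulative minimum from the top
  p <- c(0.01, 0.02, 0.03, 0.5)
  hand <- c(0.01 * 4 / 1, 0.02 * 4 / 2, 0.03 * 4 / 3, 0.5 * 4 / 4)
  hand <- rev(cummin(rev(hand)))
  expect_equal(bh_fdr(p), hand)
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("monotone smoother recovers an increasing line almost exactly", {
  x <- seq(0, 10, length.out = 50)
  y <- 2 + 0.7 * x
  fit <- fit_monotone_smoother(x, y)
  expect_lt(sqrt(mean((predict(fit, x) - y)^2)), 1e-6)
})

test_that("monotone smoother never decreases, even on decreasing data", {
  set.seed(8)
  x <- seq(0, 1, length.out = 60)
  y <- 3 - 2 * x + rnorm(60, 0, 0.1)
  fit <- fit_monotone_smoother(x, y)
  grid <- seq(0, 1, length.out = 400)
  pred <- predict(fit, grid)
  expect_true(all(diff(pred) >= -1e-10))
  expect_error(fit_monotone_smoother(rep(1, 20), rnorm(20)), "distinct")
})

test_that("on a noisy sigmoid the fit is monotone and within the noise SD of truth", {
  set.seed(21)
  n <- 200
  x <- sort(runif(n, -3, 3))
  truth <- 1 / (1 + exp(-2 * x))
  noise_sd <- 0.08
  y <- truth + rnorm(n, 0, noise_sd)
  fit <- fit_monotone_smoother(x, y)
  pred <- predict(fit, x)
  expect_true(all(diff(pred) >= -1e-10))
  expect_lt(sqrt(mean((pred - truth)^2)), noise_sd)
  # an unconstrained cubic wiggles under sign-violating noise; the
  # constrained fit never decreases
  cub <- lm(y ~ poly(x, 3))
  expect_true(all(diff(pred) >= -1e-10) || any(diff(fitted(cub)) < 0))
})

test_that("predictions are order-invariant, clamped outside the domain, and covered by the bootstrap band", {
  set.seed(30)
  x <- runif(120, 0, 5)
  y <- x + rnorm(120, 0, 0.3)
  fit1 <- fit_monotone_smoother(x, y)
  ord <- sample(120)
  fit2 <- fit_monotone_smoother(x[ord], y[ord])
  grid <- seq(min(x), max(x), length.out = 50)
  expect_equal(predict(fit1, grid), predict(fit2, grid), tolerance = 1e-8)
  expect_warning(p_out <- predict(fit1, c(-1, 6)), "clamp")
  expect_equal(p_out[1], predict(fit1, min(x)))
  expect_equal(p_out[2], predict(fit1, max(x)))

  set.seed(31)
  band <- predict(fit1, grid, interval = "bootstrap", n_boot = 120)
  truth <- grid
  cover <- mean(truth >= band$lower & truth <= band$upper)
  expect_gte(cover, 0.80)
})

test_that("residual sign analysis counts points above the line and flags degeneracy", {
  x <- seq(1, 20)
  fit <- fit_monotone_smoother(x, x)
  above <- data.frame(comprehension = x, production = x + 1)
  res <- residual_sign_analysis(above, fit)
  expect_equal(res$proportion, 1)
  expect_lt(res$p, 1e-4)

  on_line <- data.frame(comprehension = x, production = predict(fit, x))
  deg <- residual_sign_analysis(on_line, fit)
  expect_true(isTRUE(deg$degenerate))
  expect_true(is.na(deg$p))
  expect_error(residual_sign_analysis(above[0, ], fit), "non-empty")
})

test_that("run-point sampling returns k points per run, reproducibly", {
  fake_trace <- function(n) list(trace = data.frame(
    epoch = seq_len(n), comp = seq_len(n), prod = seq_len(n) - 1,
    qe_aud = 0, qe_vis = 0))
  traces <- replicate(20, fake_trace(400), simplify = FALSE)
  set.seed(5)
  pts <- sample_run_points(traces, 5)
  expect_equal(nrow(pts), 100)
  expect_equal(pts$comprehension, pts$epoch)
  set.seed(5)
  expect_identical(pts, sample_run_points(traces, 5))
  expect_equal(nrow(sample_run_points(traces, 0)), 0)
  expect_error(sample_run_points(list(fake_trace(3)), 5), "exceeds")
})
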