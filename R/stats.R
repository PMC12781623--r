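#' Exact binomial sign test
#'
#' Tests whether positive residuals outnumber negative ones beyond chance:
#' `p = P(X >= n_above)` for `X ~ Binomial(n_total, 1/2)` (one-sided,
#' greater), with a one-sided 95% Clopper-Pearson lower confidence bound for
#' the success probability. This is the machinery used both for the
#' empirical cohorts and for comparing model runs against the reference
#' prediction line.
#'
#' @param n_above Count of positive residuals.
#' @param n_total Total non-zero residuals (`>= 1`).
#' @return An object of class `"sign_test"`: list with `n_above`, `n_total`,
#'   `proportion`, `ci_lower` (one-sided 95% lower bound; the upper bound is
#'   1), and `p`.
#' @examples
#' exact_binomial_sign_test(47, 67)  # proportion 0.701, p < 0.001
#' @export
exact_binomial_sign_test <- function(n_above, n_total) {
  if (n_total < 1 || n_above < 0 || n_above > n_total)
    stop("need 0 <= n_above <= n_total with n_total >= 1", call. = FALSE)
  p <- stats::pbinom(n_above - 1, n_total, 0.5, lower.tail = FALSE)
  ci_lower <- if (n_above == 0) 0
              else stats::qbeta(0.05, n_above, n_total - n_above + 1)
  structure(list(n_above = n_above, n_total = n_total,
                 proportion = n_above / n_total,
                 ci_lower = ci_lower, p = p),
            class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf(
    "Exact binomial sign test: %d/%d above (proportion %.3f, CI [%.3f, 1.000]), p = %.3g\n",
    x$n_above, x$n_total, x$proportion, x$ci_lower, x$p))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment of a family of p-values; the adjusted values are
#' monotone in the raw values and bounded by one.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1 | is.na(p_values)))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

# I-spline (integrated spline) basis: each column is non-decreasing, 0 at
# the left boundary and 1 at the right.  Built as upper-tail partial sums of
# a B-spline basis one degree higher on the same knots.
ispline_basis <- function(x, boundary, iknots, degree) {
  ord <- degree + 2L
  knots <- c(rep(boundary[1], ord), iknots, rep(boundary[2], ord))
  xc <- pmin(pmax(x, boundary[1]), boundary[2])
  B <- splines::splineDesign(knots, xc, ord = ord)
  nb <- ncol(B)
  # I_j = sum of B-spline columns j+1 .. nb
  sapply(seq_len(nb - 1L), function(j) rowSums(B[, (j + 1L):nb, drop = FALSE]))
}

#' Fit a monotone (non-decreasing) smoother
#'
#' Least-squares regression of `y` on an I-spline basis with coefficients
#' constrained non-negative plus a free intercept, giving a smooth fit that
#' is non-decreasing everywhere: the shape-constrained analogue of an
#' ordinary spline regression, mirroring a monotone-positive-increase
#' constraint. Interior knots (if the basis dimension calls for any) are
#' evenly spaced over the predictor range. The non-negative least-squares
#' problem is solved with the Lawson-Hanson algorithm
#' ([pracma::lsqnonneg()]) after profiling out the free intercept (for any
#' slope coefficients the optimal intercept is the mean residual, so the
#' basis and response are centred and the intercept recovered afterwards).
#'
#' @param x Predictor values.
#' @param y Response values.
#' @param basis_dim Number of I-spline basis functions (default 3).
#' @return An object of class `"monotone_fit"` with the basis definition,
#'   coefficients, fitted values and the training data (kept for bootstrap
#'   intervals).
#' @export
fit_monotone_smoother <- function(x, y, basis_dim = 3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(unique(x)) < 2)
    stop("x must contain at least two distinct values", call. = FALSE)
  if (length(x) < basis_dim + 2)
    stop("need at least basis_dim + 2 points", call. = FALSE)
  boundary <- range(x)
  degree <- min(3L, basis_dim - 1L)
  n_ik <- basis_dim - 1L - degree
  iknots <- if (n_ik > 0)
    seq(boundary[1], boundary[2], length.out = n_ik + 2L)[-c(1L, n_ik + 2L)]
  else numeric(0)
  Im <- ispline_basis(x, boundary, iknots, degree)
  Ic <- scale(Im, center = TRUE, scale = FALSE)
  sol <- pracma::lsqnonneg(Ic, y - mean(y))
  beta <- sol$x
  fit <- structure(list(boundary = boundary, iknots = iknots,
                        degree = degree, basis_dim = basis_dim,
                        intercept = mean(y) - sum(colMeans(Im) * beta),
                        beta = beta,
                        x = x, y = y),
                   class = "monotone_fit")
  fit$fitted <- predict(fit, x)
  fit
}

#' Predict from a monotone fit
#'
#' Evaluates the monotone smooth at new predictor values; predictions are
#' non-decreasing in `x_new`. Outside the fitted domain the smooth is
#' clamped to its boundary value (a warning flags extrapolation).
#' Optionally returns a bootstrap percentile confidence band
#' (resample-and-refit).
#'
#' @param object A `"monotone_fit"`.
#' @param x_new New predictor values (default: training values).
#' @param interval `"none"` or `"bootstrap"`.
#' @param level Confidence level for the bootstrap band.
#' @param n_boot Bootstrap replicates (default 200).
#' @param ... Unused.
#' @return A numeric vector, or (with `interval = "bootstrap"`) a data frame
#'   with `fit`, `lower`, `upper`.
#' @export
predict.monotone_fit <- function(object, x_new = object$x,
                                 interval = c("none", "bootstrap"),
                                 level = 0.95, n_boot = 200, ...) {
  interval <- match.arg(interval)
  if (any(x_new < object$boundary[1] - 1e-12 |
          x_new > object$boundary[2] + 1e-12))
    warning("extrapolating beyond the fitted domain; predictions clamped")
  Im <- ispline_basis(x_new, object$boundary, object$iknots, object$degree)
  fit <- drop(object$intercept + Im %*% object$beta)
  if (interval == "none") return(fit)
  n <- length(object$x)
  boots <- replicate(n_boot, {
    idx <- sample.int(n, n, replace = TRUE)
    bf <- tryCatch(fit_monotone_smoother(object$x[idx], object$y[idx],
                                         object$basis_dim),
                   error = function(e) NULL)
    if (is.null(bf)) rep(NA_real_, length(x_new))
    else suppressWarnings(stats::predict(bf, x_new))  # clamping intended
  })
  a <- (1 - level) / 2
  data.frame(fit = fit,
             lower = apply(boots, 1, stats::quantile, probs = a,
                           na.rm = TRUE),
             upper = apply(boots, 1, stats::quantile, probs = 1 - a,
                           na.rm = TRUE))
}

#' Sign test of observed points against a reference prediction line
#'
#' Computes residuals `r = production - predicted production at that
#' comprehension` under a reference monotone fit, drops exact zeros
#' (standard sign-test convention), and applies
#' [exact_binomial_sign_test()] to the count of positive residuals. A
#' significant result means production systematically exceeds the
#' reference expectation at matched comprehension, i.e. a reduced
#' comprehension-production gap.
#'
#' @param points Data frame with columns `comprehension` and `production`.
#' @param ref_fit A `"monotone_fit"` of production on comprehension for the
#'   reference population.
#' @return A `"sign_test"`, or (when every residual is exactly zero) a
#'   degenerate result with `degenerate = TRUE` and `p = NA`.
#' @export
residual_sign_analysis <- function(points, ref_fit) {
  if (nrow(points) == 0) stop("points must be non-empty", call. = FALSE)
  # clamped extrapolation is the intended behaviour for points beyond the
  # reference sample's comprehension range; predictions are floored at zero
  # because production is a count
  pred <- suppressWarnings(stats::predict(ref_fit, points$comprehension))
  pred <- pmax(pred, 0)
  r <- points$production - pred
  n_above <- sum(r > 0)
  n_total <- sum(r != 0)
  if (n_total == 0)
    return(structure(list(n_above = 0L, n_total = 0L, proportion = NA_real_,
                          ci_lower = NA_real_, p = NA_real_,
                          degenerate = TRUE),
                     class = "sign_test"))
  exact_binomial_sign_test(n_above, n_total)
}

#' Sample (comprehension, production) points from a batch of runs
#'
#' Draws `k_per_run` epochs uniformly without replacement from each run and
#' returns the per-epoch comprehension/production pairs; with 20 runs and 5
#' points each this yields the 100 points entering the model-level sign
#' test.
#'
#' @param traces List of `"training_trace"` objects.
#' @param k_per_run Points sampled per run.
#' @return Data frame with `run`, `epoch`, `comprehension`, `production`.
#' @export
sample_run_points <- function(traces, k_per_run = 5) {
  if (k_per_run == 0)
    return(data.frame(run = integer(), epoch = integer(),
                      comprehension = integer(), production = integer()))
  out <- lapply(seq_along(traces), function(i) {
    tr <- traces[[i]]$trace
    if (k_per_run > nrow(tr))
      stop("k_per_run exceeds the number of epochs", call. = FALSE)
    idx <- sort(sample.int(nrow(tr), k_per_run))
    data.frame(run = i, epoch = tr$epoch[idx],
               comprehension = tr$comp[idx], production = tr$prod[idx])
  })
  do.call(rbind, out)
}
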