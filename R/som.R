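#' Initialise a self-organising map
#'
#' Neurons live on a planar (non-toroidal) `rows x cols` grid in row-major
#' order: neuron `i` sits at grid row `(i - 1) %/% cols + 1`, column
#' `(i - 1) %% cols + 1`. Weights are i.i.d. uniform on \[0, 1\]^dim, the
#' same bounded space as the inputs, so weights provably stay in \[0, 1\]
#' throughout training.
#'
#' @param rows,cols Grid dimensions (12 x 12 reference; 9 x 9 reduced).
#' @param dim Weight dimensionality (default 10).
#' @param disrupted If `TRUE`, the neighbourhood function is disrupted:
#'   weight updates reach the best-matching unit only.
#' @return An object of class `"som"`: list with `rows`, `cols`, `dim`,
#'   `weights` (`(rows*cols) x dim` matrix, neurons in row-major order) and
#'   `disrupted`.
#' @export
init_map <- function(rows, cols, dim = 10, disrupted = FALSE) {
  if (rows < 1 || cols < 1 || dim < 1)
    stop("rows, cols and dim must be positive", call. = FALSE)
  n <- rows * cols
  structure(list(rows = rows, cols = cols, dim = dim,
                 weights = matrix(stats::runif(n * dim), nrow = n,
                                  byrow = TRUE),
                 disrupted = disrupted),
            class = "som")
}

#' @export
print.som <- function(x, ...) {
  cat(sprintf("SOM: %d x %d grid (%d neurons), %d-dim weights%s\n",
              x$rows, x$cols, x$rows * x$cols, x$dim,
              if (x$disrupted) ", neighbourhood disrupted" else ""))
  invisible(x)
}

# grid coordinates of neuron indices (row-major, 1-based)
grid_coords <- function(map, idx) {
  cbind(row = (idx - 1L) %/% map$cols + 1L,
        col = (idx - 1L) %% map$cols + 1L)
}

# squared input-weight distances to every neuron
neuron_sqdist <- function(map, x) {
  if (length(x) != map$dim)
    stop("input dimension does not match map", call. = FALSE)
  rowSums((map$weights - matrix(x, nrow(map$weights), map$dim,
                                byrow = TRUE))^2)
}

#' Find the best-matching unit
#'
#' The neuron whose weight vector minimises the Euclidean distance to the
#' input; ties are broken by the smallest row-major neuron index.
#'
#' @param map A `"som"` object.
#' @param x Input vector of length `map$dim`.
#' @return List with `index` (row-major neuron index), `row`, `col` and
#'   `distance` (Euclidean input-weight distance).
#' @export
find_bmu <- function(map, x) {
  d2 <- neuron_sqdist(map, x)
  i <- which.min(d2)
  rc <- grid_coords(map, i)
  list(index = i, row = rc[1, "row"], col = rc[1, "col"],
       distance = sqrt(d2[i]))
}

#' Neighbourhood kernel around a BMU
#'
#' Gaussian kernel on planar grid distance,
#' `h(i) = exp(-g(i, bmu)^2 / (2 sigma_n^2))`, so `h(bmu) = 1`. On a
#' disrupted map the kernel collapses to an indicator of the BMU: only the
#' winning neuron updates, which removes the topographic smoothing that
#' lets the map generalise across similar inputs.
#'
#' @param map A `"som"` object.
#' @param bmu Result of [find_bmu()] (or a list with `index`).
#' @param sigma_n Neighbourhood width (> 0), in grid units.
#' @return Numeric vector of per-neuron update coefficients in \[0, 1\].
#' @export
neighbourhood_kernel <- function(map, bmu, sigma_n) {
  if (sigma_n <= 0) stop("sigma_n must be positive", call. = FALSE)
  n <- map$rows * map$cols
  if (map$disrupted) {
    h <- numeric(n)
    h[bmu$index] <- 1
    return(h)
  }
  rc <- grid_coords(map, seq_len(n))
  brc <- grid_coords(map, bmu$index)
  g2 <- (rc[, "row"] - brc[1, "row"])^2 + (rc[, "col"] - brc[1, "col"])^2
  exp(-g2 / (2 * sigma_n^2))
}

#' Kohonen weight update
#'
#' `w_i <- w_i + alpha * h(i) * (x - w_i)` for every neuron. With inputs and
#' weights in \[0, 1\] and `alpha <= 1` the update is a convex combination,
#' so weights remain in \[0, 1\].
#'
#' @param map A `"som"` object.
#' @param x Input vector.
#' @param kernel Per-neuron coefficients from [neighbourhood_kernel()].
#' @param alpha Learning rate in (0, 1\].
#' @return The updated `"som"` object.
#' @export
update_weights <- function(map, x, kernel, alpha) {
  if (alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]", call. = FALSE)
  xm <- matrix(x, nrow(map$weights), map$dim, byrow = TRUE)
  map$weights <- map$weights + (alpha * kernel) * (xm - map$weights)
  map
}

#' Quantisation error of a map over an exemplar set
#'
#' Mean Euclidean distance between each exemplar and its best-matching
#' unit's weight vector. Lower values mean internal representations that
#' match the input more closely.
#'
#' @param map A `"som"` object.
#' @param exemplars Matrix of exemplars (one per row).
#' @return Non-negative scalar.
#' @export
quantisation_error <- function(map, exemplars) {
  if (is.null(dim(exemplars))) exemplars <- matrix(exemplars, nrow = 1)
  if (nrow(exemplars) == 0)
    stop("exemplar set must be non-empty", call. = FALSE)
  d <- vapply(seq_len(nrow(exemplars)),
              function(i) sqrt(min(neuron_sqdist(map, exemplars[i, ]))),
              numeric(1))
  sum(d) / length(d)
}

#' Graded activation field of a map for one input
#'
#' `a(i) = exp(-||x - w_i||^2 / (2 kappa^2))`, normalised to sum one. The
#' field peaks at the BMU and decays with input-weight distance; it is the
#' co-activation signal consumed by Hebbian learning. Computed relative to
#' the BMU distance for numerical stability (the normalised field is
#' unchanged).
#'
#' @param map A `"som"` object.
#' @param x Input vector.
#' @param kappa Sharpness (> 0); smaller values approach a one-hot field at
#'   the BMU.
#' @return Numeric vector summing to one, maximal at the BMU.
#' @export
activation_pattern <- function(map, x, kappa) {
  if (kappa <= 0) stop("kappa must be positive", call. = FALSE)
  d2 <- neuron_sqdist(map, x)
  a <- exp(-(d2 - min(d2)) / (2 * kappa^2))
  a / sum(a)
}

#' Write map state to CSV
#'
#' One row per neuron: grid `row`, `col`, then weight components
#' `w0..w<dim-1>`. Intended for BMU/cluster visualisation by external tools.
#'
#' @param map A `"som"` object.
#' @param path Output file path.
#' @export
write_map_csv <- function(map, path) {
  rc <- grid_coords(map, seq_len(map$rows * map$cols))
  w <- as.data.frame(map$weights)
  names(w) <- paste0("w", seq_len(map$dim) - 1L)
  utils::write.csv(cbind(as.data.frame(rc), w), path, row.names = FALSE)
  invisible(path)
}
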