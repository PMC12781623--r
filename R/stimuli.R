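#' Generate category prototypes
#'
#' Draws one prototype vector per word category, with components i.i.d.
#' uniform on \[0, 1\]. Prototypes anchor the artificial vocabulary: every
#' exemplar of a category is a Gaussian perturbation of its prototype.
#'
#' @param n_categories Number of word categories (default 20).
#' @param dim Dimensionality of each vector (default 10).
#' @return A `n_categories x dim` numeric matrix, one prototype per row.
#' @seealso [generate_exemplars()], [make_vocabulary()]
#' @export
generate_prototypes <- function(n_categories = 20, dim = 10) {
  if (n_categories < 1 || dim < 1)
    stop("n_categories and dim must be positive", call. = FALSE)
  matrix(stats::runif(n_categories * dim), nrow = n_categories,
         byrow = TRUE)
}

#' Generate exemplars around category prototypes
#'
#' Each exemplar is its prototype plus i.i.d. Gaussian noise of standard
#' deviation `sigma` per component, clipped to \[0, 1\]. With `sigma = 0`
#' exemplars equal their prototypes exactly.
#'
#' @param prototypes Matrix of prototypes (one per row).
#' @param n_exemplars Exemplars per category (default 8).
#' @param sigma Within-category standard deviation.
#' @return A `(n_categories * n_exemplars) x dim` matrix with rows grouped by
#'   category; row `(c - 1) * n_exemplars + j` is exemplar `j` of category
#'   `c`. The `"category"` attribute holds the category index of each row.
#' @export
generate_exemplars <- function(prototypes, n_exemplars = 8, sigma) {
  if (sigma < 0) stop("sigma must be non-negative", call. = FALSE)
  ncat <- nrow(prototypes)
  dim <- ncol(prototypes)
  out <- matrix(0, nrow = ncat * n_exemplars, ncol = dim)
  cat_idx <- integer(ncat * n_exemplars)
  for (c in seq_len(ncat)) {
    for (j in seq_len(n_exemplars)) {
      r <- (c - 1L) * n_exemplars + j
      x <- prototypes[c, ] + sigma * stats::rnorm(dim)
      out[r, ] <- pmin(pmax(x, 0), 1)
      cat_idx[r] <- c
    }
  }
  attr(out, "category") <- cat_idx
  out
}

#' Build the paired auditory/visual artificial vocabulary
#'
#' Draws independent auditory and visual prototype sets and generates
#' modality-specific exemplar clouds. Auditory within-category variability is
#' small (word forms are phonologically stable) and visual variability large
#' (referents vary in appearance); this statistical asymmetry is what drives
#' the comprehension-production gap in the model. Category `i` in one
#' modality is paired with category `i` in the other.
#'
#' @param n_categories Number of words (default 20).
#' @param n_exemplars Exemplars per category per modality (default 8).
#' @param dim Vector dimensionality (default 10).
#' @param sigma_aud Auditory within-category SD (default 0.05).
#' @param sigma_vis Visual within-category SD (default 0.25).
#' @return An object of class `"vocabulary"`: a list with `aud_prototypes`,
#'   `vis_prototypes`, `aud_exemplars`, `vis_exemplars`, `aud_centroids` /
#'   `vis_centroids` (per-category exemplar means, the decoding reference
#'   vectors; equal to the prototypes when `sigma = 0`), `category` (index
#'   of each exemplar row) and the generating parameters.
#' @examples
#' set.seed(1)
#' voc <- make_vocabulary()
#' nrow(voc$aud_exemplars)  # 160 patterns per modality
#' @export
make_vocabulary <- function(n_categories = 20, n_exemplars = 8, dim = 10,
                            sigma_aud = 0.05, sigma_vis = 0.25) {
  ap <- generate_prototypes(n_categories, dim)
  vp <- generate_prototypes(n_categories, dim)
  ae <- generate_exemplars(ap, n_exemplars, sigma_aud)
  ve <- generate_exemplars(vp, n_exemplars, sigma_vis)
  cat_idx <- attr(ae, "category")
  centroid <- function(mat) t(vapply(seq_len(n_categories), function(c)
    colMeans(mat[cat_idx == c, , drop = FALSE]), numeric(dim)))
  structure(list(aud_prototypes = ap, vis_prototypes = vp,
                 aud_exemplars = ae, vis_exemplars = ve,
                 aud_centroids = centroid(ae), vis_centroids = centroid(ve),
                 category = cat_idx,
                 n_categories = n_categories, n_exemplars = n_exemplars,
                 dim = dim, sigma_aud = sigma_aud, sigma_vis = sigma_vis),
            class = "vocabulary")
}

#' @export
print.vocabulary <- function(x, ...) {
  cat(sprintf("Artificial vocabulary: %d categories x %d exemplars, %d-dim\n",
              x$n_categories, x$n_exemplars, x$dim))
  cat(sprintf("  sigma_aud = %g, sigma_vis = %g (%d patterns per modality)\n",
              x$sigma_aud, x$sigma_vis, nrow(x$aud_exemplars)))
  invisible(x)
}

#' Apply presentation-time input noise
#'
#' Adds fresh i.i.d. Gaussian noise to an input vector and clips to \[0, 1\].
#' This models encoding-time perceptual unreliability: the noise is redrawn
#' on every presentation, never frozen into the exemplar.
#'
#' @param x Input vector.
#' @param sigma_noise Noise standard deviation (0 = no-op).
#' @return The perturbed, clipped vector.
#' @export
apply_input_noise <- function(x, sigma_noise) {
  if (sigma_noise < 0) stop("sigma_noise must be non-negative", call. = FALSE)
  if (sigma_noise == 0) return(x)
  pmin(pmax(x + sigma_noise * stats::rnorm(length(x)), 0), 1)
}

#' Write a vocabulary to CSV
#'
#' Long format with columns `modality`, `category`, `exemplar_index`,
#' `v0..v<dim-1>`; prototypes are stored with `exemplar_index = -1`.
#'
#' @param voc A `"vocabulary"` object.
#' @param path Output file path.
#' @export
write_vocabulary_csv <- function(voc, path) {
  dim <- voc$dim
  block <- function(mat, modality, idx) {
    df <- as.data.frame(mat)
    names(df) <- paste0("v", seq_len(dim) - 1L)
    cbind(data.frame(modality = modality,
                     category = if (length(idx) == 1 && idx == -1)
                       seq_len(nrow(mat)) else voc$category,
                     exemplar_index = if (length(idx) == 1 && idx == -1)
                       -1L else idx),
          df)
  }
  ex_idx <- rep(seq_len(voc$n_exemplars), voc$n_categories)
  out <- rbind(block(voc$aud_prototypes, "aud", -1),
               block(voc$aud_exemplars, "aud", ex_idx),
               block(voc$vis_prototypes, "vis", -1),
               block(voc$vis_exemplars, "vis", ex_idx))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a vocabulary written by [write_vocabulary_csv()]
#'
#' @param path CSV file path.
#' @return A `"vocabulary"` object.
#' @export
read_vocabulary_csv <- function(path) {
  df <- utils::read.csv(path)
  vcols <- grep("^v[0-9]+$", names(df), value = TRUE)
  dim <- length(vcols)
  pick <- function(modality, proto) {
    sel <- df$modality == modality &
      (if (proto) df$exemplar_index == -1 else df$exemplar_index >= 1)
    sub <- df[sel, , drop = FALSE]
    sub <- sub[order(sub$category, sub$exemplar_index), , drop = FALSE]
    list(mat = as.matrix(sub[, vcols, drop = FALSE]), cat = sub$category)
  }
  ap <- pick("aud", TRUE); vp <- pick("vis", TRUE)
  ae <- pick("aud", FALSE); ve <- pick("vis", FALSE)
  ncat <- nrow(ap$mat)
  nex <- nrow(ae$mat) / ncat
  ex <- ae$mat; attr(ex, "category") <- ae$cat
  vx <- ve$mat; attr(vx, "category") <- ve$cat
  centroid <- function(mat, cat) unname(t(vapply(seq_len(ncat), function(c)
    colMeans(mat[cat == c, , drop = FALSE]), numeric(dim))))
  structure(list(aud_prototypes = unname(ap$mat),
                 vis_prototypes = unname(vp$mat),
                 aud_exemplars = unname(ex), vis_exemplars = unname(vx),
                 aud_centroids = centroid(ae$mat, ae$cat),
                 vis_centroids = centroid(ve$mat, ve$cat),
                 category = ae$cat, n_categories = ncat, n_exemplars = nex,
                 dim = dim, sigma_aud = NA_real_, sigma_vis = NA_real_),
            class = "vocabulary")
}
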