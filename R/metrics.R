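#' Area under a learning trajectory
#'
#' Trapezoidal area of a per-epoch count series over the epoch index; a
#' constant series of value `c` over `E` epochs has area `c * (E - 1)`. Used
#' as a cumulative words-learned measure: lower areas mean delayed learning.
#'
#' @param series Numeric vector of per-epoch counts.
#' @return Non-negative scalar.
#' @export
auc <- function(series) {
  n <- length(series)
  if (n == 0) stop("series must be non-empty", call. = FALSE)
  if (n == 1) return(0)
  sum((series[-1] + series[-n]) / 2)
}

#' Categorisation rating of a trained map
#'
#' Counts the distinct best-matching units recruited by an exemplar set and
#' normalises by the map's neuron count. Low values indicate compact,
#' prototype-based category representations (many exemplars share a BMU);
#' values near one indicate fragmented, exemplar-based representations in
#' which the map treats instances as isolated objects.
#'
#' @param map A trained `"som"`.
#' @param exemplars Exemplar matrix, or `NULL` if `bmus` is given.
#' @param bmus Optional precomputed BMU indices (as returned in a
#'   `"training_trace"`), which bypasses the BMU search.
#' @return List with `n_distinct_bmus`, `n_neurons` and `rating` in (0, 1\].
#' @export
categorisation_rating <- function(map, exemplars = NULL, bmus = NULL) {
  if (is.null(bmus)) {
    if (is.null(exemplars)) stop("need exemplars or bmus", call. = FALSE)
    bmus <- vapply(seq_len(nrow(exemplars)),
                   function(i) find_bmu(map, exemplars[i, ])$index,
                   integer(1))
  }
  n_neurons <- map$rows * map$cols
  nd <- length(unique(bmus))
  list(n_distinct_bmus = nd, n_neurons = n_neurons,
       rating = nd / n_neurons)
}

#' Summarise one training run
#'
#' Computes the trajectory areas, the comprehension-production gap
#' (`auc_comp - auc_prod`), final quantisation errors, and the auditory and
#' visual categorisation ratings (distinct BMUs of the noise-free exemplar
#' set at the final epoch, normalised by map size).
#'
#' @param result A `"training_trace"` from [train_model()].
#' @return A one-row data frame.
#' @export
run_summary <- function(result) {
  tr <- result$trace
  ac <- auc(tr$comp)
  ap <- auc(tr$prod)
  ca <- categorisation_rating(result$model$aud_map, bmus = result$bmu_aud)
  cv <- categorisation_rating(result$model$vis_map, bmus = result$bmu_vis)
  data.frame(config = result$config$name, seed = result$seed,
             auc_comp = ac, auc_prod = ap, gap = ac - ap,
             final_comp = tr$comp[nrow(tr)], final_prod = tr$prod[nrow(tr)],
             qe_aud = tr$qe_aud[nrow(tr)], qe_vis = tr$qe_vis[nrow(tr)],
             cat_aud = ca$rating, cat_vis = cv$rating)
}

#' AUC deltas between a tested model and the reference batch
#'
#' Delta = mean(test) - mean(reference) for the comprehension and production
#' areas; negative values indicate delays. Significance is assessed with
#' Welch two-sample t-tests on the run-level areas; the returned p-values
#' are intended for Benjamini-Hochberg correction across the model family
#' (see [bh_fdr()]).
#'
#' @param test_runs,ref_runs Data frames of run summaries (rows from
#'   [run_summary()]), at least two runs per side.
#' @return List with `delta_comp`, `delta_prod`, `t_comp`, `t_prod`,
#'   `p_comp`, `p_prod`.
#' @export
delta_auc <- function(test_runs, ref_runs) {
  if (nrow(test_runs) < 2 || nrow(ref_runs) < 2)
    stop("need at least two runs per side", call. = FALSE)
  one <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      list(delta = mean(a) - mean(b), t = 0, p = 1)
    } else {
      tt <- stats::t.test(a, b)
      list(delta = mean(a) - mean(b), t = unname(tt$statistic),
           p = tt$p.value)
    }
  }
  dc <- one(test_runs$auc_comp, ref_runs$auc_comp)
  dp <- one(test_runs$auc_prod, ref_runs$auc_prod)
  list(delta_comp = dc$delta, delta_prod = dp$delta,
       t_comp = dc$t, t_prod = dp$t, p_comp = dc$p, p_prod = dp$p)
}
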