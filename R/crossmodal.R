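#' Initialise a lexical model from a configuration
#'
#' Builds the two maps (sized per the configuration, with their disruption
#' flags) and an all-zero Hebbian bridge of dimension
#' `(auditory neurons) x (visual neurons)`. Both maps are structurally
#' identical mechanisms; their differentiation into "auditory" and "visual"
#' arises only from the statistics of the input each receives.
#'
#' @param config A `"model_config"`.
#' @param vocabulary A `"vocabulary"` (stored with the model).
#' @return An object of class `"lexical_model"`: list with `aud_map`,
#'   `vis_map`, `bridge` (weights matrix), `config`, `vocabulary`.
#' @export
init_model <- function(config, vocabulary) {
  if (vocabulary$dim < 1) stop("invalid vocabulary", call. = FALSE)
  aud <- init_map(config$aud_grid[1], config$aud_grid[2], vocabulary$dim,
                  disrupted = config$disrupt_aud)
  vis <- init_map(config$vis_grid[1], config$vis_grid[2], vocabulary$dim,
                  disrupted = config$disrupt_vis)
  structure(list(aud_map = aud, vis_map = vis,
                 bridge = matrix(0, nrow(aud$weights), nrow(vis$weights)),
                 config = config, vocabulary = vocabulary),
            class = "lexical_model")
}

#' @export
print.lexical_model <- function(x, ...) {
  cat(sprintf("Lexical model '%s': aud %dx%d, vis %dx%d, bridge %dx%d\n",
              x$config$name, x$aud_map$rows, x$aud_map$cols,
              x$vis_map$rows, x$vis_map$cols,
              nrow(x$bridge), ncol(x$bridge)))
  invisible(x)
}

#' Hebbian update of the cross-modal bridge
#'
#' Strengthens associations between co-activated auditory and visual
#' neurons: `w(a, v) <- w(a, v) + eta * act_aud(a) * act_vis(v)`. Any
#' auditory row whose total mass then exceeds one is divisively rescaled to
#' sum one, bounding the association weights (unnormalised Hebbian growth is
#' otherwise unbounded).
#'
#' @param bridge Association-weight matrix (auditory x visual neurons).
#' @param act_aud,act_vis Normalised activation fields (each sums to one).
#' @param eta Hebbian learning rate.
#' @return The updated bridge matrix.
#' @export
hebbian_update <- function(bridge, act_aud, act_vis, eta) {
  if (length(act_aud) != nrow(bridge) || length(act_vis) != ncol(bridge))
    stop("activation fields do not match bridge dimensions", call. = FALSE)
  bridge <- bridge + eta * outer(act_aud, act_vis)
  rs <- rowSums(bridge)
  idx <- rs > 1
  if (any(idx)) bridge[idx, ] <- bridge[idx, ] / rs[idx]
  bridge
}

#' Propagate an activation field across the bridge
#'
#' Auditory-to-visual: `out(v) = sum_a act(a) w(a, v)`; visual-to-auditory
#' uses the transposed weights. The output is renormalised to sum one when
#' its total mass is positive; an all-zero (untrained) bridge yields a flat
#' zero field, which decodes as undefined.
#'
#' @param bridge Association-weight matrix.
#' @param activation Normalised activation field on the source map.
#' @param direction `"aud2vis"` or `"vis2aud"`.
#' @return Activation field on the target map.
#' @export
propagate <- function(bridge, activation, direction = c("aud2vis", "vis2aud")) {
  direction <- match.arg(direction)
  if (direction == "aud2vis") {
    if (length(activation) != nrow(bridge))
      stop("activation length does not match bridge", call. = FALSE)
    out <- colSums(activation * bridge)
  } else {
    if (length(activation) != ncol(bridge))
      stop("activation length does not match bridge", call. = FALSE)
    out <- rowSums(bridge * matrix(activation, nrow(bridge), ncol(bridge),
                                   byrow = TRUE))
  }
  tot <- sum(out)
  if (tot > 0) out <- out / tot
  out
}

#' Decode the category expressed by an activation field
#'
#' Reference vectors are the per-category exemplar centroids — the mean of
#' the category's clipped exemplars, equal to the generating prototype when
#' `sigma = 0`. The centroid is what a trained map actually represents:
#' with large within-category variability, clipping to \[0, 1\] shifts the
#' cloud mean away from the raw prototype, and decoding against the
#' centroid avoids misattributing responses on that account.
#'
#' Three rules are provided. `"mass"` (the default) takes the field's
#' centre of mass in weight space, `wbar = sum_i field(i) w_i`, and decodes
#' to the nearest centroid: the whole distributed pattern is read out
#' (robust for the diffuse fields that propagation produces), while
#' cross-category bleed in the field still drags `wbar` toward competing
#' centroids and degrades the readout — the competition that makes
#' production the harder direction. `"region"` partitions the neurons by
#' nearest centroid and decodes to the region carrying the most field
#' mass. `"winner"` decodes to the category whose centroid is nearest to
#' the argmax neuron's weight vector (row-major tie-break). A flat field
#' carries no information and decodes to `NA` (counted as incorrect in
#' lexical testing).
#'
#' @param map The `"som"` the field lives on.
#' @param field Per-neuron activation field.
#' @param vocabulary A `"vocabulary"`.
#' @param modality `"aud"` or `"vis"` (selects the centroid set).
#' @param method `"mass"`, `"region"` or `"winner"`.
#' @return Category index, or `NA_integer_` if the field is uninformative.
#' @export
decode_category <- function(map, field, vocabulary,
                            modality = c("vis", "aud"),
                            method = c("mass", "region", "winner")) {
  modality <- match.arg(modality)
  method <- match.arg(method)
  if (max(field) - min(field) < 1e-15) return(NA_integer_)
  ref <- if (modality == "vis") vocabulary$vis_centroids
         else vocabulary$aud_centroids
  nearest_ref <- function(w) {
    which.min(rowSums((ref - matrix(w, nrow(ref), length(w),
                                    byrow = TRUE))^2))
  }
  if (method == "winner") {
    return(nearest_ref(map$weights[which.max(field), ]))
  }
  if (method == "mass") {
    wbar <- colSums(field * map$weights)
    return(nearest_ref(wbar))
  }
  region <- vapply(seq_len(nrow(map$weights)),
                   function(i) nearest_ref(map$weights[i, ]), integer(1))
  mass <- vapply(seq_len(nrow(ref)),
                 function(c) sum(field[region == c]), numeric(1))
  which.max(mass)
}

# shared word-level test: present all exemplars of each category on the
# source map, propagate across the bridge, decode on the target map; a word
# counts as known under a strict majority of correct decodings
lexical_test <- function(model, vocabulary, direction) {
  ncat <- vocabulary$n_categories
  nex <- vocabulary$n_exemplars
  if (direction == "aud2vis") {
    src_map <- model$aud_map; tgt_map <- model$vis_map
    ex <- vocabulary$aud_exemplars; tgt_mod <- "vis"
  } else {
    src_map <- model$vis_map; tgt_map <- model$aud_map
    ex <- vocabulary$vis_exemplars; tgt_mod <- "aud"
  }
  kappa <- model$config$kappa
  known <- 0L
  for (c in seq_len(ncat)) {
    correct <- 0L
    for (j in seq_len(nex)) {
      x <- ex[(c - 1L) * nex + j, ]
      act <- activation_pattern(src_map, x, kappa)
      out <- propagate(model$bridge, act, direction)
      dec <- decode_category(tgt_map, out, vocabulary, tgt_mod,
                             method = model$config$decode)
      if (!is.na(dec) && dec == c) correct <- correct + 1L
    }
    if (2L * correct > nex) known <- known + 1L
  }
  known
}

#' Test lexical comprehension
#'
#' For each word, presents each of its auditory exemplars in isolation
#' (noise-free), propagates the activation to the visual map and decodes;
#' the word counts as comprehended if a strict majority of exemplars decode
#' to the correct category.
#'
#' @param model A `"lexical_model"`.
#' @param vocabulary Vocabulary to test on (defaults to the model's own).
#' @return Number of comprehended words (0..n_categories).
#' @export
test_comprehension <- function(model, vocabulary = model$vocabulary) {
  lexical_test(model, vocabulary, "aud2vis")
}

#' Test lexical production
#'
#' Symmetric to [test_comprehension()]: visual exemplars in, visual-to-
#' auditory propagation, strict majority per word.
#'
#' @inheritParams test_comprehension
#' @return Number of produced words (0..n_categories).
#' @export
test_production <- function(model, vocabulary = model$vocabulary) {
  lexical_test(model, vocabulary, "vis2aud")
}

# Fisher-Yates shuffle, index arithmetic identical to the C++ engine so the
# two engines consume the RNG stream identically
fy_shuffle <- function(v) {
  n <- length(v)
  if (n < 2L) return(v)
  for (i in n:2L) {
    j <- floor(stats::runif(1) * i) + 1L
    tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
  }
  v
}

# pure-R training engine: the readable reference implementation built from
# the exported unit operations; bit-identical to the C++ engine
train_run_r <- function(config, vocabulary, model) {
  ncat <- vocabulary$n_categories
  nex <- vocabulary$n_exemplars
  npat <- ncat * nex
  n_epochs <- config$n_epochs
  rad_start_aud <- max(config$aud_grid) / 2
  rad_start_vis <- max(config$vis_grid) / 2
  trace <- data.frame(epoch = seq_len(n_epochs), comp = 0L, prod = 0L,
                      qe_aud = 0, qe_vis = 0)
  ep_bmu_a <- integer(npat)
  ep_bmu_v <- integer(npat)
  for (t in seq_len(n_epochs)) {
    frac <- if (n_epochs > 1) (t - 1) / (n_epochs - 1) else 0
    if (identical(config$decay, "exponential")) {
      alpha <- config$lr_start * (config$lr_end / config$lr_start)^frac
      sig_a <- rad_start_aud * (config$radius_end / rad_start_aud)^frac
      sig_v <- rad_start_vis * (config$radius_end / rad_start_vis)^frac
    } else {
      alpha <- config$lr_start + (config$lr_end - config$lr_start) * frac
      sig_a <- rad_start_aud + (config$radius_end - rad_start_aud) * frac
      sig_v <- rad_start_vis + (config$radius_end - rad_start_vis) * frac
    }

    ord <- fy_shuffle(seq_len(npat))
    vis_of <- integer(npat)
    for (c in seq_len(ncat)) {
      perm <- fy_shuffle(seq_len(nex))
      vis_of[(c - 1L) * nex + seq_len(nex)] <- (c - 1L) * nex + perm
    }

    p <- 0L
    for (e in ord) {
      p <- p + 1L
      xa <- vocabulary$aud_exemplars[e, ]
      xv <- vocabulary$vis_exemplars[vis_of[e], ]
      if (config$noise_aud > 0) xa <- apply_input_noise(xa, config$noise_aud)
      if (config$noise_vis > 0) xv <- apply_input_noise(xv, config$noise_vis)

      ba <- find_bmu(model$aud_map, xa)
      bv <- find_bmu(model$vis_map, xv)
      if (t == n_epochs) {
        ep_bmu_a[p] <- ba$index
        ep_bmu_v[p] <- bv$index
      }
      model$aud_map <- update_weights(
        model$aud_map, xa, neighbourhood_kernel(model$aud_map, ba, sig_a),
        alpha)
      model$vis_map <- update_weights(
        model$vis_map, xv, neighbourhood_kernel(model$vis_map, bv, sig_v),
        alpha)

      act_a <- activation_pattern(model$aud_map, xa, config$kappa)
      act_v <- activation_pattern(model$vis_map, xv, config$kappa)
      model$bridge <- hebbian_update(model$bridge, act_a, act_v, config$eta)
    }

    trace$comp[t] <- test_comprehension(model, vocabulary)
    trace$prod[t] <- test_production(model, vocabulary)
    trace$qe_aud[t] <- quantisation_error(model$aud_map,
                                          vocabulary$aud_exemplars)
    trace$qe_vis[t] <- quantisation_error(model$vis_map,
                                          vocabulary$vis_exemplars)
  }
  bmu_a <- vapply(seq_len(npat), function(e)
    find_bmu(model$aud_map, vocabulary$aud_exemplars[e, ])$index, integer(1))
  bmu_v <- vapply(seq_len(npat), function(e)
    find_bmu(model$vis_map, vocabulary$vis_exemplars[e, ])$index, integer(1))
  list(trace = trace, model = model, bmu_aud = bmu_a, bmu_vis = bmu_v,
       epoch_bmu_aud = ep_bmu_a, epoch_bmu_vis = ep_bmu_v)
}

#' Train a lexical model
#'
#' Runs the full epoch loop: each epoch shuffles the paired presentations,
#' re-pairs auditory exemplars with same-category visual exemplars (fresh
#' pairing every epoch, emulating hearing a word from different speakers
#' while viewing different referents), applies presentation noise if
#' configured, updates both maps and the Hebbian bridge, then tests
#' comprehension and production and records per-modality quantisation error
#' on the noise-free exemplar sets.
#'
#' The trace is a pure function of `(config, vocabulary, seed)`. The
#' default engine is compiled; `engine = "r"` runs the reference
#' implementation built from the exported unit operations and produces
#' bit-identical results (it is far slower and intended for verification).
#'
#' @param config A `"model_config"`.
#' @param vocabulary A `"vocabulary"`.
#' @param seed Integer seed for the run.
#' @param engine `"cpp"` (default) or `"r"`.
#' @return An object of class `"training_trace"`: list with `trace` (data
#'   frame `epoch`, `comp`, `prod`, `qe_aud`, `qe_vis`), `model` (the
#'   trained `"lexical_model"`), `bmu_aud`/`bmu_vis` (final BMU index of
#'   every noise-free exemplar), `epoch_bmu_aud`/`epoch_bmu_vis` (the
#'   winner of every presentation during the final training epoch, i.e.
#'   under presentation noise if configured), `seed` and `config`.
#' @export
train_model <- function(config, vocabulary, seed, engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  set.seed(seed)
  model <- init_model(config, vocabulary)
  if (config$n_epochs == 0L) {
    res <- list(trace = data.frame(epoch = integer(), comp = integer(),
                                   prod = integer(), qe_aud = numeric(),
                                   qe_vis = numeric()),
                model = model,
                bmu_aud = integer(), bmu_vis = integer(),
                epoch_bmu_aud = integer(), epoch_bmu_vis = integer())
  } else if (engine == "r") {
    res <- train_run_r(config, vocabulary, model)
  } else {
    raw <- cpp_train_run(
      vocabulary$aud_exemplars, vocabulary$vis_exemplars,
      as.integer(vocabulary$category),
      vocabulary$aud_centroids, vocabulary$vis_centroids,
      model$aud_map$weights, model$vis_map$weights,
      config$aud_grid[1], config$aud_grid[2],
      config$vis_grid[1], config$vis_grid[2],
      config$noise_aud, config$noise_vis,
      config$disrupt_aud, config$disrupt_vis,
      config$n_epochs, config$lr_start, config$lr_end,
      max(config$aud_grid) / 2, max(config$vis_grid) / 2,
      config$radius_end, config$eta, config$kappa,
      vocabulary$n_exemplars, config$test_noise,
      identical(config$decay, "exponential"),
      switch(config$decode, region = 1L, mass = 2L, 0L))
    model$aud_map$weights <- raw$W_aud
    model$vis_map$weights <- raw$W_vis
    model$bridge <- raw$bridge
    res <- list(trace = data.frame(epoch = seq_len(config$n_epochs),
                                   comp = raw$comp, prod = raw$prod,
                                   qe_aud = raw$qe_aud, qe_vis = raw$qe_vis),
                model = model, bmu_aud = raw$bmu_aud, bmu_vis = raw$bmu_vis,
                epoch_bmu_aud = raw$epoch_bmu_aud,
                epoch_bmu_vis = raw$epoch_bmu_vis)
  }
  res$seed <- seed
  res$config <- config
  class(res) <- "training_trace"
  res
}

#' @export
print.training_trace <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("Training trace '%s' (seed %d): %d epochs\n",
              x$config$name, x$seed, nrow(tr)))
  if (nrow(tr) > 0)
    cat(sprintf("  final comprehension %d/%d, production %d/%d\n",
                tr$comp[nrow(tr)], x$model$vocabulary$n_categories,
                tr$prod[nrow(tr)], x$model$vocabulary$n_categories))
  invisible(x)
}

#' Write a training trace to CSV
#'
#' Columns: `run_id`, `seed`, `epoch`, `comp`, `prod`, `qe_aud`, `qe_vis`.
#'
#' @param result A `"training_trace"`.
#' @param path Output path.
#' @param run_id Identifier recorded in the `run_id` column.
#' @export
write_trace_csv <- function(result, path, run_id = 1L) {
  out <- cbind(data.frame(run_id = run_id, seed = result$seed),
               result$trace)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
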