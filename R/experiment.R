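#' Derive a per-run seed from a master seed
#'
#' Pure function of `(master_seed, run index, offset)`; keeps every derived
#' seed inside the 32-bit integer range so independent, reproducible streams
#' can be handed to [train_model()] without global state.
#'
#' @param master_seed Integer master seed.
#' @param run Run index (1-based).
#' @param offset Stream offset (0 = vocabulary stream, 1 = training stream).
#' @return Integer seed.
#' @export
derive_run_seed <- function(master_seed, run, offset = 0L) {
  as.integer((as.numeric(master_seed) + 104729 * run + 7919 * offset) %%
               2147483647)
}

#' Run a batch of independent simulations of one configuration
#'
#' The artificial vocabulary is a fixed stimulus set: it is drawn once from
#' the master seed and shared by every run of the batch, so runs differ only
#' in map initialisation, presentation order and presentation noise. Because
#' the vocabulary and the per-run training seeds depend only on
#' `(master_seed, run)` and not on the configuration, batches of different
#' variants under the same master seed are paired run-for-run on identical
#' stimuli.
#'
#' @param config A `"model_config"`.
#' @param master_seed Master seed for the batch.
#' @param n_runs Number of runs (defaults to `config$n_runs`).
#' @param vocabulary Optional `"vocabulary"` to use instead of drawing one
#'   from the master seed.
#' @param quiet Suppress per-run progress messages.
#' @return An object of class `"run_batch"`: list with `traces` (list of
#'   `"training_trace"`), `summaries` (data frame, one row per run) and
#'   `config`.
#' @export
run_batch <- function(config, master_seed, n_runs = config$n_runs,
                      vocabulary = NULL, quiet = TRUE) {
  if (is.null(vocabulary)) {
    set.seed(derive_run_seed(master_seed, 0L, 0L))
    vocabulary <- make_vocabulary()
  }
  voc <- vocabulary
  traces <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    traces[[i]] <- train_model(config, voc,
                               seed = derive_run_seed(master_seed, i, 1L))
    if (!quiet)
      message(sprintf("[%s] run %d/%d: comp %d, prod %d", config$name, i,
                      n_runs, traces[[i]]$trace$comp[config$n_epochs],
                      traces[[i]]$trace$prod[config$n_epochs]))
  }
  summaries <- do.call(rbind, lapply(traces, run_summary))
  structure(list(traces = traces, summaries = summaries, config = config),
            class = "run_batch")
}

#' @export
print.run_batch <- function(x, ...) {
  cat(sprintf("Batch '%s': %d runs\n", x$config$name, nrow(x$summaries)))
  cat(sprintf("  mean AUC comp %.1f, prod %.1f, gap %.1f\n",
              mean(x$summaries$auc_comp), mean(x$summaries$auc_prod),
              mean(x$summaries$gap)))
  invisible(x)
}

#' Compare a tested batch against a reference batch
#'
#' Computes the AUC deltas with Welch t-tests, then mirrors the empirical
#' gap analysis: samples `k_per_run` (comprehension, production) points from
#' every run of each batch, fits the monotone reference line of production
#' on comprehension to the reference sample, and sign-tests the tested
#' sample against that line.
#'
#' @param test_batch,ref_batch `"run_batch"` objects.
#' @param k_per_run Points sampled per run (default 5).
#' @param seed Seed for the point sampling.
#' @param basis_dim I-spline basis dimension of the reference line.
#' @return List with `delta` (from [delta_auc()]), `sign_test`, the sampled
#'   points, and the batch gap means.
#' @export
compare_batches <- function(test_batch, ref_batch, k_per_run = 5,
                            seed = 1L, basis_dim = 3) {
  d <- delta_auc(test_batch$summaries, ref_batch$summaries)
  set.seed(seed)
  ref_pts <- sample_run_points(ref_batch$traces, k_per_run)
  test_pts <- sample_run_points(test_batch$traces, k_per_run)
  ref_fit <- fit_monotone_smoother(ref_pts$comprehension,
                                   ref_pts$production, basis_dim)
  st <- residual_sign_analysis(test_pts, ref_fit)
  list(delta = d, sign_test = st, ref_points = ref_pts,
       test_points = test_pts, ref_fit = ref_fit,
       gap_test = mean(test_batch$summaries$gap),
       gap_ref = mean(ref_batch$summaries$gap))
}

#' Simulate a configuration and write all artefacts to a directory
#'
#' Writes one trace CSV per run (`trace_<run>.csv`), the per-run summary
#' table (`summary.csv`), final map states
#' (`map_<run>_{aud,vis}.csv`), and an echo of the configuration
#' (`config.yaml`). Identical invocations produce identical files.
#'
#' @param config Configuration name (resolved via [get_config()]), YAML
#'   path, or a `"model_config"`.
#' @param seed Master seed.
#' @param out_dir Output directory (created if absent).
#' @param n_runs,n_epochs Optional overrides.
#' @param quiet Suppress progress messages.
#' @return The `"run_batch"`, invisibly.
#' @export
cmd_simulate <- function(config, seed, out_dir, n_runs = NULL,
                         n_epochs = NULL, quiet = FALSE) {
  if (is.character(config)) config <- get_config(config)
  if (!is.null(n_epochs)) config$n_epochs <- as.integer(n_epochs)
  if (!is.null(n_runs)) config$n_runs <- as.integer(n_runs)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!quiet)
    message(sprintf("simulating '%s': %d runs x %d epochs (seed %d)",
                    config$name, config$n_runs, config$n_epochs, seed))
  batch <- run_batch(config, seed, quiet = quiet)
  for (i in seq_along(batch$traces)) {
    write_trace_csv(batch$traces[[i]],
                    file.path(out_dir, sprintf("trace_%02d.csv", i)),
                    run_id = i)
    write_map_csv(batch$traces[[i]]$model$aud_map,
                  file.path(out_dir, sprintf("map_%02d_aud.csv", i)))
    write_map_csv(batch$traces[[i]]$model$vis_map,
                  file.path(out_dir, sprintf("map_%02d_vis.csv", i)))
  }
  utils::write.csv(batch$summaries, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  write_model_config(config, file.path(out_dir, "config.yaml"))
  invisible(batch)
}

# reload the traces written by cmd_simulate (trace data frames only)
read_trace_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "^trace_[0-9]+\\.csv$",
                           full.names = TRUE))
  if (length(files) == 0)
    stop(sprintf("no trace CSVs found in '%s'", dir), call. = FALSE)
  lapply(files, function(f) {
    df <- utils::read.csv(f)
    list(trace = df[, c("epoch", "comp", "prod", "qe_aud", "qe_vis")],
         seed = df$seed[1])
  })
}

#' Compare two simulation output directories
#'
#' Reads the trace CSVs written by [cmd_simulate()] from both directories,
#' computes the AUC deltas and the sign test of the tested model against the
#' reference prediction line, and writes a one-row comparison CSV.
#'
#' @param test_dir,ref_dir Directories of the tested and reference model.
#' @param out_file Output CSV path (`NULL` to skip writing).
#' @param seed Seed for the point sampling.
#' @param k_per_run Points sampled per run.
#' @return The comparison row as a data frame, invisibly.
#' @export
cmd_compare <- function(test_dir, ref_dir, out_file = NULL, seed = 1L,
                        k_per_run = 5) {
  test_traces <- read_trace_dir(test_dir)
  ref_traces <- read_trace_dir(ref_dir)
  summarise <- function(traces) {
    do.call(rbind, lapply(traces, function(x)
      data.frame(auc_comp = auc(x$trace$comp), auc_prod = auc(x$trace$prod))))
  }
  d <- delta_auc(summarise(test_traces), summarise(ref_traces))
  set.seed(seed)
  ref_pts <- sample_run_points(ref_traces, k_per_run)
  test_pts <- sample_run_points(test_traces, k_per_run)
  ref_fit <- fit_monotone_smoother(ref_pts$comprehension,
                                   ref_pts$production, 3)
  st <- residual_sign_analysis(test_pts, ref_fit)
  row <- data.frame(test_dir = test_dir, ref_dir = ref_dir,
                    delta_comp = d$delta_comp, delta_prod = d$delta_prod,
                    t_comp = d$t_comp, t_prod = d$t_prod,
                    p_comp = d$p_comp, p_prod = d$p_prod,
                    n_above = st$n_above, n_total = st$n_total,
                    proportion = st$proportion, ci_lower = st$ci_lower,
                    sign_p = st$p)
  if (!is.null(out_file)) utils::write.csv(row, out_file, row.names = FALSE)
  invisible(row)
}

#' Run the empirical CDI pipeline from a file or the synthetic generator
#'
#' @param input Path to a CDI CSV, or `NULL` with `synthetic = TRUE` to
#'   generate a cohort with [generate_cdi_dataset()].
#' @param seed Seed for the synthetic generator.
#' @param out_file Output CSV for the per-group sign-test table (`NULL` to
#'   skip writing).
#' @param synthetic Generate the cohort instead of reading a file.
#' @return The [empirical_pipeline()] result, invisibly.
#' @export
cmd_empirical <- function(input = NULL, seed = 1L, out_file = NULL,
                          synthetic = is.null(input)) {
  records <- if (synthetic) {
    set.seed(seed)
    generate_cdi_dataset()
  } else {
    read_cdi_csv(input)
  }
  res <- empirical_pipeline(records)
  if (!is.null(out_file))
    utils::write.csv(res$sign_tests, out_file, row.names = FALSE)
  invisible(res)
}
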