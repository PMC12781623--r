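# Oxford CDI ceiling: 418 words
CDI_MAX_WORDS <- 418L

#' Default cohort specifications for the synthetic CDI generator
#'
#' One spec per group with the study's group sizes and age ranges (TD
#' n = 1210, 12-25 months; WS n = 67, 7-74 months; DS n = 27, 11-40 months;
#' FXS n = 15, 14-47 months). Comprehension follows a logistic growth curve
#' in age with a group-specific rightward delay; production is a binomial
#' thinning of comprehension with group-specific retention `gamma`, which
#' encodes the gap structure: `gamma` is raised in WS (reduced gap),
#' canonical in DS, and lowered in FXS (enlarged production deficit). The
#' growth-curve and gap parameters are the generator's own calibration
#' choices, not empirical estimates.
#'
#' @return Named list of group specs (`group`, `n`, `age_range`,
#'   `asymptote`, `midpoint`, `rate`, `delay`, `gamma`, `gamma_sd`,
#'   `noise_sd`).
#' @export
default_group_specs <- function() {
  spec <- function(group, n, age_range, midpoint, rate, delay, gamma,
                   gamma_sd, asymptote = CDI_MAX_WORDS, noise_sd = 25) {
    list(group = group, n = n, age_range = age_range,
         asymptote = asymptote, midpoint = midpoint, rate = rate,
         delay = delay, gamma = gamma, gamma_sd = gamma_sd,
         noise_sd = noise_sd)
  }
  list(
    TD  = spec("TD", 1210L, c(12, 25), midpoint = 19, rate = 0.28,
               delay = 0,  gamma = 0.35, gamma_sd = 0.08),
    WS  = spec("WS",   67L, c(7.5, 73.6), midpoint = 19, rate = 0.14,
               delay = 22, gamma = 0.47, gamma_sd = 0.12),
    DS  = spec("DS",   27L, c(11.9, 39.3), midpoint = 19, rate = 0.14,
               delay = 16, gamma = 0.35, gamma_sd = 0.10),
    FXS = spec("FXS",  15L, c(14.8, 46.2), midpoint = 19, rate = 0.14,
               delay = 20, gamma = 0.15, gamma_sd = 0.06))
}

#' Generate a synthetic CDI-style dataset
#'
#' Per child: age uniform over the group range; comprehension is a clipped,
#' rounded logistic in age plus Gaussian noise; production is
#' `Binomial(comprehension, gamma_child)` with a child-level jitter on
#' `gamma`, so `production <= comprehension <= 418` holds by construction
#' (the Oxford CDI scores as expressive only words the child both
#' understands and produces). The dataset is a deterministic function of the
#' RNG state.
#'
#' @param specs Group specifications, as from [default_group_specs()].
#' @return Data frame with `child_id`, `group`, `age_months`,
#'   `comprehension`, `production`.
#' @export
generate_cdi_dataset <- function(specs = default_group_specs()) {
  if (length(specs) == 0) stop("specs must be non-empty", call. = FALSE)
  blocks <- lapply(specs, function(s) {
    age <- stats::runif(s$n, s$age_range[1], s$age_range[2])
    mu <- s$asymptote / (1 + exp(-s$rate * (age - s$midpoint - s$delay)))
    comp <- round(mu + s$noise_sd * stats::rnorm(s$n))
    comp <- pmin(pmax(comp, 0), CDI_MAX_WORDS)
    g <- pmin(pmax(s$gamma + s$gamma_sd * stats::rnorm(s$n), 0), 1)
    prod <- stats::rbinom(s$n, comp, g)
    data.frame(group = s$group, age_months = age,
               comprehension = as.integer(comp),
               production = as.integer(prod))
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  cbind(child_id = sprintf("c%04d", seq_len(nrow(out))), out)
}

#' Run the empirical comprehension-production analysis on a CDI dataset
#'
#' Mirrors the analysis used for the observed cohorts: fits monotone
#' smoothers of comprehension and production on age for each group, fits
#' the reference (TD) monotone curve of production on comprehension, and
#' runs the residual sign test of each syndrome group against that TD line.
#' A significant result for a group means its production systematically
#' exceeds the TD expectation at matched comprehension, i.e. a reduced
#' comprehension-production gap.
#'
#' @param records CDI data frame (schema of [generate_cdi_dataset()]).
#' @param basis_dim I-spline basis dimension for all monotone fits.
#' @return List with `td_fit` (production ~ comprehension on TD),
#'   `age_fits` (per group, comprehension ~ age and production ~ age),
#'   and `sign_tests`: a data frame with one row per non-TD group
#'   (`group`, `n_above`, `n_total`, `proportion`, `ci_lower`, `p`).
#' @export
empirical_pipeline <- function(records, basis_dim = 3) {
  if (!"TD" %in% records$group)
    stop("records must include a TD group", call. = FALSE)
  td <- records[records$group == "TD", ]
  td_fit <- fit_monotone_smoother(td$comprehension, td$production, basis_dim)
  groups <- unique(records$group)
  age_fits <- lapply(stats::setNames(groups, groups), function(g) {
    sub <- records[records$group == g, ]
    list(comprehension = fit_monotone_smoother(sub$age_months,
                                               sub$comprehension, basis_dim),
         production = fit_monotone_smoother(sub$age_months,
                                            sub$production, basis_dim))
  })
  syn <- setdiff(groups, "TD")
  rows <- lapply(syn, function(g) {
    sub <- records[records$group == g, ]
    st <- residual_sign_analysis(
      data.frame(comprehension = sub$comprehension,
                 production = sub$production), td_fit)
    data.frame(group = g, n_above = st$n_above, n_total = st$n_total,
               proportion = st$proportion, ci_lower = st$ci_lower, p = st$p)
  })
  sign_tests <- if (length(rows)) do.call(rbind, rows)
                else data.frame(group = character(), n_above = integer(),
                                n_total = integer(), proportion = numeric(),
                                ci_lower = numeric(), p = numeric())
  rownames(sign_tests) <- NULL
  list(td_fit = td_fit, age_fits = age_fits, sign_tests = sign_tests)
}

#' Write CDI records to CSV
#'
#' @param records CDI data frame.
#' @param path Output path.
#' @export
write_cdi_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate a CDI CSV
#'
#' Expects the header `child_id, group, age_months, comprehension,
#' production`. Rows violating the CDI invariants (counts outside
#' \[0, 418\], production exceeding comprehension, non-integer counts) are
#' rejected with their row numbers.
#'
#' @param path CSV file path.
#' @return Validated CDI data frame.
#' @export
read_cdi_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("child_id", "group", "age_months", "comprehension", "production")
  if (!all(need %in% names(df)))
    stop(sprintf("CDI CSV must have columns: %s", paste(need, collapse = ", ")),
         call. = FALSE)
  if (nrow(df) == 0) return(df[, need])
  bad <- which(!is.finite(df$comprehension) | !is.finite(df$production) |
                 df$comprehension %% 1 != 0 | df$production %% 1 != 0 |
                 df$comprehension < 0 | df$comprehension > CDI_MAX_WORDS |
                 df$production < 0 | df$production > df$comprehension)
  if (length(bad))
    stop(sprintf("invalid CDI rows (production/comprehension out of range): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  df$comprehension <- as.integer(df$comprehension)
  df$production <- as.integer(df$production)
  df[, need]
}
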