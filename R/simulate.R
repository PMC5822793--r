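#' Simulation configuration for synthetic multi-cohort expression + survival data
#'
#' Defines a multi-cohort study with planted block-correlated gene modules and
#' planted module-level proportional-hazards effects. Module genes follow the
#' single-factor model \eqn{x = \lambda f + \epsilon}, \eqn{\epsilon \sim
#' N(0, \sigma^2)}, where \eqn{f} is a standard-normal latent module factor
#' shared by all genes of the module within a cohort. Background genes are pure
#' noise. Event times are exponential under proportional hazards with linear
#' predictor \eqn{\sum_k \beta_k f_k} (plus an optional product interaction of
#' the first two module factors); censoring is independent uniform, calibrated
#' numerically to the target censoring fraction.
#'
#' With the default `noise_sd = 0.6` a loading of 0.8 yields gene variance
#' \eqn{\lambda^2 + \sigma^2 = 1}, gene-factor correlation \eqn{\lambda} and
#' mean within-module pairwise correlation \eqn{\lambda^2}.
#'
#' @param n_genes total number of genes (module genes + background noise genes).
#' @param n_samples_per_cohort integer vector of cohort sizes; the first cohort
#'   is the training set, the rest are test sets.
#' @param n_modules number of planted modules.
#' @param module_sizes integer vector (length `n_modules`) of genes per module;
#'   must sum to at most `n_genes`.
#' @param module_loading per-module gene-factor loading in (0, 1].
#' @param survival_effect per-module log-hazard coefficient on the latent
#'   factor; 0 marks a null module.
#' @param baseline_hazard constant baseline hazard of the exponential event-time
#'   model (per month).
#' @param censoring_rate_target target fraction of censored records in [0, 1).
#' @param noise_sd standard deviation of the residual expression noise.
#' @param interaction_effect log-hazard coefficient on the product of the first
#'   two module factors (0 = purely linear hazard).
#' @param seed integer seed; together with the cohort index it fully determines
#'   every generated number.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 300L,
                              n_samples_per_cohort = c(300L, 200L),
                              n_modules = 6L,
                              module_sizes = rep(30L, 6L),
                              module_loading = rep(0.8, 6L),
                              survival_effect = c(1, 1, 0, 0, 0, 0),
                              baseline_hazard = 0.01,
                              censoring_rate_target = 0.6,
                              noise_sd = 0.6,
                              interaction_effect = 0,
                              seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_samples_per_cohort <- as.integer(n_samples_per_cohort)
  n_modules <- as.integer(n_modules)
  module_sizes <- as.integer(module_sizes)
  stopifnot(n_genes >= 1L, all(n_samples_per_cohort >= 2L), n_modules >= 0L)
  if (length(module_sizes) != n_modules)
    stop("module_sizes must have length n_modules")
  if (length(module_loading) != n_modules)
    stop("module_loading must have length n_modules")
  if (length(survival_effect) != n_modules)
    stop("survival_effect must have length n_modules")
  if (sum(module_sizes) > n_genes)
    stop("sum(module_sizes) exceeds n_genes")
  if (any(module_loading <= 0 | module_loading > 1))
    stop("module_loading must lie in (0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (censoring_rate_target < 0 || censoring_rate_target >= 1)
    stop("censoring_rate_target must lie in [0, 1)")
  structure(
    list(n_genes = n_genes,
         n_samples_per_cohort = n_samples_per_cohort,
         n_modules = n_modules,
         module_sizes = module_sizes,
         module_loading = as.numeric(module_loading),
         survival_effect = as.numeric(survival_effect),
         baseline_hazard = as.numeric(baseline_hazard),
         censoring_rate_target = as.numeric(censoring_rate_target),
         noise_sd = as.numeric(noise_sd),
         interaction_effect = as.numeric(interaction_effect),
         seed = as.integer(seed)),
    class = "simulation_config")
}

# Gene ids and planted gene -> module map (0 = background), shared by all cohorts.
planted_gene_map <- function(config) {
  ids <- sprintf("g%04d", seq_len(config$n_genes))
  module <- integer(config$n_genes)
  at <- 0L
  for (m in seq_len(config$n_modules)) {
    module[at + seq_len(config$module_sizes[m])] <- m
    at <- at + config$module_sizes[m]
  }
  names(module) <- ids
  module
}

#' Generate one synthetic cohort with planted truth
#'
#' All randomness is drawn from a single generator seeded by
#' `seed + 7919 * cohort_index`, so each cohort has an independent but fully
#' reproducible stream. Expression is standardized per gene (mean 0, sd 1)
#' after adding a cohort-specific per-gene mean shift, which the
#' standardization removes again (a stand-in for cross-cohort preprocessing).
#' Independent null clinical covariates (age, sex, stage) are attached for
#' multivariate and subgroup analyses.
#'
#' @param config a [simulation_config()].
#' @param cohort_index 1-based cohort index (1 = training cohort).
#' @return a list with elements `cohort` (class `cohort`: `expression`
#'   genes-by-samples matrix, `survival` data.frame with columns
#'   sample/time/event/age/sex/stage, `name`) and `truth` (class
#'   `planted_truth`: `gene_to_module`, `module_effects`, `latent_factors`,
#'   `interaction_effect`).
#' @export
generate_cohort <- function(config, cohort_index = 1L) {
  stopifnot(inherits(config, "simulation_config"), cohort_index >= 1L)
  n <- config$n_samples_per_cohort[cohort_index]
  if (is.na(n)) stop("cohort_index exceeds length(n_samples_per_cohort)")
  set.seed(config$seed + 7919L * as.integer(cohort_index))

  gene_map <- planted_gene_map(config)
  ids <- names(gene_map)
  K <- config$n_modules

  f <- matrix(stats::rnorm(n * max(K, 1L)), nrow = n, ncol = max(K, 1L))
  if (K == 0L) f <- f[, 0, drop = FALSE]
  colnames(f) <- if (K > 0L) paste0("module", seq_len(K)) else character(0)

  expr <- matrix(stats::rnorm(config$n_genes * n, sd = config$noise_sd),
                 nrow = config$n_genes, ncol = n,
                 dimnames = list(ids, sprintf("s%04d", seq_len(n))))
  for (m in seq_len(K)) {
    g <- which(gene_map == m)
    if (length(g))
      expr[g, ] <- expr[g, ] + config$module_loading[m] * matrix(f[, m],
        nrow = length(g), ncol = n, byrow = TRUE)
  }
  # cohort-specific per-gene offsets, removed by per-gene standardization
  expr <- expr + stats::rnorm(config$n_genes, sd = 0.5)
  expr <- standardize_rows(expr)

  eta <- if (K > 0L) drop(f %*% config$survival_effect) else rep(0, n)
  if (config$interaction_effect != 0 && K >= 2L)
    eta <- eta + config$interaction_effect * f[, 1L] * f[, 2L]

  event_time <- -log(stats::runif(n)) / (config$baseline_hazard * exp(eta))
  if (config$censoring_rate_target > 0) {
    target <- config$censoring_rate_target
    # expected censored fraction when C ~ U(0, cmax): mean(min(T/cmax, 1))
    cens_frac <- function(cmax) mean(pmin(event_time / cmax, 1)) - target
    cmax <- stats::uniroot(cens_frac,
                           lower = min(event_time) * 1e-6,
                           upper = max(event_time) * 1e6,
                           tol = 1e-10)$root
    cens_time <- stats::runif(n, 0, cmax)
    time <- pmin(event_time, cens_time)
    event <- as.integer(event_time <= cens_time)
  } else {
    time <- event_time
    event <- rep(1L, n)
  }

  survival <- data.frame(
    sample = colnames(expr),
    time = time,
    event = event,
    age = round(stats::rnorm(n, 65, 9), 1),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stage = sample(c("I", "II", "III"), n, replace = TRUE,
                   prob = c(0.55, 0.3, 0.15)),
    stringsAsFactors = FALSE)

  cohort <- structure(
    list(expression = expr, survival = survival,
         name = if (cohort_index == 1L) "training"
                else paste0("test", cohort_index - 1L)),
    class = "cohort")
  truth <- structure(
    list(gene_to_module = gene_map,
         module_effects = config$survival_effect,
         latent_factors = f,
         interaction_effect = config$interaction_effect),
    class = "planted_truth")
  list(cohort = cohort, truth = truth)
}

#' Generate a multi-cohort study (training + test sets)
#'
#' Cohorts share gene ids, module memberships and hazard coefficients but have
#' independent latent factors and noise, mirroring a merged training set
#' validated in independent test cohorts.
#'
#' @param config a [simulation_config()] whose `n_samples_per_cohort` has
#'   length at least 2.
#' @return a list with `cohorts` (list of `cohort`, first = training) and
#'   `truth` (shared gene map and effects; `latent_factors` is a per-cohort
#'   list).
#' @export
generate_multi_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_cohorts <- length(config$n_samples_per_cohort)
  if (n_cohorts < 2L) stop("at least 2 cohorts are required (training + test)")
  gen <- lapply(seq_len(n_cohorts), function(i) generate_cohort(config, i))
  cohorts <- lapply(gen, `[[`, "cohort")
  names(cohorts) <- vapply(cohorts, `[[`, "", "name")
  truth <- gen[[1L]]$truth
  truth$latent_factors <- lapply(gen, function(g) g$truth$latent_factors)
  names(truth$latent_factors) <- names(cohorts)
  list(cohorts = cohorts, truth = truth)
}

# Standardize matrix rows to mean 0, sd 1; errors on zero-variance rows.
standardize_rows <- function(x) {
  s <- apply(x, 1L, stats::sd)
  if (any(s == 0))
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(x)[s == 0], 5L), collapse = ", "))
  t(scale(t(x)))[, , drop = FALSE]
}
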