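#' Cox proportional-hazards fit (Breslow ties)
#'
#' Fits a Cox model by maximum partial likelihood with Breslow tie handling
#' (via \pkg{survival}'s Newton-Raphson engine, convergence tolerance 1e-9,
#' up to 50 iterations). Categorical covariates are expanded to
#' reference-coded indicators with the most frequent level as reference.
#' Wald confidence intervals are \eqn{\exp(\beta \pm 1.96\, se)}.
#'
#' @param design samples-by-covariates data.frame or numeric matrix, rows
#'   aligned with `survival` rows.
#' @param survival data.frame with `time` and `event` columns.
#' @return object of class `cox_result`: `coefficients` (data.frame with term,
#'   beta, hr, ci_lo, ci_hi, z, p), `loglik` (c(null, fitted) log partial
#'   likelihood), `iter`, `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(design, survival) {
  if (is.matrix(design)) design <- as.data.frame(design)
  if (!is.data.frame(design)) design <- as.data.frame(design)
  stopifnot(nrow(design) == nrow(survival))
  if (sum(survival$event) < 1L) stop("at least one event is required")
  if (anyNA(design)) stop("missing covariate values")
  for (j in names(design)) {
    v <- design[[j]]
    if (is.character(v) || is.factor(v)) {
      v <- as.factor(v)
      ref <- names(sort(table(v), decreasing = TRUE))[1L]
      design[[j]] <- stats::relevel(v, ref = ref)
      if (nlevels(design[[j]]) < 2L)
        stop("constant covariate: ", j)
    } else if (stats::sd(v) == 0) stop("constant covariate: ", j)
  }
  x <- stats::model.matrix(~ ., data = design)[, -1L, drop = FALSE]
  if (qr(x)$rank < ncol(x)) stop("design matrix is rank-deficient")
  dat <- data.frame(.time = survival$time, .event = survival$event, x,
                    check.names = FALSE)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", colnames(x)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)),
    warning = function(w) {
      # divergence is re-detected below and raised as an error
      if (grepl("infinite|converge|NaNs produced", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  # a diverging fit can produce a negative-diagonal vcov; the resulting NaN
  # se is caught by the finiteness check below
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  if (any(!is.finite(beta)) || any(!is.finite(se)) ||
      any(abs(beta) > 15 & se > 10))
    stop("monotone partial likelihood (possible perfect separation); ",
         "coefficient estimates diverge")
  z <- beta / se
  coefs <- data.frame(
    term = names(beta),
    beta = unname(beta),
    se = unname(se),
    hr = unname(exp(beta)),
    ci_lo = unname(exp(beta - 1.96 * se)),
    ci_hi = unname(exp(beta + 1.96 * se)),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    stringsAsFactors = FALSE)
  structure(list(coefficients = coefs,
                 loglik = fit$loglik,
                 iter = fit$iter,
                 converged = fit$iter < 50,
                 n = nrow(design),
                 n_events = sum(survival$event)),
            class = "cox_result")
}

#' Kaplan-Meier product-limit estimator
#'
#' @param survival data.frame with `time` and `event`.
#' @return object of class `km_curve`: data.frame `curve` with time, n_risk,
#'   n_event, n_censor, surv (the estimate starts at S(0) = 1).
#' @export
kaplan_meier <- function(survival) {
  stopifnot(nrow(survival) >= 1L)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = survival)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      n_event = fit$n.event, n_censor = fit$n.censor,
                      surv = fit$surv)
  structure(list(curve = curve, n = nrow(survival)), class = "km_curve")
}

#' Log-rank test for survival differences between groups
#'
#' @param groups group labels aligned to `survival` rows (at least two
#'   non-empty groups).
#' @param survival data.frame with `time` and `event`.
#' @return list with `chisq`, `df` (groups - 1) and `p`.
#' @export
logrank_test <- function(groups, survival) {
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("at least two non-empty groups are required")
  if (any(table(groups) == 0L)) stop("a group has zero members")
  dat <- data.frame(time = survival$time, event = survival$event, g = groups)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g, data = dat)
  df <- nlevels(groups) - 1L
  list(chisq = unname(sd_$chisq), df = df,
       p = stats::pchisq(sd_$chisq, df, lower.tail = FALSE))
}

# Concordant / comparable pair counts for Harrell's C. A pair (i, j) is
# comparable when one time is strictly smaller and that subject had an event;
# tied event times are not comparable. Higher score with shorter time is
# concordant; tied scores count 1/2.
harrell_counts <- function(score, time, event) {
  n <- length(time)
  ti <- matrix(time, n, n)
  si <- matrix(score, n, n)
  ei <- matrix(as.logical(event), n, n)
  comp <- (ti < t(ti)) & ei          # i fails first, observed
  conc <- sum(comp & (si > t(si))) + 0.5 * sum(comp & (si == t(si)))
  c(concordant = conc, comparable = sum(comp))
}

#' Harrell's concordance index with bootstrap standard error
#'
#' @param score numeric risk score per sample (higher = higher risk).
#' @param survival data.frame with `time` and `event`, aligned to `score`.
#' @param n_boot bootstrap resamples for the standard error (0 = skip).
#' @param seed seed for the bootstrap.
#' @return object of class `concordance_result`: `c_index`, `se`,
#'   `comparable_pairs`.
#' @export
concordance_index <- function(score, survival, n_boot = 200L, seed = 1L) {
  stopifnot(length(score) == nrow(survival))
  cnt <- harrell_counts(score, survival$time, survival$event)
  if (cnt[["comparable"]] == 0L) stop("no comparable pairs")
  ci <- cnt[["concordant"]] / cnt[["comparable"]]
  se <- NA_real_
  if (n_boot > 0L) {
    set.seed(seed)
    n <- length(score)
    boots <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      ct <- harrell_counts(score[idx], survival$time[idx], survival$event[idx])
      if (ct[["comparable"]] == 0L) NA_real_
      else ct[["concordant"]] / ct[["comparable"]]
    }, 0)
    se <- stats::sd(boots, na.rm = TRUE)
  }
  structure(list(c_index = ci, se = se,
                 comparable_pairs = unname(cnt[["comparable"]])),
            class = "concordance_result")
}

#' Dichotomize a score at its within-cohort median
#'
#' Scores strictly above the median are labeled `"high"`, scores at or below
#' the median `"low"`. The median is always computed within the cohort being
#' labeled.
#'
#' @param score numeric vector (length >= 2, not all identical).
#' @return factor with levels `low`, `high`.
#' @export
dichotomize_by_median <- function(score) {
  if (length(score) < 2L) stop("at least 2 samples are required")
  if (length(unique(score)) == 1L)
    stop("degenerate split: all scores identical")
  med <- stats::median(score)
  factor(ifelse(score > med, "high", "low"), levels = c("low", "high"))
}
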