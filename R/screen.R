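#' Screen module eigengenes for association with overall survival
#'
#' One univariate Cox fit per module eigengene in the training cohort.
#' A module is flagged significant when its uncorrected Wald p-value is below
#' `alpha` (default 0.05). Non-converging fits are reported with missing
#' statistics and never flagged significant.
#'
#' @param mes a `module_eigengenes` object.
#' @param survival data.frame with `time` and `event`, aligned to
#'   `mes$sample_ids`.
#' @param alpha significance threshold on the uncorrected p (default 0.05).
#' @return data.frame with one row per module: module, n_genes (NA here),
#'   beta, hr, ci_lo, ci_hi, p, significant, converged.
#' @export
screen_modules <- function(mes, survival, alpha = 0.05) {
  stopifnot(inherits(mes, "module_eigengenes"))
  if (sum(survival$event) < 10L)
    stop("at least 10 events are required for module screening")
  mods <- colnames(mes$eigengenes)
  rows <- lapply(mods, function(m) {
    fit <- tryCatch(
      cox_fit(data.frame(ME = mes$eigengenes[, m]), survival),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      if (is.null(fit)) warning("Cox fit failed for module ", m)
      data.frame(module = m, beta = NA_real_, hr = NA_real_,
                 ci_lo = NA_real_, ci_hi = NA_real_, p = NA_real_,
                 significant = FALSE, converged = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      co <- fit$coefficients
      data.frame(module = m, beta = co$beta, hr = co$hr, ci_lo = co$ci_lo,
                 ci_hi = co$ci_hi, p = co$p,
                 significant = co$p < alpha, converged = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Validate survival-related modules in an independent test cohort
#'
#' Module eigengenes are recomputed from the test cohort's own expression
#' (not projected from training loadings) using the training module
#' memberships, then screened against the test cohort's survival. Genes
#' missing from the test cohort are dropped with a warning; a module with
#' fewer than `min_frac` of its genes present is skipped.
#'
#' @param assignment a `module_assignment` from the training network.
#' @param cohort a test `cohort` (expression + survival).
#' @param alpha significance threshold (default 0.05).
#' @param min_frac minimum fraction of module genes that must be present
#'   (default 0.5).
#' @return data.frame as [screen_modules()] plus columns n_genes_used and
#'   skipped.
#' @export
validate_modules <- function(assignment, cohort, alpha = 0.05,
                             min_frac = 0.5) {
  stopifnot(inherits(assignment, "module_assignment"),
            inherits(cohort, "cohort"))
  labels <- assignment$labels
  mods <- module_labels(assignment)
  present <- lapply(mods, function(m) {
    genes <- names(labels)[labels == m]
    intersect(genes, rownames(cohort$expression))
  })
  names(present) <- mods
  frac <- vapply(mods, function(m)
    length(present[[m]]) / sum(labels == m), 0)
  missing_any <- vapply(mods, function(m)
    length(present[[m]]) < sum(labels == m), NA)
  if (any(missing_any))
    warning("dropped genes missing from test cohort in module(s): ",
            paste(mods[missing_any], collapse = ", "))
  keep <- mods[frac >= min_frac & vapply(present, length, 0L) >= 2L]
  skip <- setdiff(mods, keep)
  if (length(skip))
    warning("skipped module(s) with <", round(100 * min_frac),
            "% of genes present: ", paste(skip, collapse = ", "))
  out <- NULL
  if (length(keep)) {
    sub_labels <- labels[labels %in% keep & names(labels) %in%
                           rownames(cohort$expression)]
    sub_assign <- structure(
      list(labels = sub_labels,
           sizes = stats::setNames(
             vapply(keep, function(m) sum(sub_labels == m), 0L), keep),
           params = assignment$params),
      class = "module_assignment")
    mes <- module_eigengenes(cohort$expression, sub_assign)
    out <- screen_modules(mes, cohort$survival, alpha = alpha)
    out$n_genes_used <- vapply(out$module, function(m)
      length(present[[m]]), 0L)
    out$skipped <- FALSE
  }
  if (length(skip)) {
    skipped_rows <- data.frame(
      module = skip, beta = NA_real_, hr = NA_real_, ci_lo = NA_real_,
      ci_hi = NA_real_, p = NA_real_, significant = FALSE, converged = FALSE,
      n_genes_used = vapply(skip, function(m) length(present[[m]]), 0L),
      skipped = TRUE, stringsAsFactors = FALSE)
    out <- rbind(out, skipped_rows)
  }
  rownames(out) <- NULL
  out[match(mods, out$module), , drop = FALSE]
}

#' Per-gene univariate Cox significance
#'
#' Fits a univariate Cox model per gene on its (standardized) expression and
#' reports the Wald p-value and the score \eqn{s_g = -\log_{10}(p)}.
#' Non-converging genes get score 0 with a warning.
#'
#' @param expr genes-by-samples matrix.
#' @param survival data.frame with `time` and `event`, aligned to columns of
#'   `expr`.
#' @return data.frame with gene, p, score.
#' @export
gene_significance <- function(expr, survival) {
  stopifnot(ncol(expr) == nrow(survival))
  failed <- character(0)
  rows <- lapply(rownames(expr), function(g) {
    fit <- tryCatch(cox_fit(data.frame(x = expr[g, ]), survival),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) {
      failed <<- c(failed, g)
      data.frame(gene = g, p = NA_real_, score = 0, stringsAsFactors = FALSE)
    } else {
      p <- fit$coefficients$p
      data.frame(gene = g, p = p, score = -log10(max(p, .Machine$double.xmin)),
                 stringsAsFactors = FALSE)
    }
  })
  if (length(failed))
    warning("Cox fit failed for ", length(failed), " gene(s); score set to 0")
  do.call(rbind, rows)
}

#' Correlation between gene module membership and gene survival significance
#'
#' Pearson correlation, within one module, between the member genes'
#' \eqn{|kME|} and their significance score \eqn{-\log_{10}(p)}.
#'
#' @param gmm genes-by-modules kME matrix.
#' @param sig data.frame from [gene_significance()].
#' @param module module label (column of `gmm`).
#' @param assignment a `module_assignment` giving module memberships.
#' @return list with `r`, `p`, `n`.
#' @export
gmm_significance_correlation <- function(gmm, sig, module, assignment) {
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels
            else assignment
  members <- intersect(names(labels)[labels == module], rownames(gmm))
  members <- intersect(members, sig$gene)
  if (length(members) < 10L)
    stop("module ", module, " has fewer than 10 genes with both kME and ",
         "significance scores")
  x <- abs(gmm[members, module])
  y <- sig$score[match(members, sig$gene)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(members))
}

#' Select the top-k representative (hub) genes of a module by |kME|
#'
#' Member genes are ranked by decreasing absolute module membership (ties
#' broken by gene id); the top `k` are returned. Set `signed = TRUE` to rank
#' by signed kME instead.
#'
#' @param gmm genes-by-modules kME matrix.
#' @param module module label.
#' @param assignment module memberships.
#' @param k number of genes (default 10); if the module is smaller than `k`
#'   the whole module is returned with a warning.
#' @param signed rank by signed kME rather than |kME| (default FALSE).
#' @return character vector of gene ids, in rank order.
#' @export
select_representative_genes <- function(gmm, module, assignment, k = 10L,
                                        signed = FALSE) {
  if (k < 1L) stop("k must be at least 1")
  labels <- if (inherits(assignment, "module_assignment")) assignment$labels
            else assignment
  members <- intersect(names(labels)[labels == module], rownames(gmm))
  if (!length(members)) stop("module ", module, " has no genes in gmm")
  key <- if (signed) gmm[members, module] else abs(gmm[members, module])
  ord <- order(-key, members)
  ranked <- members[ord]
  if (length(ranked) < k) {
    warning("module ", module, " has only ", length(ranked),
            " genes (< k = ", k, "); returning all of them")
    return(ranked)
  }
  ranked[seq_len(k)]
}

#' Hypergeometric gene-set enrichment of a module
#'
#' Upper-tail hypergeometric test \eqn{P(X \ge \mathrm{overlap})} of each
#' gene set against the module, within a gene universe. Gene sets are
#' intersected with the universe first. An optional Benjamini-Hochberg
#' q-value column is provided as an extension beyond the uncorrected test.
#'
#' @param module_genes character vector (must be a subset of `universe`).
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector of all genes considered.
#' @param adjust add a BH q-value column (default FALSE).
#' @return data.frame sorted by p: set, overlap, set_size, module_size,
#'   universe_size, p (and q if requested).
#' @export
hypergeometric_enrichment <- function(module_genes, gene_sets, universe,
                                      adjust = FALSE) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  if (!all(module_genes %in% universe))
    stop("module_genes must be a subset of the universe")
  module_genes <- unique(module_genes)
  m <- length(module_genes)
  N <- length(universe)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    ov <- length(intersect(set, module_genes))
    p <- stats::phyper(ov - 1L, length(set), N - length(set), m,
                       lower.tail = FALSE)
    data.frame(set = nm, overlap = ov, set_size = length(set),
               module_size = m, universe_size = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$set), , drop = FALSE]
  if (adjust) out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}
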