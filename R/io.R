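#' Read a gene expression TSV (first column gene id, header row sample ids)
#' @param path file path.
#' @return numeric matrix, genes in rows, samples in columns.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}

#' Write a gene expression matrix as TSV
#' @param expr genes-by-samples matrix with dimnames.
#' @param path output path.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a survival TSV (sample, time, event, optional covariate columns)
#' @param path file path.
#' @return data.frame with at least sample/time/event columns.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "time", "event")
  if (!all(need %in% names(df)))
    stop("survival table must contain columns: ", paste(need, collapse = ", "))
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (!all(df$event %in% c(0L, 1L))) stop("event must be 0 or 1")
  df
}

#' Write a survival table as TSV
#' @param survival data.frame with sample/time/event (+ covariates).
#' @param path output path.
#' @export
write_survival_tsv <- function(survival, path) {
  utils::write.table(survival, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a cohort (expression + survival) to a directory
#' @param cohort a `cohort` object.
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ep <- file.path(dir, paste0(cohort$name, "_expression.tsv"))
  sp <- file.path(dir, paste0(cohort$name, "_survival.tsv"))
  write_expression_tsv(cohort$expression, ep)
  write_survival_tsv(cohort$survival, sp)
  invisible(c(expression = ep, survival = sp))
}

#' Read a cohort from expression + survival TSVs
#' @param expression_path,survival_path file paths.
#' @param name cohort name.
#' @return a `cohort` object (samples aligned; errors if sample sets differ).
#' @export
read_cohort <- function(expression_path, survival_path, name = "cohort") {
  expr <- read_expression_tsv(expression_path)
  surv <- read_survival_tsv(survival_path)
  if (!setequal(colnames(expr), surv$sample))
    stop("expression samples and survival samples differ")
  surv <- surv[match(colnames(expr), surv$sample), , drop = FALSE]
  rownames(surv) <- NULL
  structure(list(expression = expr, survival = surv, name = name),
            class = "cohort")
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @param path file path.
#' @return named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(l, 1, 40))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], "")
  sets
}

# Deterministic TSV writer for pipeline outputs: fixed significant digits so
# reruns with identical seeds produce byte-identical files.
write_tsv_repro <- function(df, path) {
  df2 <- df
  for (j in seq_along(df2))
    if (is.numeric(df2[[j]]) && !is.integer(df2[[j]]))
      df2[[j]] <- sprintf("%.10g", df2[[j]])
  utils::write.table(df2, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
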