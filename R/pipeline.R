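#' Pipeline configuration
#'
#' Exactly one of `cohorts` (list of `cohort` objects or named lists with
#' `expression`/`survival` TSV paths) or `simulation` (a
#' [simulation_config()]) must be supplied.
#'
#' @param cohorts list of cohorts (first = training) or NULL.
#' @param simulation a [simulation_config()] or NULL.
#' @param power soft-threshold power (integer) or `"auto"` to select by
#'   scale-free fit; default 6.
#' @param top_n_genes keep the N most variable genes before networking
#'   (NULL = all).
#' @param height_cutoff,deep_split,min_size dynamic tree cut parameters
#'   (defaults 0.99, 2, 30).
#' @param alpha screening significance threshold (default 0.05).
#' @param genes_per_module representative genes per surviving module
#'   (default 10).
#' @param cv_grid list of CV configurations (see
#'   [cross_validate_netscore()]); NULL = a small default grid.
#' @param cv_folds number of CV folds (default 5).
#' @param covariates character vector of clinical covariate columns for the
#'   multivariate model (default none).
#' @param subgroups list of subgroup specifications, each
#'   `list(covariate=, value=)` or `list(covariate=, cut=)` (default none).
#' @param seed master seed (default 1).
#' @param make_plots write Kaplan-Meier PDF figures (default FALSE).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohorts = NULL, simulation = NULL, power = 6L,
                            top_n_genes = NULL, height_cutoff = 0.99,
                            deep_split = 2L, min_size = 30L, alpha = 0.05,
                            genes_per_module = 10L, cv_grid = NULL,
                            cv_folds = 5L, covariates = character(0),
                            subgroups = list(), seed = 1L,
                            make_plots = FALSE) {
  if (is.null(cohorts) == is.null(simulation))
    stop("exactly one of cohorts or simulation must be supplied")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  structure(list(cohorts = cohorts, simulation = simulation, power = power,
                 top_n_genes = top_n_genes, height_cutoff = height_cutoff,
                 deep_split = deep_split, min_size = min_size, alpha = alpha,
                 genes_per_module = as.integer(genes_per_module),
                 cv_grid = cv_grid, cv_folds = as.integer(cv_folds),
                 covariates = covariates, subgroups = subgroups,
                 seed = as.integer(seed), make_plots = make_plots),
            class = "pipeline_config")
}

default_cv_grid <- function() {
  list(list(filters_per_module = 4L, fc_sizes = c(16L, 8L, 4L),
            lr = 1e-2, epochs = 200L),
       list(filters_per_module = 8L, fc_sizes = c(32L, 16L, 8L),
            lr = 1e-2, epochs = 200L))
}

pipeline_log <- function(con, ...) {
  msg <- paste0(...)
  if (!is.null(con)) writeLines(msg, con)
  message(msg)
}

resolve_cohorts <- function(config) {
  if (!is.null(config$simulation))
    return(generate_multi_cohort(config$simulation)$cohorts)
  lapply(seq_along(config$cohorts), function(i) {
    co <- config$cohorts[[i]]
    if (inherits(co, "cohort")) co
    else read_cohort(co$expression, co$survival,
                     name = co$name %||%
                       if (i == 1L) "training" else paste0("test", i - 1L))
  })
}

#' Run the full network-to-risk-score pipeline
#'
#' Stages: (1) coexpression network construction on the training cohort;
#' (2) module eigengene screening against overall survival; (3) validation of
#' every module in each test cohort; (4) modules significant in training and
#' in every test cohort advance; (5) top-k representative genes per advanced
#' module; (6) cross-validated architecture selection and final training of
#' the survival network; (7) scoring of all cohorts; (8) per-cohort survival
#' analytics (continuous-score Cox, median dichotomization, Kaplan-Meier +
#' log-rank, multivariate Cox with the supplied covariates, subgroup table);
#' (9) a manifest recording every seed, parameter and output checksum.
#'
#' If no module survives validation the pipeline stops after stage 4 with a
#' structured report (`status = "stopped_no_modules"`), not an error.
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory (created; stage outputs are TSV files).
#' @return invisible list: `outdir`, `status` (`"ok"` or
#'   `"stopped_no_modules"`), `assignment`, `screen`, `validation`,
#'   `selected_modules`, `genes`, `cv`, `model`, `scores`, `analysis`,
#'   `manifest`.
#' @export
run_full_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logf <- file(file.path(outdir, "pipeline.log"), open = "wt")
  on.exit(close(logf), add = TRUE)

  cohorts <- resolve_cohorts(config)
  training <- cohorts[[1L]]
  tests <- cohorts[-1L]
  pipeline_log(logf, "cohorts: ",
               paste(vapply(cohorts, function(c) sprintf("%s(n=%d)", c$name,
                 ncol(c$expression)), ""), collapse = ", "))

  # stage 1: network construction
  expr <- training$expression
  if (!is.null(config$top_n_genes) && config$top_n_genes < nrow(expr)) {
    v <- apply(expr, 1L, stats::var)
    keep <- rownames(expr)[order(-v)][seq_len(config$top_n_genes)]
    expr <- expr[sort(keep), , drop = FALSE]
    pipeline_log(logf, "gene filter: kept top ", config$top_n_genes,
                 " variable genes")
  }
  corr <- correlation_matrix(expr)
  if (identical(config$power, "auto")) {
    ps <- pick_soft_threshold(corr)
    power <- ps$power
    write_tsv_repro(ps$table, file.path(outdir, "01_power_selection.tsv"))
    pipeline_log(logf, "auto-selected soft-threshold power ", power)
  } else power <- as.integer(config$power)
  adj <- adjacency_matrix(corr, power)
  tom <- topological_overlap(adj)
  dend <- hierarchical_cluster(1 - tom)
  assignment <- dynamic_tree_cut(dend, 1 - tom,
                                 height_cutoff = config$height_cutoff,
                                 deep_split = config$deep_split,
                                 min_size = config$min_size)
  write_tsv_repro(data.frame(gene = names(assignment$labels),
                             module = unname(assignment$labels)),
                  file.path(outdir, "01_modules.tsv"))
  pipeline_log(logf, "modules: ",
               paste(sprintf("%s=%d", names(assignment$sizes),
                             assignment$sizes), collapse = ", "),
               "; gray=", sum(assignment$labels == "gray"))

  manifest_path <- file.path(outdir, "manifest.json")
  if (!length(assignment$sizes)) {
    report <- c("# Pipeline report", "",
                "No modules were detected (all genes unassigned);",
                "the pipeline stopped before screening.")
    writeLines(report, file.path(outdir, "report.md"))
    manifest <- write_manifest(manifest_path, config, outdir,
                               status = "stopped_no_modules")
    return(invisible(list(outdir = outdir, status = "stopped_no_modules",
                          assignment = assignment, screen = NULL,
                          validation = NULL,
                          selected_modules = character(0),
                          genes = character(0), manifest = manifest)))
  }

  # stage 2: screening in training cohort
  mes <- module_eigengenes(expr, assignment)
  screen <- screen_modules(mes, training$survival, alpha = config$alpha)
  write_tsv_repro(screen, file.path(outdir, "02_screen_training.tsv"))

  # stage 3: validation in each test cohort
  validation <- lapply(tests, function(co) {
    v <- validate_modules(assignment, co, alpha = config$alpha)
    write_tsv_repro(v, file.path(outdir,
                                 sprintf("03_validate_%s.tsv", co$name)))
    v
  })
  names(validation) <- vapply(tests, `[[`, "", "name")

  # stage 4: modules significant everywhere advance
  sig_train <- screen$module[screen$significant]
  selected <- as.character(sig_train)
  for (v in validation)
    selected <- intersect(selected, v$module[v$significant & !v$skipped])
  writeLines(selected, file.path(outdir, "04_selected_modules.txt"))
  pipeline_log(logf, "significant in training: ",
               paste(sig_train, collapse = ", "), "; advanced: ",
               if (length(selected)) paste(selected, collapse = ", ")
               else "(none)")

  if (!length(selected)) {
    report <- c("# Pipeline report", "",
                "No survival-related modules validated in all cohorts;",
                "the pipeline stopped before model building.")
    writeLines(report, file.path(outdir, "report.md"))
    manifest <- write_manifest(manifest_path, config, outdir,
                               status = "stopped_no_modules")
    return(invisible(list(outdir = outdir, status = "stopped_no_modules",
                          assignment = assignment, screen = screen,
                          validation = validation,
                          selected_modules = character(0),
                          genes = character(0), manifest = manifest)))
  }

  # stage 5: representative gene selection (by |kME| in the training cohort)
  gmm <- gene_module_membership(expr, mes)
  modules_genes <- lapply(selected, function(m)
    select_representative_genes(gmm, m, assignment,
                                k = config$genes_per_module))
  names(modules_genes) <- selected
  gene_tab <- do.call(rbind, lapply(selected, function(m)
    data.frame(module = m, rank = seq_along(modules_genes[[m]]),
               gene = modules_genes[[m]],
               kme = gmm[modules_genes[[m]], m],
               stringsAsFactors = FALSE)))
  write_tsv_repro(gene_tab, file.path(outdir, "05_selected_genes.tsv"))

  # stage 6: cross-validated architecture selection + final training
  grid <- config$cv_grid %||% default_cv_grid()
  cv <- cross_validate_netscore(training, modules_genes, grid,
                                k = config$cv_folds, seed = config$seed)
  write_tsv_repro(cv$table, file.path(outdir, "06_cv.tsv"))
  best <- cv$chosen_config
  spec <- architecture_spec(modules_genes,
                            filters_per_module = best$filters_per_module %||% 8L,
                            fc_sizes = best$fc_sizes %||% c(16L, 8L, 4L))
  model <- train_netscore(build_netscore_model(spec, seed = config$seed),
                          training,
                          training_config(lr = best$lr %||% 1e-2,
                                          epochs = best$epochs %||% 300L,
                                          seed = config$seed))
  pipeline_log(logf, "chosen CV config ", cv$chosen, " (mean C = ",
               sprintf("%.3f", cv$table$mean_c[cv$chosen]), ")")

  # stage 7: scoring all cohorts
  scores <- lapply(cohorts, function(co) {
    s <- predict_netscore(model, co)
    write_tsv_repro(data.frame(sample = names(s), netscore = unname(s)),
                    file.path(outdir, sprintf("07_scores_%s.tsv", co$name)))
    s
  })
  names(scores) <- vapply(cohorts, `[[`, "", "name")

  # stage 8: survival analytics per cohort
  analysis <- lapply(cohorts, function(co) {
    analyze_cohort(co, scores[[co$name]], config, outdir)
  })
  names(analysis) <- names(scores)

  # stage 9: manifest + report
  manifest <- write_manifest(manifest_path, config, outdir, status = "ok",
                             extra = list(power = power,
                                          selected_modules = selected,
                                          n_input_genes = length(unlist(modules_genes)),
                                          cv_chosen = cv$chosen))
  write_report(outdir)
  invisible(list(outdir = outdir, status = "ok", assignment = assignment,
                 screen = screen, validation = validation,
                 selected_modules = selected, genes = unlist(modules_genes),
                 cv = cv, model = model, scores = scores,
                 analysis = analysis, manifest = manifest))
}

# Stage-8 analytics for one cohort: continuous Cox, dichotomized KM +
# log-rank, C-index, multivariate Cox, subgroups.
analyze_cohort <- function(cohort, score, config, outdir) {
  surv <- cohort$survival
  nm <- cohort$name
  cont <- tryCatch(cox_fit(data.frame(netscore = score), surv),
                   error = function(e) NULL)
  risk <- dichotomize_by_median(score)
  group_fit <- tryCatch(cox_fit(data.frame(risk_group = risk), surv),
                        error = function(e) NULL)
  lr <- logrank_test(risk, surv)
  ci <- concordance_index(score, surv, n_boot = 200L, seed = config$seed)
  km_rows <- do.call(rbind, lapply(levels(risk), function(g) {
    km <- kaplan_meier(surv[risk == g, , drop = FALSE])
    cbind(group = g, km$curve)
  }))
  write_tsv_repro(km_rows, file.path(outdir, sprintf("08_km_%s.tsv", nm)))
  if (isTRUE(config$make_plots))
    km_plot(surv, risk, file.path(outdir, sprintf("08_km_%s.pdf", nm)),
            main = paste("Overall survival by risk group:", nm))

  uni_rows <- data.frame(
    cohort = nm,
    term = c("netscore_continuous", "risk_group_high"),
    beta = c(if (!is.null(cont)) cont$coefficients$beta else NA_real_,
             if (!is.null(group_fit)) group_fit$coefficients$beta else NA_real_),
    hr = c(if (!is.null(cont)) cont$coefficients$hr else NA_real_,
           if (!is.null(group_fit)) group_fit$coefficients$hr else NA_real_),
    ci_lo = c(if (!is.null(cont)) cont$coefficients$ci_lo else NA_real_,
              if (!is.null(group_fit)) group_fit$coefficients$ci_lo else NA_real_),
    ci_hi = c(if (!is.null(cont)) cont$coefficients$ci_hi else NA_real_,
              if (!is.null(group_fit)) group_fit$coefficients$ci_hi else NA_real_),
    p = c(if (!is.null(cont)) cont$coefficients$p else NA_real_,
          if (!is.null(group_fit)) group_fit$coefficients$p else NA_real_),
    stringsAsFactors = FALSE)
  multi <- NULL
  if (length(config$covariates)) {
    design <- data.frame(risk_group = risk,
                         surv[, config$covariates, drop = FALSE])
    multi <- tryCatch(cox_fit(design, surv), error = function(e) NULL)
    if (!is.null(multi))
      write_tsv_repro(cbind(cohort = nm, multi$coefficients),
                      file.path(outdir, sprintf("08_multivariate_%s.tsv", nm)))
  }
  write_tsv_repro(uni_rows, file.path(outdir, sprintf("08_cox_%s.tsv", nm)))
  write_tsv_repro(
    data.frame(cohort = nm, logrank_chisq = lr$chisq, logrank_df = lr$df,
               logrank_p = lr$p, c_index = ci$c_index, c_index_se = ci$se),
    file.path(outdir, sprintf("08_summary_%s.tsv", nm)))
  sub <- NULL
  if (length(config$subgroups)) {
    sub <- subgroup_analysis(risk, surv, config$subgroups)
    write_tsv_repro(cbind(cohort = nm, sub),
                    file.path(outdir, sprintf("08_subgroups_%s.tsv", nm)))
  }
  list(continuous = cont, group = group_fit, logrank = lr, c_index = ci,
       multivariate = multi, subgroups = sub)
}

#' Univariate Cox of the risk group within clinical subgroups
#'
#' Each subgroup is defined by a covariate level (`value`) or a numeric cut
#' (`cut`, meaning `covariate > cut`). Subgroups with fewer than 10 samples
#' or fewer than 3 events are reported as `"insufficient"` and no model is
#' fitted.
#'
#' @param risk factor of risk groups (`low`/`high`) per sample.
#' @param survival data.frame with `time`, `event` and the subgroup
#'   covariates.
#' @param subgroups list of `list(covariate=, value=)` or
#'   `list(covariate=, cut=)`.
#' @return data.frame: subgroup, n, n_events, hr, ci_lo, ci_hi, p, status.
#' @export
subgroup_analysis <- function(risk, survival, subgroups) {
  rows <- lapply(subgroups, function(sg) {
    if (!sg$covariate %in% names(survival))
      stop("unknown covariate: ", sg$covariate)
    v <- survival[[sg$covariate]]
    if (!is.null(sg$value)) {
      idx <- v == sg$value
      label <- paste0(sg$covariate, "=", sg$value)
    } else {
      idx <- v > sg$cut
      label <- paste0(sg$covariate, ">", sg$cut)
    }
    n <- sum(idx); ne <- sum(survival$event[idx])
    if (n < 10L || ne < 3L || length(unique(risk[idx])) < 2L)
      return(data.frame(subgroup = label, n = n, n_events = ne,
                        hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        p = NA_real_, status = "insufficient",
                        stringsAsFactors = FALSE))
    fit <- tryCatch(
      cox_fit(data.frame(risk_group = droplevels(risk[idx])),
              survival[idx, , drop = FALSE]),
      error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(subgroup = label, n = n, n_events = ne,
                        hr = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                        p = NA_real_, status = "failed",
                        stringsAsFactors = FALSE))
    co <- fit$coefficients
    data.frame(subgroup = label, n = n, n_events = ne, hr = co$hr,
               ci_lo = co$ci_lo, ci_hi = co$ci_hi, p = co$p, status = "ok",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier plot of risk groups
#' @param survival data.frame with `time` and `event`.
#' @param groups factor of group labels.
#' @param path PDF output path.
#' @param main plot title.
#' @export
km_plot <- function(survival, groups, path, main = "Overall survival") {
  grDevices::pdf(path, width = 6, height = 5)
  on.exit(grDevices::dev.off(), add = TRUE)
  fit <- survival::survfit(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = survival$time, event = survival$event,
                      g = groups))
  graphics::plot(fit, col = c("steelblue", "firebrick"), lwd = 2,
                 xlab = "Time (months)", ylab = "Survival probability",
                 main = main)
  graphics::legend("bottomleft", legend = levels(as.factor(groups)),
                   col = c("steelblue", "firebrick"), lwd = 2, bty = "n")
}

# Manifest: every seed/parameter plus md5 checksums of all TSV outputs, so a
# rerun with identical config is verifiable bit-for-bit.
write_manifest <- function(path, config, outdir, status, extra = list()) {
  tsvs <- sort(list.files(outdir, pattern = "\\.(tsv|txt)$"))
  sums <- tools::md5sum(file.path(outdir, tsvs))
  names(sums) <- tsvs
  cfg <- unclass(config)
  cfg$cohorts <- NULL   # file paths/objects: not serializable parameters
  if (!is.null(cfg$simulation)) cfg$simulation <- unclass(cfg$simulation)
  manifest <- c(list(package = "netscore",
                     version = as.character(utils::packageVersion("netscore")),
                     status = status,
                     config = cfg,
                     checksums = as.list(sums)),
                extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest
}

#' Regenerate the markdown report of a completed (or stopped) run directory
#'
#' Deterministic: regenerating from the same run directory is byte-identical.
#' Partial runs produce partial reports with explicit "not run" markers.
#'
#' @param outdir a pipeline run directory.
#' @return invisibly, the report path.
#' @export
write_report <- function(outdir) {
  path <- file.path(outdir, "report.md")
  lines <- c("# Pipeline report", "")
  add_table <- function(lines, file, title) {
    fp <- file.path(outdir, file)
    if (!file.exists(fp))
      return(c(lines, paste0("## ", title), "", "_not run_", ""))
    tab <- readLines(fp, warn = FALSE)
    header <- strsplit(tab[1L], "\t")[[1L]]
    sep <- paste(rep("---", length(header)), collapse = " | ")
    body <- vapply(tab, function(l)
      paste(strsplit(l, "\t")[[1L]], collapse = " | "), "")
    c(lines, paste0("## ", title), "", body[1L], sep,
      if (length(body) > 1L) body[-1L] else "_(empty)_", "")
  }
  lines <- add_table(lines, "02_screen_training.tsv",
                     "Module screening (training)")
  vfiles <- sort(list.files(outdir, pattern = "^03_validate_.*\\.tsv$"))
  for (f in vfiles)
    lines <- add_table(lines, f,
                       paste("Validation:", sub("^03_validate_(.*)\\.tsv$",
                                                "\\1", f)))
  sel <- file.path(outdir, "04_selected_modules.txt")
  lines <- c(lines, "## Modules advanced to model building", "")
  if (file.exists(sel)) {
    mods <- readLines(sel, warn = FALSE)
    lines <- c(lines,
               if (length(mods)) paste0("- ", mods)
               else "no survival-related modules validated", "")
  } else lines <- c(lines, "_not run_", "")
  lines <- add_table(lines, "05_selected_genes.tsv", "Selected genes")
  lines <- add_table(lines, "06_cv.tsv", "Cross-validation")
  sfiles <- sort(list.files(outdir, pattern = "^08_summary_.*\\.tsv$"))
  for (f in sfiles)
    lines <- add_table(lines, f,
                       paste("Survival summary:",
                             sub("^08_summary_(.*)\\.tsv$", "\\1", f)))
  mfiles <- sort(list.files(outdir, pattern = "^08_multivariate_.*\\.tsv$"))
  for (f in mfiles)
    lines <- add_table(lines, f,
                       paste("Multivariate Cox:",
                             sub("^08_multivariate_(.*)\\.tsv$", "\\1", f)))
  gfiles <- sort(list.files(outdir, pattern = "^08_subgroups_.*\\.tsv$"))
  for (f in gfiles)
    lines <- add_table(lines, f,
                       paste("Subgroups:",
                             sub("^08_subgroups_(.*)\\.tsv$", "\\1", f)))
  writeLines(lines, path)
  invisible(path)
}
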