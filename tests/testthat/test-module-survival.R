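# Multi-cohort study with one strong planted effect module among several null
# modules; used across the screening/validation/selection tests.
effect_study <- function(seed, beta = 1, loading = 0.8, n_train = 300,
                         n_test = 200, n_modules = 3, msize = 25) {
  cfg <- simulation_config(
    n_genes = n_modules * msize + 20,
    n_samples_per_cohort = c(n_train, n_test),
    n_modules = n_modules, module_sizes = rep(msize, n_modules),
    module_loading = rep(loading, n_modules),
    survival_effect = c(beta, rep(0, n_modules - 1)),
    censoring_rate_target = 0.3, seed = seed)
  generate_multi_cohort(cfg)
}

truth_assignment <- function(truth, colors = NULL) {
  m <- truth$gene_to_module
  k <- max(m)
  colors <- colors %||% module_color_sequence(k)
  lab <- ifelse(m > 0, colors[pmax(m, 1)], "gray")
  names(lab) <- names(m)
  sizes <- vapply(colors[seq_len(k)], function(cl) sum(lab == cl), 0L)
  structure(list(labels = lab, sizes = sizes,
                 params = list(height_cutoff = 0.99, deep_split = 2L,
                               min_size = 2L, assign_outliers = FALSE)),
            class = "module_assignment")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("screening flags a planted effect module with high power", {
  hits <- vapply(1:25, function(s) {
    mc <- effect_study(s)
    asg <- truth_assignment(mc$truth)
    mes <- module_eigengenes(mc$cohorts$training$expression, asg)
    sc <- screen_modules(mes, mc$cohorts$training$survival)
    sc$significant[sc$module == "turquoise"]
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("screening respects the uncorrected 0.05 threshold and errors on few events", {
  mc <- effect_study(1)
  asg <- truth_assignment(mc$truth)
  mes <- module_eigengenes(mc$cohorts$training$expression, asg)
  sc <- screen_modules(mes, mc$cohorts$training$survival)
  expect_identical(sc$significant, sc$p < 0.05)
  few <- mc$cohorts$training$survival
  few$event <- c(rep(1L, 5), rep(0L, nrow(few) - 5))
  expect_error(screen_modules(mes, few), "10 events")
})

test_that("validation recomputes eigengenes from the test cohort and tracks truth", {
  hits <- vapply(1:25, function(s) {
    mc <- effect_study(s)
    asg <- truth_assignment(mc$truth)
    v <- validate_modules(asg, mc$cohorts$test1)
    v$significant[v$module == "turquoise"]
  }, NA)
  expect_gte(mean(hits), 0.8)
})

test_that("validation skips modules with too few genes present", {
  mc <- effect_study(2)
  asg <- truth_assignment(mc$truth)
  co <- mc$cohorts$test1
  # drop 60% of the first module's genes
  m1_genes <- names(asg$labels)[asg$labels == "turquoise"]
  co$expression <- co$expression[
    !rownames(co$expression) %in% m1_genes[1:15], , drop = FALSE]
  expect_warning(expect_warning(v <- validate_modules(asg, co),
                                "dropped"), "skipped")
  row <- v[v$module == "turquoise", ]
  expect_true(row$skipped)
  expect_false(row$significant)
  # other modules still screened
  expect_false(any(v$skipped[v$module != "turquoise"]))
})

test_that("per-gene significance scores behave at both ends", {
  mc <- effect_study(3, beta = 1.5)
  tr <- mc$cohorts$training
  sig <- gene_significance(tr$expression, tr$survival)
  expect_true(all(sig$score >= 0, na.rm = TRUE))
  expect_identical(sig$gene, rownames(tr$expression))
  # effect-module genes score far higher than background genes
  m1 <- names(mc$truth$gene_to_module)[mc$truth$gene_to_module == 1]
  bg <- names(mc$truth$gene_to_module)[mc$truth$gene_to_module == 0]
  expect_gt(mean(sig$score[sig$gene %in% m1]),
            mean(sig$score[sig$gene %in% bg]) + 1)
})

test_that("null gene p-values are approximately uniform", {
  # one pure-noise gene per seed, same survival-generating process
  ps <- vapply(1:300, function(s) {
    set.seed(s)
    n <- 60
    x <- rnorm(n)
    tt <- rexp(n, 0.1)
    surv <- surv_df(time = tt, event = rep(1L, n))
    fitp <- gene_significance(
      matrix(x, 1, n, dimnames = list("g1", surv$sample)), surv)$p
    fitp
  }, 0)
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("kME-significance correlation is strong for effect modules, null otherwise", {
  rs_eff <- c(); rs_null <- c()
  for (s in 1:10) {
    mc <- effect_study(s, beta = 1, loading = 0.8)
    tr <- mc$cohorts$training
    asg <- truth_assignment(mc$truth)
    mes <- module_eigengenes(tr$expression, asg)
    gmm <- gene_module_membership(tr$expression, mes)
    sig <- gene_significance(tr$expression, tr$survival)
    ce <- gmm_significance_correlation(gmm, sig, "turquoise", asg)
    cn <- gmm_significance_correlation(gmm, sig, "blue", asg)
    rs_eff <- c(rs_eff, ce$r); rs_null <- c(rs_null, cn$r)
  }
  expect_gte(mean(rs_eff > 0.3), 0.8)
  expect_lt(abs(mean(rs_null)), 0.25)
  # identity: score perfectly aligned with |kME| gives r = 1
  gmm_id <- matrix(seq(0.1, 1, length.out = 10), ncol = 1,
                   dimnames = list(paste0("g", 1:10), "red"))
  sig_id <- data.frame(gene = paste0("g", 1:10),
                       p = NA, score = seq(0.1, 1, length.out = 10))
  lab <- setNames(rep("red", 10), paste0("g", 1:10))
  expect_equal(gmm_significance_correlation(gmm_id, sig_id, "red", lab)$r, 1,
               tolerance = 1e-12)
})

test_that("representative gene selection sorts by |kME| with deterministic ties", {
  set.seed(6)
  genes <- sprintf("g%02d", 1:30)
  kme <- matrix(round(runif(30, -1, 1), 2), ncol = 1,
                dimnames = list(genes, "blue"))
  lab <- setNames(rep("blue", 30), genes)
  got <- select_representative_genes(kme, "blue", lab, k = 10)
  want <- genes[order(-abs(kme[, 1]), genes)][1:10]
  expect_identical(got, want)
  # invariant to gene input order
  perm <- sample(30)
  got2 <- select_representative_genes(kme[perm, , drop = FALSE], "blue",
                                      lab[perm], k = 10)
  expect_identical(got2, got)
  # saturation: k >= module size returns the whole module with a warning
  expect_warning(all30 <- select_representative_genes(kme, "blue", lab,
                                                      k = 50), "only")
  expect_setequal(all30, genes)
  # signed ranking differs when strong negative kMEs exist
  signed <- select_representative_genes(kme, "blue", lab, k = 10,
                                        signed = TRUE)
  expect_identical(signed, genes[order(-kme[, 1], genes)][1:10])
})

test_that("default selection yields k genes per surviving module", {
  mc <- effect_study(4)
  tr <- mc$cohorts$training
  asg <- truth_assignment(mc$truth)
  mes <- module_eigengenes(tr$expression, asg)
  gmm <- gene_module_membership(tr$expression, mes)
  picked <- unlist(lapply(c("turquoise", "blue"), function(m)
    select_representative_genes(gmm, m, asg, k = 10)))
  expect_length(picked, 20)
  expect_length(unique(picked), 20)
})

test_that("hypergeometric enrichment matches the explicit combinatorial sum", {
  universe <- sprintf("u%03d", 1:100)
  module <- universe[1:20]
  sets <- list(hit = c(universe[1:5], universe[90:94]),  # overlap 5, size 10
               none = universe[80:89],                   # overlap 0
               exact = module)                           # overlap 20
  res <- hypergeometric_enrichment(module, sets, universe)
  expect_equal(res$p[res$set == "hit"],
               hyper_upper_explicit(5, 10, 100, 20), tolerance = 1e-12)
  expect_equal(res$p[res$set == "none"], 1)
  # monotone: more overlap, smaller p (rows sorted by p)
  expect_identical(res$set, c("exact", "hit", "none"))
  # p is monotone decreasing in overlap at fixed sizes
  ps <- vapply(0:10, function(ov)
    hyper_upper_explicit(max(ov, 0), 10, 100, 20), 0)
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeometric_enrichment(c("zz"), sets, universe), "subset")
  expect_error(hypergeometric_enrichment(module, sets, character(0)), "empty")
  # BH extension
  resq <- hypergeometric_enrichment(module, sets, universe, adjust = TRUE)
  expect_equal(resq$q, p.adjust(resq$p, "BH"))
})

test_that("GMT files round-trip through the reader", {
  dir <- withr::local_tempdir()
  gmt <- file.path(dir, "sets.gmt")
  writeLines(c("setA\tdesc A\tg1\tg2\tg3", "setB\tdesc B\tg2\tg4"), gmt)
  sets <- read_gmt(gmt)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  writeLines("broken\tonly-desc", file.path(dir, "bad.gmt"))
  expect_error(read_gmt(file.path(dir, "bad.gmt")), "malformed")
})
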