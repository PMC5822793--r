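# Independent brute-force oracles used to verify the package's fast paths.
# These deliberately re-derive each quantity from its definition (triple
# loops, explicit sums, grid searches) and never call the code they check.

# Topological overlap by triple loop over the definition.
tom_bruteforce <- function(adj) {
  n <- nrow(adj)
  k <- rowSums(adj)
  tom <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { tom[i, j] <- 1; next }
    l <- 0
    for (u in seq_len(n)) l <- l + adj[i, u] * adj[u, j]
    tom[i, j] <- (l + adj[i, j]) / (min(k[i], k[j]) + 1 - adj[i, j])
  }
  tom
}

# Average linkage from first principles: repeatedly merge the closest pair of
# clusters, distance between clusters = mean pairwise dissimilarity. Returns
# sorted merge heights (merge order of equal heights is not compared).
average_linkage_heights <- function(diss) {
  clusters <- as.list(seq_len(nrow(diss)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      d <- mean(diss[clusters[[a]], clusters[[b]]])
      if (d < bd) { bd <- d; best <- c(a, b) }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  sort(heights)
}

# Harrell's C by exhaustive enumeration of ordered pairs.
cindex_bruteforce <- function(score, time, event) {
  conc <- comp <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      comp <- comp + 1
      if (score[i] > score[j]) conc <- conc + 1
      else if (score[i] == score[j]) conc <- conc + 0.5
    }
  }
  list(c = conc / comp, comparable = comp)
}

# Explicit Cox log partial likelihood (Breslow) for a single covariate.
cox_loglik_explicit <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Hypergeometric upper tail by explicit combinatorial sum.
hyper_upper_explicit <- function(overlap, set_size, universe, module_size) {
  tot <- choose(universe, module_size)
  sum(vapply(overlap:min(set_size, module_size), function(i)
    choose(set_size, i) * choose(universe - set_size, module_size - i), 0)) / tot
}

# Adjusted Rand index between two labelings (mclust's implementation is the
# independent reference when available; this is the closed form otherwise).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# Small survival data frame helper.
surv_df <- function(time, event, ...)
  data.frame(sample = sprintf("s%03d", seq_along(time)), time = time,
             event = event, ...)

# Simulated single-covariate exponential PH cohort for Cox recovery checks.
# Censoring is independent exponential with rate chosen to give roughly the
# requested censored fraction (exact at beta = 0).
sim_ph <- function(n, beta, censor_frac = 0.3, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  t_ev <- -log(runif(n)) / (0.1 * exp(beta * x))
  cens <- rexp(n, 0.1 * censor_frac / (1 - censor_frac))
  list(x = x, surv = surv_df(pmin(t_ev, cens), as.integer(t_ev <= cens)))
}

# Fast planted-block fixture for network recovery tests.
block_network_data <- function(sizes = c(60, 50, 40), n_noise = 100,
                               loading = 0.8, n = 150, seed = 1) {
  cfg <- simulation_config(
    n_genes = sum(sizes) + n_noise,
    n_samples_per_cohort = c(n, n),
    n_modules = length(sizes), module_sizes = sizes,
    module_loading = rep(loading, length(sizes)),
    survival_effect = rep(0, length(sizes)),
    seed = seed)
  generate_cohort(cfg, 1)
}
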