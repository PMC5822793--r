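#' Architecture of the convolutional survival network
#'
#' The input layer is the concatenation of the modules' representative-gene
#' expression blocks. The first (convolutional) stage applies, to each module
#' block separately, `filters_per_module` one-dimensional filters whose length
#' equals that module's gene count (stride = block length), i.e. each filter
#' summarizes one module's gene vector into a single activation. The
#' concatenated activations feed three fully connected hidden layers and a
#' linear scalar output: the risk score (NetScore).
#'
#' @param modules named list, module label -> character vector of input genes
#'   (non-overlapping, each non-empty); gene order within a block should be
#'   decreasing |kME|.
#' @param filters_per_module number of filters per module block (default 8).
#' @param fc_sizes integer vector of exactly 3 hidden-layer widths
#'   (default c(16, 8, 4)).
#' @param activation `"tanh"` (default; smooth, avoids dead units in very small
#'   networks) or `"relu"`.
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(modules, filters_per_module = 8L,
                              fc_sizes = c(16L, 8L, 4L),
                              activation = c("tanh", "relu")) {
  activation <- match.arg(activation)
  if (!length(modules)) stop("at least one module is required")
  if (is.null(names(modules)) || any(!nzchar(names(modules))))
    stop("modules must be a named list")
  if (any(vapply(modules, length, 0L) < 1L))
    stop("every module must contribute at least one gene")
  all_genes <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(all_genes)) stop("module gene lists must not overlap")
  if (length(fc_sizes) != 3L)
    stop("exactly 3 fully connected hidden layers are required")
  if (filters_per_module < 1L || any(fc_sizes < 1L))
    stop("layer sizes must be positive")
  structure(list(modules = modules,
                 filters_per_module = as.integer(filters_per_module),
                 fc_sizes = as.integer(fc_sizes),
                 activation = activation,
                 input_genes = all_genes),
            class = "architecture_spec")
}

act_fun <- function(z, activation)
  if (activation == "relu") pmax(z, 0) else tanh(z)
act_deriv <- function(z, a, activation)
  if (activation == "relu") (z > 0) * 1 else 1 - a^2

#' Build (initialize) a NetScore model
#'
#' Weights are drawn from a seeded normal scheme with standard deviation
#' \eqn{\sqrt{2/\mathrm{fan~in}}}; biases start at zero. A fixed seed gives
#' bit-identical initial weights.
#'
#' @param spec an [architecture_spec()].
#' @param seed integer seed for weight initialization.
#' @return object of class `netscore_model` with untrained weights.
#' @export
build_netscore_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "architecture_spec"))
  set.seed(seed)
  nf <- spec$filters_per_module
  M <- length(spec$modules)
  params <- list()
  for (m in seq_len(M)) {
    g <- length(spec$modules[[m]])
    params[[paste0("convW", m)]] <-
      matrix(stats::rnorm(nf * g, sd = sqrt(2 / g)), nrow = nf)
    params[[paste0("convb", m)]] <- numeric(nf)
  }
  d0 <- M * nf
  dims <- c(d0, spec$fc_sizes)
  for (l in 1:3) {
    params[[paste0("W", l)]] <-
      matrix(stats::rnorm(dims[l + 1L] * dims[l], sd = sqrt(2 / dims[l])),
             nrow = dims[l + 1L])
    params[[paste0("b", l)]] <- numeric(dims[l + 1L])
  }
  params$wout <- stats::rnorm(dims[4L], sd = sqrt(2 / dims[4L]))
  params$bout <- 0
  structure(list(spec = spec, params = params, seed = as.integer(seed),
                 trained = FALSE, config = NULL, loss_trace = NULL),
            class = "netscore_model")
}

# Forward pass. X: samples x genes in spec$input_genes order. Returns eta and
# (optionally) the activation cache needed for backprop.
netscore_forward <- function(params, spec, X, cache = FALSE) {
  M <- length(spec$modules)
  act <- spec$activation
  sizes <- vapply(spec$modules, length, 0L)
  offsets <- cumsum(c(0L, sizes))
  Zc <- Ac <- vector("list", M)
  for (m in seq_len(M)) {
    idx <- offsets[m] + seq_len(sizes[m])
    Zc[[m]] <- sweep(X[, idx, drop = FALSE] %*% t(params[[paste0("convW", m)]]),
                     2L, params[[paste0("convb", m)]], "+")
    Ac[[m]] <- act_fun(Zc[[m]], act)
  }
  H0 <- do.call(cbind, Ac)
  Z1 <- sweep(H0 %*% t(params$W1), 2L, params$b1, "+"); A1 <- act_fun(Z1, act)
  Z2 <- sweep(A1 %*% t(params$W2), 2L, params$b2, "+"); A2 <- act_fun(Z2, act)
  Z3 <- sweep(A2 %*% t(params$W3), 2L, params$b3, "+"); A3 <- act_fun(Z3, act)
  eta <- drop(A3 %*% params$wout) + params$bout
  if (!cache) return(eta)
  list(eta = eta, X = X, Zc = Zc, Ac = Ac, H0 = H0,
       Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, Z3 = Z3, A3 = A3)
}

# Backward pass: gradient of the loss w.r.t. every parameter, given
# d loss / d eta.
netscore_backward <- function(params, spec, cache, deta) {
  M <- length(spec$modules)
  act <- spec$activation
  sizes <- vapply(spec$modules, length, 0L)
  offsets <- cumsum(c(0L, sizes))
  nf <- spec$filters_per_module
  grads <- list()
  grads$wout <- drop(t(cache$A3) %*% deta)
  grads$bout <- sum(deta)
  dA3 <- outer(deta, params$wout)
  dZ3 <- dA3 * act_deriv(cache$Z3, cache$A3, act)
  grads$W3 <- t(dZ3) %*% cache$A2; grads$b3 <- colSums(dZ3)
  dA2 <- dZ3 %*% params$W3
  dZ2 <- dA2 * act_deriv(cache$Z2, cache$A2, act)
  grads$W2 <- t(dZ2) %*% cache$A1; grads$b2 <- colSums(dZ2)
  dA1 <- dZ2 %*% params$W2
  dZ1 <- dA1 * act_deriv(cache$Z1, cache$A1, act)
  grads$W1 <- t(dZ1) %*% cache$H0; grads$b1 <- colSums(dZ1)
  dH0 <- dZ1 %*% params$W1
  for (m in seq_len(M)) {
    cols <- (m - 1L) * nf + seq_len(nf)
    idx <- offsets[m] + seq_len(sizes[m])
    dZc <- dH0[, cols, drop = FALSE] *
      act_deriv(cache$Zc[[m]], cache$Ac[[m]], act)
    grads[[paste0("convW", m)]] <- t(dZc) %*% cache$X[, idx, drop = FALSE]
    grads[[paste0("convb", m)]] <- colSums(dZc)
  }
  grads
}

#' Negative Cox log partial likelihood of a score vector (with gradient)
#'
#' \deqn{L(\eta) = -\sum_{i: event} [\eta_i - \log \sum_{j: t_j \ge t_i}
#' e^{\eta_j}]} with Breslow handling of tied event times. This is the
#' training objective of the survival network; it is invariant to adding a
#' constant to all scores.
#'
#' @param eta numeric risk scores.
#' @param survival data.frame with `time` and `event` aligned to `eta`
#'   (at least one event).
#' @return list with `loss` (scalar) and `gradient` (d loss / d eta).
#' @export
cox_loss <- function(eta, survival) {
  time <- survival$time; event <- survival$event
  stopifnot(length(eta) == length(time))
  if (sum(event) < 1L) stop("cox_loss undefined: no events in batch")
  o <- order(time)
  ts <- time[o]; es <- event[o]; hs <- eta[o]
  mx <- max(hs)
  w <- exp(hs - mx)
  rc <- rev(cumsum(rev(w)))
  first <- match(ts, ts)                 # first index of each tie group
  logS <- log(rc[first]) + mx            # log sum_{t_j >= t_i} e^{eta_j}
  loss <- -sum((hs - logS)[es == 1L])
  # gradient: -event_k + e^{eta_k} * sum_{events i: t_i <= t_k} 1 / S_i
  last <- length(ts) - match(ts, rev(ts)) + 1L   # last index of tie group
  cum <- cumsum(es * exp(-logS))
  grad_s <- -es + exp(hs) * cum[last]
  grad <- numeric(length(eta))
  grad[o] <- grad_s
  list(loss = loss, gradient = grad)
}

#' Training configuration for the survival network
#'
#' @param lr learning rate (> 0).
#' @param epochs number of full-batch gradient steps (>= 0).
#' @param seed seed recorded with the model (weight initialization uses the
#'   model's own seed; training itself is deterministic).
#' @param optimizer `"adam"` (adaptive-moment estimation) or `"sgd"`.
#' @param l2 L2 weight-decay coefficient on all weights (biases excluded);
#   decoupled weight decay: regularizes the small full-batch network against
#   overfitting the partial likelihood (default 1).
#' @return object of class `training_config`.
#' @export
training_config <- function(lr = 1e-2, epochs = 500L, seed = 1L,
                            optimizer = c("adam", "sgd"), l2 = 1) {
  optimizer <- match.arg(optimizer)
  if (lr <= 0) stop("learning rate must be positive")
  if (epochs < 0) stop("epochs must be non-negative")
  if (l2 < 0) stop("l2 must be non-negative")
  structure(list(lr = lr, epochs = as.integer(epochs), seed = as.integer(seed),
                 optimizer = optimizer, l2 = l2, full_batch = TRUE),
            class = "training_config")
}

# Assemble the samples x genes input matrix for a cohort, standardizing each
# gene within the cohort.
netscore_input <- function(spec, cohort) {
  expr <- if (inherits(cohort, "cohort")) cohort$expression else cohort
  missing <- setdiff(spec$input_genes, rownames(expr))
  if (length(missing))
    stop("missing input gene(s): ", paste(missing, collapse = ", "))
  t(standardize_rows(expr[spec$input_genes, , drop = FALSE]))
}

#' Train a NetScore model by full-batch minimization of the Cox loss
#'
#' The partial likelihood couples samples through risk sets, so training is
#' full-batch: every epoch is one gradient step on the whole training cohort
#' (Adam by default). Training is deterministic given the model's
#' initialization and the data.
#'
#' @param model an (untrained) `netscore_model`.
#' @param cohort a `cohort` providing all input genes, with at least 20
#'   samples and 5 events.
#' @param config a [training_config()].
#' @return the trained `netscore_model` (with `loss_trace` recorded).
#' @export
train_netscore <- function(model, cohort, config = training_config()) {
  stopifnot(inherits(model, "netscore_model"),
            inherits(config, "training_config"))
  X <- netscore_input(model$spec, cohort)
  surv <- cohort$survival
  if (nrow(X) < 20L) stop("at least 20 training samples are required")
  if (sum(surv$event) < 5L) stop("at least 5 events are required")
  params <- model$params
  trace <- numeric(config$epochs)
  if (config$optimizer == "adam") {
    mo <- lapply(params, function(p) p * 0)
    vo <- lapply(params, function(p) p * 0)
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  }
  for (ep in seq_len(config$epochs)) {
    fw <- netscore_forward(params, model$spec, X, cache = TRUE)
    cl <- cox_loss(fw$eta, surv)
    if (!is.finite(cl$loss))
      stop("training diverged (non-finite loss) at learning rate ", config$lr)
    trace[ep] <- cl$loss
    grads <- netscore_backward(params, model$spec, fw, cl$gradient)
    if (config$optimizer == "adam") {
      for (nm in names(params)) {
        mo[[nm]] <- b1 * mo[[nm]] + (1 - b1) * grads[[nm]]
        vo[[nm]] <- b2 * vo[[nm]] + (1 - b2) * grads[[nm]]^2
        mhat <- mo[[nm]] / (1 - b1^ep)
        vhat <- vo[[nm]] / (1 - b2^ep)
        decay <- if (grepl("^(convW|W|wout)", nm)) config$l2 else 0
        params[[nm]] <- params[[nm]] -
          config$lr * (mhat / (sqrt(vhat) + eps) + decay * params[[nm]])
      }
    } else {
      for (nm in names(params)) {
        decay <- if (grepl("^(convW|W|wout)", nm)) config$l2 else 0
        params[[nm]] <- params[[nm]] -
          config$lr * (grads[[nm]] + decay * params[[nm]])
      }
    }
  }
  model$params <- params
  model$trained <- TRUE
  model$config <- config
  model$loss_trace <- trace
  model
}

#' Score a cohort with a NetScore model
#'
#' Deterministic forward pass; genes are standardized within the cohort being
#' scored before entering the network; sample order is preserved.
#'
#' @param model a `netscore_model`.
#' @param cohort a `cohort` (or genes-by-samples matrix) covering all input
#'   genes.
#' @return named numeric vector of risk scores (one per sample).
#' @export
predict_netscore <- function(model, cohort) {
  X <- netscore_input(model$spec, cohort)
  eta <- netscore_forward(model$params, model$spec, X)
  names(eta) <- rownames(X)
  eta
}

#' 5-fold cross-validation over an architecture/training grid
#'
#' The training cohort is partitioned into `k` seeded random folds; each grid
#' configuration is trained on k-1 folds and scored by Harrell's C-index on
#' the held-out fold; the configuration with maximal mean C-index is chosen.
#' If any fold contains zero events the partition is re-randomized once, then
#' an error is raised.
#'
#' @param cohort training `cohort`.
#' @param modules named list module -> input gene vector (defines the
#'   network input layout).
#' @param grid list of configurations, each a list with
#'   `filters_per_module`, `fc_sizes`, `lr`, `epochs` (optional
#'   `activation`, and `init_params` to score a fixed pre-set model).
#' @param k number of folds (default 5).
#' @param seed seed for the fold partition and per-fold initializations.
#' @return object of class `cv_record`: `folds` (fold id per sample),
#'   `table` (per-config mean/sd of fold C-indices), `fold_c`
#'   (configs x folds matrix), `chosen` (index of the best config),
#'   `chosen_config`.
#' @export
cross_validate_netscore <- function(cohort, modules, grid, k = 5L, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"), length(grid) >= 1L, k >= 2L)
  n <- ncol(cohort$expression)
  surv <- cohort$survival
  make_folds <- function(s) {
    set.seed(s)
    sample(rep(seq_len(k), length.out = n))
  }
  folds <- make_folds(seed)
  if (any(tapply(surv$event, folds, sum) == 0)) {
    folds <- make_folds(seed + 1L)
    if (any(tapply(surv$event, folds, sum) == 0))
      stop("a cross-validation fold has zero events")
  }
  fold_c <- matrix(NA_real_, nrow = length(grid), ncol = k)
  for (ci in seq_along(grid)) {
    g <- grid[[ci]]
    spec <- architecture_spec(
      modules,
      filters_per_module = g$filters_per_module %||% 8L,
      fc_sizes = g$fc_sizes %||% c(16L, 8L, 4L),
      activation = g$activation %||% "relu")
    for (f in seq_len(k)) {
      tr <- folds != f
      tr_cohort <- subset_cohort(cohort, tr)
      te_cohort <- subset_cohort(cohort, !tr)
      mdl <- build_netscore_model(spec, seed = seed + 1000L * ci + f)
      if (!is.null(g$init_params)) mdl$params <- g$init_params
      mdl <- train_netscore(mdl, tr_cohort,
                            training_config(lr = g$lr %||% 1e-2,
                                            epochs = g$epochs %||% 300L,
                                            seed = seed))
      sc <- predict_netscore(mdl, te_cohort)
      fold_c[ci, f] <- concordance_index(sc, te_cohort$survival,
                                         n_boot = 0L)$c_index
    }
  }
  tab <- data.frame(
    config = seq_along(grid),
    filters = vapply(grid, function(g) g$filters_per_module %||% 8L, 0L),
    fc = vapply(grid, function(g)
      paste(g$fc_sizes %||% c(16L, 8L, 4L), collapse = "-"), ""),
    lr = vapply(grid, function(g) g$lr %||% 1e-2, 0),
    epochs = vapply(grid, function(g) as.integer(g$epochs %||% 300L), 0L),
    mean_c = rowMeans(fold_c),
    sd_c = apply(fold_c, 1L, stats::sd))
  chosen <- which.max(tab$mean_c)
  structure(list(folds = folds, table = tab, fold_c = fold_c,
                 chosen = chosen, chosen_config = grid[[chosen]]),
            class = "cv_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Subset a cohort to a logical/integer sample index.
subset_cohort <- function(cohort, idx) {
  structure(list(expression = cohort$expression[, idx, drop = FALSE],
                 survival = cohort$survival[idx, , drop = FALSE],
                 name = cohort$name),
            class = "cohort")
}

#' Compare NetScore with a conventional Cox model on the same genes
#'
#' Fits a multivariate Cox proportional-hazards model on the selected genes
#' and trains a NetScore network on the same genes, both on the training
#' cohort; reports Harrell's C-index (with bootstrap SE) of both scores on
#' every cohort. If the Cox fit fails, its rows carry NA and the NetScore
#' rows are still emitted.
#'
#' @param cohorts list of `cohort`s, first = training.
#' @param modules named list module -> gene vector (union = the gene panel).
#' @param filters_per_module,fc_sizes network architecture (defaults 8 and
#'   c(16, 8, 4)).
#' @param config a [training_config()].
#' @param seed seed for initialization and bootstrap SEs.
#' @param n_boot bootstrap resamples for the C-index SE.
#' @return data.frame: cohort, model ("netscore"/"cox"), c_index, se.
#' @export
compare_with_cox_baseline <- function(cohorts, modules,
                                      filters_per_module = 8L,
                                      fc_sizes = c(16L, 8L, 4L),
                                      config = training_config(),
                                      seed = 1L, n_boot = 200L) {
  stopifnot(length(cohorts) >= 1L)
  genes <- unlist(modules, use.names = FALSE)
  train <- cohorts[[1L]]
  spec <- architecture_spec(modules, filters_per_module, fc_sizes)
  net <- train_netscore(build_netscore_model(spec, seed = seed), train, config)
  cox_beta <- tryCatch({
    fit <- cox_fit(as.data.frame(t(train$expression[genes, , drop = FALSE])),
                   train$survival)
    stats::setNames(fit$coefficients$beta, genes)
  }, error = function(e) {
    warning("Cox baseline failed on training cohort: ", conditionMessage(e))
    NULL
  })
  rows <- lapply(seq_along(cohorts), function(i) {
    co <- cohorts[[i]]
    nm <- co$name %||% paste0("cohort", i)
    ns <- predict_netscore(net, co)
    cn <- concordance_index(ns, co$survival, n_boot = n_boot, seed = seed)
    out <- data.frame(cohort = nm, model = "netscore",
                      c_index = cn$c_index, se = cn$se,
                      stringsAsFactors = FALSE)
    if (!is.null(cox_beta)) {
      lp <- drop(t(co$expression[genes, , drop = FALSE]) %*% cox_beta)
      cc <- concordance_index(lp, co$survival, n_boot = n_boot, seed = seed)
      out <- rbind(out, data.frame(cohort = nm, model = "cox",
                                   c_index = cc$c_index, se = cc$se,
                                   stringsAsFactors = FALSE))
    } else {
      out <- rbind(out, data.frame(cohort = nm, model = "cox",
                                   c_index = NA_real_, se = NA_real_,
                                   stringsAsFactors = FALSE))
    }
    out
  })
  do.call(rbind, rows)
}
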