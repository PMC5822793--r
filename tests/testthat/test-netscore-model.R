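two_module_layout <- function() {
  list(turquoise = sprintf("t%02d", 1:10), blue = sprintf("b%02d", 1:10))
}

# Small cohort whose hazard depends linearly on the mean of each gene block.
toy_cohort <- function(n = 60, seed = 1, beta = 1.2) {
  set.seed(seed)
  genes <- unlist(two_module_layout())
  f1 <- rnorm(n); f2 <- rnorm(n)
  expr <- rbind(
    t(sapply(1:10, function(i) 0.9 * f1 + rnorm(n, sd = 0.44))),
    t(sapply(1:10, function(i) 0.9 * f2 + rnorm(n, sd = 0.44))))
  dimnames(expr) <- list(genes, sprintf("s%03d", 1:n))
  eta <- beta * (f1 + f2)
  tt <- -log(runif(n)) / (0.1 * exp(eta))
  structure(list(expression = expr,
                 survival = data.frame(sample = colnames(expr), time = tt,
                                       event = rep(1L, n)),
                 name = "toy"),
            class = "cohort")
}

test_that("architecture invariants are enforced", {
  mods <- two_module_layout()
  expect_error(architecture_spec(list()), "at least one")
  expect_error(architecture_spec(list(a = character(0))), "at least one gene")
  expect_error(architecture_spec(list(a = "g1", b = "g1")), "overlap")
  expect_error(architecture_spec(mods, fc_sizes = c(8, 4)), "exactly 3")
  spec <- architecture_spec(mods)
  expect_length(spec$input_genes, 20)   # 2 modules x 10 genes
})

test_that("model building is deterministic and shape-consistent", {
  spec <- architecture_spec(two_module_layout(), 4L, c(8L, 4L, 2L))
  m1 <- build_netscore_model(spec, seed = 7)
  m2 <- build_netscore_model(spec, seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- build_netscore_model(spec, seed = 8)
  expect_false(identical(m1$params, m3$params))
  expect_identical(dim(m1$params$convW1), c(4L, 10L))
  expect_identical(dim(m1$params$W1), c(8L, 8L))   # 2 modules x 4 filters in
  expect_length(m1$params$wout, 2L)
})

test_that("a 1-gene 1-filter (1,1,1) network is an explicit affine chain", {
  spec <- architecture_spec(list(m = "g1"), 1L, c(1L, 1L, 1L),
                            activation = "tanh")
  mdl <- build_netscore_model(spec, seed = 3)
  x <- c(-1.3, 0, 0.8, 2.1)
  X <- matrix(x, ncol = 1, dimnames = list(paste0("s", 1:4), "g1"))
  got <- netscore_forward(mdl$params, spec, X)
  p <- mdl$params
  hand <- vapply(x, function(v) {
    a0 <- tanh(p$convW1[1, 1] * v + p$convb1[1])
    a1 <- tanh(p$W1[1, 1] * a0 + p$b1[1])
    a2 <- tanh(p$W2[1, 1] * a1 + p$b2[1])
    a3 <- tanh(p$W3[1, 1] * a2 + p$b3[1])
    p$wout[1] * a3 + p$bout
  }, 0)
  expect_equal(unname(got), hand, tolerance = 1e-12)
})

test_that("cox_loss matches its closed forms and is shift-invariant", {
  surv <- surv_df(time = c(3, 1, 4, 2, 5), event = c(1L, 1L, 0L, 1L, 1L))
  # all-equal scores: loss = sum over events of log(risk-set size)
  cl0 <- cox_loss(rep(0.7, 5), surv)
  expect_equal(cl0$loss, log(5) + log(4) + log(3) + log(1), tolerance = 1e-12)
  set.seed(1)
  eta <- rnorm(5)
  cl1 <- cox_loss(eta, surv)
  cl2 <- cox_loss(eta + 13.7, surv)
  expect_equal(cl1$loss, cl2$loss, tolerance = 1e-8)
  expect_equal(cl1$gradient, cl2$gradient, tolerance = 1e-8)
  expect_error(cox_loss(eta, surv_df(time = 1:5, event = rep(0L, 5))),
               "no events")
  # ties: loss agrees with coxph's null/offset likelihood machinery
  survt <- surv_df(time = c(2, 2, 3, 3, 5, 6), event = c(1L, 1L, 1L, 0L, 1L, 1L))
  etat <- c(0.5, -0.2, 0.1, 0.9, -1, 0.3)
  fit <- survival::coxph(survival::Surv(time, event) ~ offset(etat),
                         data = survt, ties = "breslow")
  expect_equal(cox_loss(etat, survt)$loss, -fit$loglik[1], tolerance = 1e-8)
})

test_that("cox_loss analytic gradient matches central finite differences", {
  for (s in 1:5) {
    set.seed(s)
    n <- 10
    surv <- surv_df(time = sample(1:8, n, replace = TRUE),
                    event = rbinom(n, 1, 0.7))
    if (sum(surv$event) == 0) surv$event[1] <- 1L
    eta <- rnorm(n)
    g <- cox_loss(eta, surv)$gradient
    h <- 1e-6
    fd <- vapply(seq_len(n), function(i) {
      ep <- en <- eta
      ep[i] <- ep[i] + h; en[i] <- en[i] - h
      (cox_loss(ep, surv)$loss - cox_loss(en, surv)$loss) / (2 * h)
    }, 0)
    denom <- pmax(abs(fd), 1e-8)
    expect_lt(max(abs(g - fd) / denom), 1e-5)
  }
})

test_that("full network gradient matches finite differences", {
  spec <- architecture_spec(list(a = paste0("t", 1:3), b = paste0("u", 1:2)),
                            2L, c(3L, 2L, 2L), activation = "tanh")
  mdl <- build_netscore_model(spec, seed = 5)
  set.seed(5)
  n <- 12
  X <- matrix(rnorm(n * 5), n, 5)
  surv <- surv_df(time = runif(n, 1, 10), event = rep(1L, n))
  fw <- netscore_forward(mdl$params, spec, X, cache = TRUE)
  cl <- cox_loss(fw$eta, surv)
  grads <- netscore_backward(mdl$params, spec, fw, cl$gradient)
  h <- 1e-6
  for (nm in c("convW1", "W2", "wout", "b1", "bout")) {
    p <- mdl$params[[nm]]
    for (i in seq_along(p)[seq_len(min(4, length(p)))]) {
      pp <- pm <- mdl$params
      pp[[nm]][i] <- pp[[nm]][i] + h
      pm[[nm]][i] <- pm[[nm]][i] - h
      fd <- (cox_loss(netscore_forward(pp, spec, X), surv)$loss -
             cox_loss(netscore_forward(pm, spec, X), surv)$loss) / (2 * h)
      expect_equal(unname(grads[[nm]][i]), fd, tolerance = 1e-4)
    }
  }
})

test_that("training is a deterministic no-op at 0 epochs and reduces the loss", {
  co <- toy_cohort(seed = 2)
  spec <- architecture_spec(two_module_layout(), 4L, c(8L, 4L, 2L))
  mdl <- build_netscore_model(spec, seed = 2)
  m0 <- train_netscore(mdl, co, training_config(epochs = 0L))
  expect_identical(m0$params, mdl$params)
  m1 <- train_netscore(mdl, co, training_config(lr = 1e-2, epochs = 150L))
  expect_lt(m1$loss_trace[150], m1$loss_trace[1])
  m2 <- train_netscore(mdl, co, training_config(lr = 1e-2, epochs = 150L))
  expect_identical(m1$params, m2$params)
  # divergence names the learning rate
  expect_error(train_netscore(mdl, co, training_config(lr = 50, epochs = 200L)),
               "learning rate")
})

test_that("prediction is deterministic, order-preserving and checks genes", {
  co <- toy_cohort(seed = 3)
  spec <- architecture_spec(two_module_layout())
  mdl <- train_netscore(build_netscore_model(spec, seed = 3), co,
                        training_config(epochs = 50L))
  s1 <- predict_netscore(mdl, co)
  s2 <- predict_netscore(mdl, co)
  expect_identical(s1, s2)
  expect_identical(names(s1), colnames(co$expression))
  co2 <- co
  co2$expression <- co2$expression[-1, ]
  expect_error(predict_netscore(mdl, co2), "t01")
  # scoring is a pointwise function: identical sample columns score equally
  co4 <- co
  co4$expression[, 6] <- co4$expression[, 5]
  s4 <- predict_netscore(mdl, co4)
  expect_equal(unname(s4[5]), unname(s4[6]), tolerance = 1e-12)
})

test_that("cross-validation partitions correctly and selects the oracle config", {
  co <- toy_cohort(n = 80, seed = 4, beta = 1.5)
  mods <- two_module_layout()
  # oracle config: weights preloaded with the planted linear solution, 0 epochs
  spec1 <- architecture_spec(mods, 1L, c(1L, 1L, 1L), activation = "relu")
  oracle <- build_netscore_model(spec1, seed = 1)
  p <- oracle$params
  p$convW1 <- matrix(1 / 10, 1, 10); p$convW2 <- matrix(1 / 10, 1, 10)
  p$convb1 <- 10; p$convb2 <- 10        # keep ReLU units in the linear regime
  p$W1 <- matrix(c(1, 1), 1, 2); p$b1 <- 0
  p$W2 <- matrix(1, 1, 1); p$b2 <- 0
  p$W3 <- matrix(1, 1, 1); p$b3 <- 0
  p$wout <- 1; p$bout <- 0
  grid <- list(
    list(filters_per_module = 1L, fc_sizes = c(1L, 1L, 1L),
         activation = "relu", lr = 1e-3, epochs = 0L, init_params = p),
    list(filters_per_module = 2L, fc_sizes = c(2L, 2L, 2L),
         activation = "tanh", lr = 1e-3, epochs = 0L))   # random untrained net
  cv <- cross_validate_netscore(co, mods, grid, k = 5L, seed = 9)
  expect_identical(sort(unique(cv$folds)), 1:5)
  expect_length(cv$folds, 80)
  expect_equal(cv$chosen, 1L)
  expect_gt(cv$table$mean_c[1], cv$table$mean_c[2])
  expect_gt(cv$table$mean_c[1], 0.7)
})

test_that("cross-validation re-randomizes once, then errors on event-free folds", {
  co <- toy_cohort(n = 30, seed = 5)
  co$survival$event <- c(rep(1L, 3), rep(0L, 27))
  grid <- list(list(filters_per_module = 1L, fc_sizes = c(1L, 1L, 1L),
                    epochs = 0L))
  expect_error(
    cross_validate_netscore(co, two_module_layout(), grid, k = 10L,
                            seed = 1),
    "zero events")
})

test_that("NetScore and the Cox baseline are compared on every cohort", {
  co_tr <- toy_cohort(n = 80, seed = 6)
  co_te <- toy_cohort(n = 50, seed = 7)
  co_te$name <- "test1"
  tab <- compare_with_cox_baseline(list(co_tr, co_te), two_module_layout(),
                                   config = training_config(epochs = 100L),
                                   seed = 2, n_boot = 20L)
  expect_identical(dim(tab), c(4L, 4L))
  expect_setequal(tab$model, c("netscore", "cox"))
  expect_setequal(tab$cohort, c("toy", "test1"))
  expect_true(all(tab$c_index >= 0 & tab$c_index <= 1))
  expect_true(all(is.finite(tab$se)))
})
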