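test_that("hyperparameter grids match the benchmarking design", {
  expect_equal(hyper_grid("LR"), 10^seq(-6, 3, length.out = 10))
  expect_equal(hyper_grid("CoxPH"), hyper_grid("LR"))
  expect_equal(hyper_grid("RF"), c(2, 4, 8, 16, 32, 64, 128))
  expect_equal(hyper_grid("kNN"), c(1, 3, 5, 7, 9))
})

test_that("logistic regression matches second-order reference solvers", {
  set.seed(21)
  n <- 200; p <- 5
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(1, -0.5, 0.3, 0, 0.8)
  y <- factor(rbinom(n, 1, plogis(X %*% beta - 0.2)))

  # unpenalized: against IRLS (glm)
  m <- fit_logistic(X, y, 0, maxit = 5000, tol = 1e-9)
  bhat <- m$coefficients[, 2] - m$coefficients[, 1]
  ref <- glm(y ~ X, family = binomial)
  expect_lt(max(abs(bhat - coef(ref)[-1])), 1e-2)
  expect_lt(abs((m$fit$b[2] - m$fit$b[1]) - coef(ref)[1]), 1e-2)

  # penalized: against a quasi-Newton minimizer of the identical objective
  lam <- 0.01
  m2 <- fit_logistic(X, y, lam, maxit = 5000, tol = 1e-10)
  obj <- function(th) {
    W <- matrix(th[1:(2 * p)], p, 2); b <- th[2 * p + 1:2]
    eta <- sweep(X %*% W, 2, b, "+")
    -mean(eta[cbind(1:n, as.integer(y))] - log(rowSums(exp(eta)))) +
      lam * sum(W^2)
  }
  ref2 <- optim(rep(0, 2 * p + 2), obj, method = "BFGS",
                control = list(maxit = 1000, reltol = 1e-14))
  W_ref <- matrix(ref2$par[1:(2 * p)], p, 2)
  expect_lt(max(abs((m2$coefficients[, 2] - m2$coefficients[, 1]) -
                      (W_ref[, 2] - W_ref[, 1]))), 1e-2)
})

test_that("logistic limits: separability and heavy regularization", {
  X <- matrix(c(rnorm(30, -3), rnorm(30, 3)), ncol = 1)
  y <- factor(rep(c(0, 1), each = 30))
  m <- fit_logistic(X, y, 1e-6, maxit = 2000)
  pred <- predict_model(m, X)
  expect_equal(accuracy(colnames(pred)[max.col(pred)], y), 1)
  expect_equal(rowSums(pred), rep(1, 60), tolerance = 1e-12)

  m_big <- fit_logistic(X, y, 1e3, maxit = 2000)
  expect_lt(sqrt(sum(m_big$coefficients^2)),
            0.01 * sqrt(sum(m$coefficients^2)))

  expect_error(fit_logistic(X, factor(rep("a", 60)), 0), "2 classes")
})

test_that("random forest and kNN behave at their regime limits", {
  set.seed(31)
  n <- 50
  X <- matrix(rnorm(n * 3), n, 3)
  y <- factor(as.numeric(X[, 1] > 0))
  rf <- fit_rf(X, y, 128, seed = 1)
  pred <- predict_model(rf, X)
  expect_gte(accuracy(colnames(pred)[max.col(pred)], y), 0.98)

  k1 <- fit_knn(X, y, 1)
  p1 <- predict_model(k1, X)
  expect_equal(accuracy(colnames(p1)[max.col(p1)], y), 1)

  y_imb <- factor(c(rep(0, 35), rep(1, 15)))
  kn <- fit_knn(X, y_imb, n)
  pn <- predict_model(kn, X)
  expect_true(all(colnames(pn)[max.col(pn)] == "0"))
  expect_error(fit_knn(X, y, n + 1), "exceeds")
})

test_that("Efron pseudolikelihood matches closed forms and survival", {
  # 2 subjects, first fails: risk set of 2 at beta = 0
  r <- efron_pseudolikelihood(0, matrix(c(1, 2), 2, 1), c(1, 2), c(1, 0))
  expect_equal(r$value, log(2))

  # tied pair toy at beta = 0: hand-evaluated Efron correction
  # times (1,1,2), events (1,1,0): -ll = log(3) + log(3 - 2/2) = log(6)
  r2 <- efron_pseudolikelihood(0, matrix(1:3, 3, 1), c(1, 1, 2),
                               c(1, 1, 0))
  expect_equal(r2$value, log(3) + log(2))

  # tie-free: equals the standard partial likelihood (reference library)
  set.seed(41)
  n <- 60; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  time <- rexp(n, exp(X[, 1] * 0.5)); ev <- rbinom(n, 1, 0.8)
  b0 <- rnorm(p) * 0.3
  mine <- efron_pseudolikelihood(b0, X, time, ev)
  ref <- survival::coxph(survival::Surv(time, ev) ~ X, init = b0,
                         control = survival::coxph.control(iter.max = 0))
  expect_equal(-mine$value, ref$loglik[2], tolerance = 1e-8)

  expect_error(efron_pseudolikelihood(0, X, time, rep(0, n)),
               "at least one event")
})

test_that("Efron gradient matches central finite differences", {
  set.seed(43)
  for (rep in 1:3) {
    n <- 30; p <- 3
    X <- matrix(rnorm(n * p), n, p)
    time <- round(rexp(n), 1) + 0.1          # induces ties
    ev <- rbinom(n, 1, 0.7)
    if (sum(ev) == 0) ev[1] <- 1
    b0 <- rnorm(p) * 0.5
    g <- efron_pseudolikelihood(b0, X, time, ev)$gradient
    fd <- vapply(seq_len(p), function(j) {
      h <- 1e-5
      bp <- b0; bp[j] <- bp[j] + h
      bm <- b0; bm[j] <- bm[j] - h
      (efron_pseudolikelihood(bp, X, time, ev)$value -
         efron_pseudolikelihood(bm, X, time, ev)$value) / (2 * h)
    }, numeric(1))
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("Cox fit matches a Newton-based reference and shrinks to zero", {
  set.seed(47)
  n <- 50; p <- 3
  X <- matrix(rnorm(n * p), n, p)
  time <- rexp(n, exp(X %*% c(0.8, -0.5, 0.2)))
  ev <- rbinom(n, 1, 0.85)
  m <- fit_cox_efron(X, time, ev, 0, maxit = 5000, tol = 1e-9)
  ref <- survival::coxph(survival::Surv(time, ev) ~ X, ties = "efron")
  expect_lt(max(abs(m$fit$beta - coef(ref))), 1e-2)

  m_big <- fit_cox_efron(X, time, ev, 1e3, maxit = 1000)
  expect_lt(sqrt(sum(m_big$fit$beta^2)), 1e-3)

  # order invariance: the likelihood does not depend on subject order
  perm <- sample(n)
  m_perm <- fit_cox_efron(X[perm, ], time[perm], ev[perm], 0.1,
                          maxit = 2000, tol = 1e-8)
  m_orig <- fit_cox_efron(X, time, ev, 0.1, maxit = 2000, tol = 1e-8)
  expect_equal(m_perm$fit$beta, m_orig$fit$beta, tolerance = 1e-5)
})

test_that("fits are reproducible bit for bit", {
  set.seed(51)
  X <- matrix(rnorm(200), 50, 4)
  y <- factor(rbinom(50, 1, 0.5))
  expect_identical(fit_logistic(X, y, 0.1)$coefficients,
                   fit_logistic(X, y, 0.1)$coefficients)
  rf1 <- predict_model(fit_rf(X, y, 8, seed = 9), X)
  rf2 <- predict_model(fit_rf(X, y, 8, seed = 9), X)
  expect_identical(rf1, rf2)
})

test_that("single-gene comparator selects the informative gene", {
  set.seed(61)
  n <- 150
  signal <- rnorm(n)
  X <- cbind(g1 = rnorm(n), g2 = signal, g3 = rnorm(n))
  y <- factor(as.numeric(signal + 0.3 * rnorm(n) > 0))
  task <- task_spec("toy", "binary", "train", paste0("s", 1:n), labels = y)
  r <- nested_cv_run(X, task, "single-gene-LR", seed = 5)
  expect_true(all(r$folds$hyperparameter == 2))   # gene index of g2
  expect_gt(r$mean_metric, 0.85)

  # all-noise genes: outer AUC compatible with chance
  y_noise <- factor(rbinom(n, 1, 0.5))
  task2 <- task_spec("noise", "binary", "train", paste0("s", 1:n),
                     labels = y_noise)
  r2 <- nested_cv_run(X, task2, "single-gene-LR", seed = 5)
  expect_lt(abs(r2$mean_metric - 0.5), 0.15)
})
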