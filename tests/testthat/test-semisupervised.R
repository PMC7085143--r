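# hand-built linear autoencoder model for the loss-formula checks
manual_semisup <- function(p = 3, pi = 0.5, lambda_ae = 0, lambda_p = 0,
                           A = diag(p), B = diag(p), b = rep(0, p),
                           heads = list(t1 = list(w = rep(0, p), c = 0))) {
  structure(list(A = A, a = rep(0, ncol(A)), B = B, b = b, heads = heads,
                 pi = pi, lambda_ae = lambda_ae, lambda_p = lambda_p,
                 d = ncol(A), log = NULL, sampled_ids = character(0)),
            class = "semisup_model")
}

test_that("reconstruction loss is the elementwise squared error", {
  m <- manual_semisup()
  x <- matrix(c(1, -2, 0.5), 1, 3)
  expect_equal(as.numeric(reconstruction_loss(m, x)), c(0, 0, 0))
  m_off <- manual_semisup(b = rep(1, 3))       # AE(x) = x + 1
  expect_equal(as.numeric(reconstruction_loss(m_off, x)), c(1, 1, 1))
  expect_true(all(reconstruction_loss(m_off, matrix(rnorm(9), 3)) >= 0))
})

test_that("classification loss is the stated binary cross-entropy", {
  m <- manual_semisup()                        # zero head: P = 0.5 always
  x <- matrix(rnorm(3), 1, 3)
  expect_equal(classification_loss(m, x, 1, "t1"), log(2))
  expect_equal(classification_loss(m, x, 0, "t1"), log(2))
  # P -> 1 with l = 1: loss -> 0; P = 0.9 with l = 0: -log 0.1
  m_conf <- manual_semisup(heads = list(t1 = list(w = rep(0, 3), c = 40)))
  expect_lt(classification_loss(m_conf, x, 1, "t1"), 1e-10)
  m9 <- manual_semisup(heads = list(t1 = list(w = rep(0, 3),
                                              c = qlogis(0.9))))
  expect_equal(classification_loss(m9, x, 0, "t1"), -log(0.1),
               tolerance = 1e-10)
  expect_error(classification_loss(m, x, 1, "nope"), "unknown task")
})

test_that("the combined loss honors its limits and is linear in pi", {
  set.seed(23)
  xu <- matrix(rnorm(12), 4, 3)
  lab <- list(x = matrix(rnorm(6), 2, 3), l = c(1, 0),
              task = c("t1", "t1"))

  # pi = 0: head parameters do not enter the data term
  m0a <- manual_semisup(pi = 0)
  m0b <- manual_semisup(pi = 0,
                        heads = list(t1 = list(w = c(5, -5, 5), c = 2)))
  expect_equal(combined_loss(m0a, xu, lab), combined_loss(m0b, xu, lab))

  # pi = 1: reconstruction does not enter (decoder change is irrelevant)
  m1a <- manual_semisup(pi = 1)
  m1b <- manual_semisup(pi = 1, B = diag(3) * 9, b = rep(7, 3))
  expect_equal(combined_loss(m1a, xu, lab), combined_loss(m1b, xu, lab))
  expect_error(combined_loss(manual_semisup(pi = 0.5), xu, NULL),
               "labeled")

  # perfect reconstruction + certain heads + zero penalties: loss ~ 0
  m_perf <- manual_semisup(pi = 0.5,
                           heads = list(t1 = list(w = rep(0, 3), c = 40)))
  lab1 <- list(x = lab$x, l = c(1, 1), task = c("t1", "t1"))
  expect_lt(combined_loss(m_perf, xu, lab1), 1e-10)

  # linearity in pi for fixed parameters and batches
  ms <- lapply(c(0, 0.5, 1), function(pp)
    manual_semisup(pi = pp, lambda_ae = 0.01, lambda_p = 0.02,
                   B = diag(3) * 0.9,
                   heads = list(t1 = list(w = c(1, 0, -1), c = 0.3))))
  ls <- vapply(ms, combined_loss, numeric(1), unlabeled = xu,
               labeled = lab)
  expect_equal(ls[2], (ls[1] + ls[3]) / 2, tolerance = 1e-12)
})

test_that("divided halves are stratified, disjoint and exhaustive", {
  sim <- small_sim()
  split <- split_divided_tasks(sim$ds$tasks, threshold = 100, seed = 5)
  expect_equal(split$selected, sim$ds$tasks[[1]]$task_id)
  h <- split$halves[[1]]
  t <- sim$ds$tasks[[1]]
  expect_length(intersect(h$first, h$second), 0)
  expect_setequal(c(h$first, h$second), t$sample_ids)
  lab1 <- t$labels[match(h$first, t$sample_ids)]
  lab2 <- t$labels[match(h$second, t$sample_ids)]
  expect_lte(abs(sum(lab1 == "1") - sum(lab2 == "1")), 1)

  # below-threshold selection is empty
  expect_length(split_divided_tasks(sim$ds$tasks, threshold = 500)$selected,
                0)
})

test_that("pi = 0 training is a pure autoencoder", {
  fx <- semisup_fixture()
  spec <- train_spec(epochs = 3, learning_rate = 0.01, seed = 9)
  m_a <- train_semisup(fx$pool, fx$sim$ds$tasks, fx$split, pi = 0,
                       lambda_p = 0, d = 8, spec = spec)
  m_b <- train_semisup(fx$pool, fx$sim$ds$tasks, fx$split, pi = 0,
                       lambda_p = 0.1, d = 8, spec = spec)
  # lambda_p is inert at pi = 0 because heads stay at zero
  expect_equal(m_a$log$loss, m_b$log$loss)
  expect_true(all(vapply(m_a$heads, function(h) all(h$w == 0),
                         logical(1))))
  expect_lt(m_a$log$loss[nrow(m_a$log)], m_a$log$loss[1])
})

test_that("pi = 1 trains heads that predict the held-out halves", {
  fx <- semisup_fixture()
  spec <- train_spec(epochs = 30, learning_rate = 0.02, seed = 9)
  m <- train_semisup(fx$pool, fx$sim$ds$tasks, fx$split, pi = 1,
                     d = 8, spec = spec, batch_recon = 64,
                     batch_class = 32)
  t <- fx$sim$ds$tasks[[1]]
  h <- fx$split$halves[[1]]
  X2 <- fx$expr$values[match(h$second, rownames(fx$expr$values)), ]
  p2 <- phenobench:::head_prob(m, X2, t$task_id)
  l2 <- t$labels[match(h$second, t$sample_ids)]
  expect_gt(auc(p2, l2 == "1"), 0.85)
})

test_that("held-out halves are never sampled during training", {
  fx <- semisup_fixture()
  m <- train_semisup(fx$pool, fx$sim$ds$tasks, fx$split, pi = 0.1,
                     d = 8, spec = train_spec(epochs = 2, seed = 3))
  second <- unlist(lapply(fx$split$halves, `[[`, "second"))
  expect_length(intersect(m$sampled_ids, second), 0)
  # a pool containing second-half samples is rejected outright
  bad_ids <- c(rownames(fx$pool), fx$split$halves[[1]]$second[1])
  bad <- fx$expr$values[match(bad_ids, rownames(fx$expr$values)), ]
  expect_error(train_semisup(bad, fx$sim$ds$tasks, fx$split, pi = 0.1,
                             d = 8), "held-out")
})

test_that("the lambda sweep enumerates 16 pairs and picks the minimum", {
  fx <- semisup_fixture()
  sw <- sweep_lambdas(fx$pool, fx$expr$values, fx$sim$ds$tasks, fx$split,
                      pi = 0.5, d = 8,
                      spec = train_spec(epochs = 3, learning_rate = 0.02,
                                        seed = 2),
                      batch_recon = 64, batch_class = 32)
  expect_equal(nrow(sw$results), 16)
  grid <- expand.grid(lambda_ae = c(0, 0.1, 0.01, 0.001),
                      lambda_p = c(0, 0.1, 0.01, 0.001))
  expect_setequal(paste(sw$results$lambda_ae, sw$results$lambda_p),
                  paste(grid$lambda_ae, grid$lambda_p))
  expect_equal(min(sw$results$error),
               sw$results$error[sw$results$lambda_ae == sw$best$lambda_ae &
                                  sw$results$lambda_p == sw$best$lambda_p])
})

test_that("embedding evaluation matches the plain pipeline when identity", {
  fx <- semisup_fixture()
  t <- fx$sim$ds$tasks[[1]]
  feats <- fx$expr$values
  r_id <- evaluate_embedding(NULL, list(t), feats, learners = "LR",
                             seed = 11)
  rows <- match(t$sample_ids, rownames(feats))
  direct <- nested_cv_run(feats[rows, ], t, "LR",
                          plan = make_folds(t, K = 5,
                                            seed = phenobench:::derive_seed(
                                              11, t$task_id)),
                          seed = phenobench:::derive_seed(11, t$task_id,
                                                          "LR"))
  expect_equal(r_id[[1]]$mean_metric, direct$mean_metric)
})
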