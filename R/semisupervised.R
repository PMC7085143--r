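# Semi-supervised shared embedding: a linear single-hidden-layer autoencoder
# whose latent space feeds one binary logistic head per training task. The
# training loss is a convex combination (predictor strength pi) of the
# reconstruction and classification errors plus l2 penalties.

#' Select and halve the divided tasks
#'
#' Binary tasks in the train group with at least `threshold` samples are
#' selected; each is split into two stratified halves. The first halves join
#' the semi-supervised training pool, the second halves are held out for
#' within-task validation.
#'
#' @param tasks list of [task_spec()]s, or a task table like
#'   [benchmark_tasks()] (in which case only the selection is returned).
#' @param threshold minimum sample count, default 200 (inclusive).
#' @param seed RNG seed for the stratified halving.
#' @return object of class `divided_split` with `selected` (task ids) and,
#'   for task_spec input, `halves` (per task: `first` and `second` sample
#'   ids, disjoint and exhaustive).
#' @export
split_divided_tasks <- function(tasks, threshold = 200, seed = 1) {
  if (is.data.frame(tasks)) {
    sel <- tasks$task_type == "binary" & tasks$group == "train" &
      tasks$n_samples >= threshold
    return(structure(list(selected = tasks$task_id[sel], halves = NULL,
                          threshold = threshold),
                     class = "divided_split"))
  }
  keep <- vapply(tasks, function(t)
    t$task_type == "binary" && t$group == "train" &&
      length(t$sample_ids) >= threshold, logical(1))
  sel <- tasks[keep]
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  halves <- lapply(sel, function(t) {
    first <- logical(length(t$sample_ids))
    for (cl in levels(t$labels)) {
      idx <- which(t$labels == cl)
      idx <- idx[sample.int(length(idx))]
      first[idx[seq_len(ceiling(length(idx) / 2))]] <- TRUE
    }
    list(first = t$sample_ids[first], second = t$sample_ids[!first])
  })
  names(halves) <- vapply(sel, `[[`, "", "task_id")
  structure(list(selected = names(halves), halves = halves,
                 threshold = threshold),
            class = "divided_split")
}

new_semisup <- function(p, d, task_ids, pi, lambda_ae, lambda_p) {
  structure(list(
    A = matrix(stats::rnorm(p * d, 0, sqrt(1 / p)), p, d),
    a = numeric(d),
    B = matrix(stats::rnorm(d * p, 0, sqrt(1 / d)), d, p),
    b = numeric(p),
    heads = stats::setNames(lapply(task_ids, function(id)
      list(w = numeric(d), c = 0)), task_ids),
    pi = pi, lambda_ae = lambda_ae, lambda_p = lambda_p, d = d,
    log = NULL, sampled_ids = character(0)),
    class = "semisup_model")
}

#' @export
print.semisup_model <- function(x, ...) {
  cat(sprintf("semisup_model: %d -> %d, %d heads, pi = %g\n", nrow(x$A),
              x$d, length(x$heads), x$pi))
  invisible(x)
}

#' Latent encoding of the semi-supervised autoencoder
#'
#' @param model a `semisup_model`.
#' @param x feature matrix (or single vector).
#' @return latent matrix, samples x d.
#' @export
semisup_encode <- function(model, x) {
  x <- matrix(as.numeric(x), ncol = nrow(model$A))
  sweep(x %*% model$A, 2, model$a, "+")
}

semisup_decode <- function(model, z) {
  sweep(z %*% model$B, 2, model$b, "+")
}

#' Per-gene squared reconstruction error
#'
#' `R(x)_i = (AE(x)_i - x_i)^2` for the linear autoencoder.
#'
#' @param model a `semisup_model`.
#' @param x feature matrix or vector.
#' @return matrix (samples x genes) of squared errors.
#' @export
reconstruction_loss <- function(model, x) {
  x <- matrix(as.numeric(x), ncol = nrow(model$A))
  (semisup_decode(model, semisup_encode(model, x)) - x)^2
}

sigmoid <- function(x) 1 / (1 + exp(-x))

head_prob <- function(model, x, task) {
  h <- model$heads[[task]]
  if (is.null(h)) stop("unknown task: ", task)
  z <- semisup_encode(model, x)
  as.numeric(sigmoid(z %*% h$w + h$c))
}

#' Binary cross-entropy of a task head
#'
#' `-log(P_j(x) l_x + (1 - P_j(x))(1 - l_x))` where `P_j` is task j's
#' logistic head on the latent encoding of `x`.
#'
#' @param model a `semisup_model`.
#' @param x feature matrix or vector.
#' @param l_x 0/1 labels.
#' @param task task id of the head.
#' @return numeric vector of losses.
#' @export
classification_loss <- function(model, x, l_x, task) {
  stopifnot(all(l_x %in% c(0, 1)))
  p <- head_prob(model, x, task)
  -log(pmax(p * l_x + (1 - p) * (1 - l_x), 1e-300))
}

#' The combined semi-supervised training loss
#'
#' `(1 - pi)/BR * sum_m R(x_m) + pi/BC * sum_n C(x_n, l_n) +
#' lambda_AE * l2(AE) + lambda_P * sum_j l2(P_j)`, with the reconstruction
#' error summed over genes per sample. Linear in pi for fixed batches.
#'
#' @param model a `semisup_model`.
#' @param unlabeled matrix of BR expression vectors (reconstruction batch).
#' @param labeled list with `x` (BC x p matrix), `l` (0/1 labels) and
#'   `task` (head id per row); may be NULL when `pi = 0`.
#' @return scalar loss.
#' @export
combined_loss <- function(model, unlabeled, labeled = NULL) {
  pi <- model$pi
  if (pi > 0 && (is.null(labeled) || nrow(labeled$x) == 0))
    stop("pi > 0 requires labeled data")
  loss <- 0
  if (pi < 1) {
    R <- reconstruction_loss(model, unlabeled)
    loss <- loss + (1 - pi) / nrow(R) * sum(R)
  }
  if (pi > 0) {
    C <- vapply(seq_len(nrow(labeled$x)), function(n)
      classification_loss(model, labeled$x[n, , drop = FALSE],
                          labeled$l[n], labeled$task[n]),
      numeric(1))
    loss <- loss + pi / length(C) * sum(C)
  }
  loss + model$lambda_ae * (sum(model$A^2) + sum(model$B^2)) +
    model$lambda_p * sum(vapply(model$heads, function(h) sum(h$w^2),
                                numeric(1)))
}

#' Train the semi-supervised shared-embedding model
#'
#' Stochastic gradient descent on [combined_loss()]. Reconstruction batches
#' are drawn from the whole training pool (unlabeled samples plus the first
#' halves of the divided tasks); labeled batches are drawn uniformly from
#' the union of the first halves, each sample routed to its own task's
#' head. Second halves must not be part of `features`; every id the sampler
#' touches is recorded in the returned model for auditing.
#'
#' @param features training-pool matrix with sample ids as rownames.
#' @param tasks list of [task_spec()]s covering the divided tasks.
#' @param split a `divided_split` from [split_divided_tasks()].
#' @param pi predictor strength in \[0, 1\].
#' @param lambda_ae,lambda_p l2 penalties on autoencoder and head weights.
#' @param d latent dimension.
#' @param spec a [train_spec()] (epochs, learning rate, momentum, seed).
#' @param batch_recon,batch_class batch sizes BR and BC.
#' @param clip global gradient-norm cap per step; the per-sample
#'   reconstruction loss is summed over genes, so raw gradients scale with
#'   the gene count and clipping keeps a single learning rate usable across
#'   feature spaces.
#' @return a trained `semisup_model` with per-epoch loss log.
#' @export
train_semisup <- function(features, tasks, split, pi, lambda_ae = 0,
                          lambda_p = 0, d = 32, spec = train_spec(),
                          batch_recon = 256, batch_class = 64, clip = 10) {
  stopifnot(pi >= 0, pi <= 1)
  X <- as_features(features)
  if (is.null(rownames(X))) stop("features must carry sample ids as rownames")
  p <- ncol(X)

  # labeled pool: first halves only, labels as 0/1 (second level = 1)
  lab_ids <- character(0); lab_l <- numeric(0); lab_task <- character(0)
  task_map <- stats::setNames(tasks, vapply(tasks, `[[`, "", "task_id"))
  for (id in split$selected) {
    t <- task_map[[id]]
    if (is.null(t)) next
    first <- split$halves[[id]]$first
    pos <- levels(t$labels)[2]
    l <- as.numeric(t$labels[match(first, t$sample_ids)] == pos)
    lab_ids <- c(lab_ids, first)
    lab_l <- c(lab_l, l)
    lab_task <- c(lab_task, rep(id, length(first)))
  }
  second <- unlist(lapply(split$halves, `[[`, "second"))
  if (any(second %in% rownames(X)))
    stop("held-out second halves must not be in the training pool")
  if (pi > 0 && length(lab_ids) == 0)
    stop("pi > 0 requires labeled data")
  lab_rows <- match(lab_ids, rownames(X))
  if (anyNA(lab_rows)) stop("labeled first-half samples missing from pool")

  old <- local_rng_seed(spec$seed)
  on.exit(restore_rng(old))
  model <- new_semisup(p, d, split$selected, pi, lambda_ae, lambda_p)
  vel <- list(A = model$A * 0, a = model$a * 0, B = model$B * 0,
              b = model$b * 0,
              heads = lapply(model$heads, function(h)
                list(w = h$w * 0, c = 0)))
  n <- nrow(X)
  steps <- ceiling(n / batch_recon)
  lr <- spec$learning_rate; mom <- spec$momentum
  sampled <- character(0)
  log <- NULL

  for (ep in seq_len(spec$epochs)) {
    perm <- sample.int(n)
    ep_loss <- 0
    for (s in seq_len(steps)) {
      ridx <- perm[((s - 1) * batch_recon + 1):min(s * batch_recon, n)]
      gA <- model$A * 0; ga <- model$a * 0
      gB <- model$B * 0; gb <- model$b * 0
      loss <- 0

      if (pi < 1) {
        Xu <- X[ridx, , drop = FALSE]
        BR <- nrow(Xu)
        Z <- semisup_encode(model, Xu)
        E <- semisup_decode(model, Z) - Xu
        loss <- loss + (1 - pi) / BR * sum(E^2)
        dXhat <- 2 * (1 - pi) / BR * E
        gB <- gB + crossprod(Z, dXhat)
        gb <- gb + colSums(dXhat)
        dZ <- dXhat %*% t(model$B)
        gA <- gA + crossprod(Xu, dZ)
        ga <- ga + colSums(dZ)
        sampled <- union(sampled, rownames(X)[ridx])
      }

      ghead <- lapply(model$heads, function(h) list(w = h$w * 0, c = 0))
      if (pi > 0) {
        pick <- sample(seq_along(lab_rows), batch_class, replace = TRUE)
        Xl <- X[lab_rows[pick], , drop = FALSE]
        BC <- nrow(Xl)
        Zl <- semisup_encode(model, Xl)
        dZl <- Zl * 0
        for (id in unique(lab_task[pick])) {
          rows <- which(lab_task[pick] == id)
          h <- model$heads[[id]]
          pr <- sigmoid(as.numeric(Zl[rows, , drop = FALSE] %*% h$w + h$c))
          l <- lab_l[pick][rows]
          loss <- loss + pi / BC *
            sum(-log(pmax(pr * l + (1 - pr) * (1 - l), 1e-300)))
          dlogit <- pi / BC * (pr - l)
          ghead[[id]]$w <- ghead[[id]]$w +
            as.numeric(crossprod(Zl[rows, , drop = FALSE], dlogit))
          ghead[[id]]$c <- ghead[[id]]$c + sum(dlogit)
          dZl[rows, ] <- dZl[rows, ] + outer(dlogit, h$w)
        }
        gA <- gA + crossprod(Xl, dZl)
        ga <- ga + colSums(dZl)
        sampled <- union(sampled, rownames(X)[lab_rows[pick]])
      }

      gA <- gA + 2 * lambda_ae * model$A
      gB <- gB + 2 * lambda_ae * model$B
      gnorm <- sqrt(sum(gA^2) + sum(ga^2) + sum(gB^2) + sum(gb^2) +
                      sum(vapply(ghead, function(h)
                        sum(h$w^2) + h$c^2, numeric(1))))
      if (is.finite(clip) && gnorm > clip) {
        sc <- clip / gnorm
        gA <- gA * sc; ga <- ga * sc; gB <- gB * sc; gb <- gb * sc
        ghead <- lapply(ghead, function(h)
          list(w = h$w * sc, c = h$c * sc))
      }
      loss <- loss + lambda_ae * (sum(model$A^2) + sum(model$B^2)) +
        lambda_p * sum(vapply(model$heads, function(h) sum(h$w^2),
                              numeric(1)))

      vel$A <- mom * vel$A - lr * gA; model$A <- model$A + vel$A
      vel$a <- mom * vel$a - lr * ga; model$a <- model$a + vel$a
      vel$B <- mom * vel$B - lr * gB; model$B <- model$B + vel$B
      vel$b <- mom * vel$b - lr * gb; model$b <- model$b + vel$b
      for (id in names(model$heads)) {
        gw <- ghead[[id]]$w + 2 * lambda_p * model$heads[[id]]$w
        vel$heads[[id]]$w <- mom * vel$heads[[id]]$w - lr * gw
        vel$heads[[id]]$c <- mom * vel$heads[[id]]$c - lr * ghead[[id]]$c
        model$heads[[id]]$w <- model$heads[[id]]$w + vel$heads[[id]]$w
        model$heads[[id]]$c <- model$heads[[id]]$c + vel$heads[[id]]$c
      }
      if (!is.finite(loss))
        stop("semi-supervised training diverged (non-finite loss)")
      ep_loss <- ep_loss + loss
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / steps))
  }
  model$log <- log
  model$sampled_ids <- sampled
  model
}

#' Sweep the l2 penalty pairs of the semi-supervised model
#'
#' Trains one model per pair in \{0, 0.1, 0.01, 0.001\}^2 (16 pairs) and
#' selects the pair minimizing the average error, defined as one minus the
#' mean AUC of logistic classifiers fit on the first-half latent encodings
#' and evaluated on the held-out second halves of the divided tasks.
#'
#' @inheritParams train_semisup
#' @param heldout_features matrix holding (at least) the second-half
#'   samples, rownames = sample ids.
#' @return list with `best` (the selected pair), `results` (all 16 rows of
#'   lambda_ae, lambda_p, error) and `models`.
#' @export
sweep_lambdas <- function(features, heldout_features, tasks, split, pi,
                          d = 32, spec = train_spec(),
                          batch_recon = 256, batch_class = 64) {
  grid <- expand.grid(lambda_ae = c(0, 0.1, 0.01, 0.001),
                      lambda_p = c(0, 0.1, 0.01, 0.001))
  models <- vector("list", nrow(grid))
  err <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    m <- train_semisup(features, tasks, split, pi,
                       lambda_ae = grid$lambda_ae[g],
                       lambda_p = grid$lambda_p[g], d = d, spec = spec,
                       batch_recon = batch_recon,
                       batch_class = batch_class)
    models[[g]] <- m
    err[g] <- 1 - mean(vapply(split$selected, function(id)
      heldout_half_auc(m, features, heldout_features,
                       tasks[[which(vapply(tasks, `[[`, "", "task_id") ==
                                      id)]], split), numeric(1)))
  }
  results <- cbind(grid, error = err)
  best <- which.min(err)                 # ties: first pair in grid order
  list(best = grid[best, ], results = results, models = models,
       best_model = models[[best]])
}

# AUC on the held-out second half of one divided task: logistic classifier
# fit on the first-half latent encodings
heldout_half_auc <- function(model, features, heldout_features, task,
                             split) {
  h <- split$halves[[task$task_id]]
  pos <- levels(task$labels)[2]
  Z1 <- semisup_encode(model, as_features(features)[h$first, , drop = FALSE])
  Z2 <- semisup_encode(model,
                       as_features(heldout_features)[h$second, ,
                                                     drop = FALSE])
  l1 <- task$labels[match(h$first, task$sample_ids)]
  l2 <- task$labels[match(h$second, task$sample_ids)]
  clf <- fit_logistic(Z1, l1, 1e-3, maxit = 200, tol = 1e-5)
  auc(predict_model(clf, Z2)[, pos], l2 == pos)
}

#' Evaluate a learned embedding on downstream tasks
#'
#' Encodes each task's features through the model's latent map (or leaves
#' them unembedded when `model` is NULL) and runs the standard nested
#' cross-validation for each learner kind.
#'
#' @param model a `semisup_model`, an `embedder`, or NULL (no embedding).
#' @param tasks list of [task_spec()]s to evaluate.
#' @param features matrix with rownames covering every task sample.
#' @param learners learner kinds, default the three classifiers.
#' @param K,seed nested-CV settings.
#' @param config extra descriptor fields carried into each result.
#' @return list of `cv_result` objects.
#' @export
evaluate_embedding <- function(model, tasks, features,
                               learners = c("LR", "RF", "kNN"), K = 5,
                               seed = 1, config = list()) {
  X <- as_features(features)
  out <- list()
  for (t in tasks) {
    rows <- match(t$sample_ids, rownames(X))
    if (anyNA(rows)) stop("task samples missing from features: ", t$task_id)
    feat <- X[rows, , drop = FALSE]
    if (inherits(model, "semisup_model"))
      feat <- semisup_encode(model, feat)
    else if (inherits(model, "embedder")) feat <- encode(model, feat)
    plan <- make_folds(t, K = K, seed = derive_seed(seed, t$task_id))
    for (l in learners) {
      out[[paste(t$task_id, l, sep = ".")]] <-
        nested_cv_run(feat, t, l, plan = plan,
                      seed = derive_seed(seed, t$task_id, l),
                      config = config)
    }
  }
  out
}
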