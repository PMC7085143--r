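# Nested cross-validation: the inner loop selects a hyperparameter, the
# outer loop estimates generalization. K(KN+1) model fits per configuration.

#' Model-fit count of nested cross-validation
#'
#' With K folds in both loops and N hyperparameter values, nested
#' cross-validation trains `K * (K * N + 1)` individual models: K inner-fold
#' fits per value per outer fold, plus one refit per outer fold.
#'
#' @param K fold count (>= 2).
#' @param N hyperparameter grid size (>= 1).
#' @return integer model count.
#' @export
count_models <- function(K, N) {
  stopifnot(K >= 2, N >= 1)
  K * (K * N + 1)
}

# cyclic stratified assignment; carries the offset across strata so global
# fold sizes differ by at most one
stratified_assign <- function(strata, K) {
  assign <- integer(length(strata))
  offset <- 0L
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- ((seq_along(idx) - 1L + offset) %% K) + 1L
    offset <- offset + length(idx)
  }
  assign
}

#' Build a stratified nested fold plan
#'
#' Outer folds partition the task samples (sizes differing by at most one);
#' for each outer fold, inner folds partition the remaining samples with the
#' same K. Classification tasks are stratified by class, survival tasks by
#' the event indicator, so no fold degenerates to a single class. Set
#' `stratify = FALSE` for plain random folds.
#'
#' @param task a [task_spec()].
#' @param K fold count, used for both loops (default 5).
#' @param seed RNG seed; the same seed reproduces the same plan.
#' @param stratify stratify folds by class / event indicator.
#' @return object of class `fold_plan` with elements `outer` (fold index per
#'   sample) and `inner` (per outer fold, fold index per outer-training
#'   sample).
#' @export
make_folds <- function(task, K = 5, seed = 1, stratify = TRUE) {
  n <- length(task$sample_ids)
  if (n < 2 * K) stop("need at least 2K samples for K-fold nesting")
  key <- if (!stratify) rep(1L, n) else if (task$task_type == "survival")
    as.integer(task$event) else as.integer(task$labels)
  if (stratify && any(table(key) < K))
    stop("a stratum has fewer than K samples; use a smaller K")
  old <- local_rng_seed(seed)
  on.exit(restore_rng(old))
  outer <- stratified_assign(key, K)
  inner <- lapply(seq_len(K), function(k) {
    tr <- which(outer != k)
    stratified_assign(key[tr], K)
  })
  structure(list(outer = outer, inner = inner, K = K, seed = seed,
                 stratify = stratify),
            class = "fold_plan")
}

# deterministic sub-seed derivation for independent RNG streams
derive_seed <- function(seed, ...) {
  lab <- paste(c(...), collapse = "/")
  h <- sum(utf8ToInt(lab) * seq_along(utf8ToInt(lab)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

local_rng_seed <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# conservative preference used to break selection ties: stronger
# regularization first (larger penalty, smaller depth, larger k)
conservative_order <- function(kind, grid) {
  switch(kind,
         LR = ,
         CoxPH = order(grid, decreasing = TRUE),
         RF = order(grid),
         kNN = order(grid, decreasing = TRUE),
         seq_along(grid))               # single-gene: stable gene order
}

fit_learner <- function(kind, X, task, idx, hyper, seed,
                        maxit = 300, tol = 1e-5) {
  Xs <- X[idx, , drop = FALSE]
  switch(kind,
    LR = fit_logistic(Xs, task$labels[idx], hyper, maxit = maxit, tol = tol),
    RF = fit_rf(Xs, task$labels[idx], hyper, seed = seed),
    kNN = fit_knn(Xs, task$labels[idx], hyper),
    CoxPH = fit_cox_efron(Xs, task$time[idx], task$event[idx], hyper,
                          maxit = maxit, tol = tol),
    `single-gene-LR` = {
      m <- fit_logistic(Xs[, hyper, drop = FALSE], task$labels[idx], 0,
                        maxit = maxit, tol = tol)
      m$kind <- "single-gene-LR"; m$gene <- hyper; m
    },
    `single-gene-Cox` = {
      m <- fit_cox_efron(Xs[, hyper, drop = FALSE], task$time[idx],
                         task$event[idx], 0, maxit = maxit, tol = tol)
      m$kind <- "single-gene-Cox"; m$gene <- hyper; m
    },
    stop("unknown learner kind: ", kind))
}

score_learner <- function(kind, model, X, idx) {
  Xs <- X[idx, , drop = FALSE]
  if (startsWith(kind, "single-gene"))
    Xs <- Xs[, model$gene, drop = FALSE]
  predict_model(model, Xs)
}

eval_metric <- function(task, pred, idx) {
  switch(task$task_type,
    binary = {
      pos <- levels(task$labels)[2]
      auc(pred[, pos], task$labels[idx] == pos)
    },
    multiclass = {
      cls <- colnames(pred)[max.col(pred, ties.method = "first")]
      accuracy(cls, task$labels[idx])
    },
    survival = concordance_index(pred, task$time[idx], task$event[idx]))
}

#' Run nested cross-validation for one task / representation / learner cell
#'
#' For each outer fold: every grid value is evaluated by K-fold
#' cross-validation inside the outer-training data, the value with the best
#' mean inner metric is selected (ties broken toward the stronger
#' regularization), the model is refit on the full outer-training data, and
#' evaluated on the held-out fold. The metric is AUC for binary tasks,
#' accuracy for multiclass, C-index for survival. The result carries an
#' audit of the model-fit count and of every sample id used in training.
#'
#' @param features numeric matrix aligned to `task$sample_ids` (one row per
#'   task sample), already normalized / embedded.
#' @param task a [task_spec()].
#' @param learner `"LR"`, `"RF"`, `"kNN"`, `"CoxPH"`, `"single-gene-LR"` or
#'   `"single-gene-Cox"` (the single-gene kinds treat the gene index as the
#'   hyperparameter).
#' @param grid hyperparameter values; defaults to [hyper_grid()] for the
#'   standard kinds and all genes for single-gene kinds.
#' @param plan a [make_folds()] plan; built from `seed` when omitted.
#' @param seed RNG seed (fold plan and forest seeds).
#' @param maxit,tol passed to the first-order fitters.
#' @param config optional named list describing the representation
#'   (gene set, normalization, embedder), carried into the result.
#' @return object of class `cv_result`: per-fold chosen hyperparameter and
#'   metric, their mean, the K outer refits, and the audit.
#' @export
nested_cv_run <- function(features, task, learner, grid = NULL, plan = NULL,
                          seed = 1, maxit = 300, tol = 1e-5,
                          config = list()) {
  features <- as.matrix(features)
  n <- length(task$sample_ids)
  stopifnot(nrow(features) == n)
  if (is.null(grid))
    grid <- if (startsWith(learner, "single-gene"))
      seq_len(ncol(features)) else hyper_grid(learner)
  if (length(grid) == 0) stop("empty hyperparameter grid")
  if (is.null(plan)) plan <- make_folds(task, seed = seed)
  K <- plan$K
  pref <- conservative_order(learner, grid)

  n_fits <- 0L
  folds <- vector("list", K)
  models <- vector("list", K)
  trained_ids <- vector("list", K)

  for (k in seq_len(K)) {
    test_idx <- which(plan$outer == k)
    train_idx <- which(plan$outer != k)
    inner <- plan$inner[[k]]
    used <- integer(0)

    inner_mean <- vapply(seq_along(grid), function(g) {
      ms <- vapply(seq_len(K), function(j) {
        fit_idx <- train_idx[inner != j]
        val_idx <- train_idx[inner == j]
        m <- fit_learner(learner, features, task, fit_idx, grid[g],
                         seed = derive_seed(seed, "inner", k, j, g),
                         maxit = maxit, tol = tol)
        n_fits <<- n_fits + 1L
        used <<- union(used, fit_idx)
        eval_metric(task, score_learner(learner, m, features, val_idx),
                    val_idx)
      }, numeric(1))
      mean(ms)
    }, numeric(1))

    best <- max(inner_mean)
    chosen <- pref[which(inner_mean[pref] == best)[1]]
    refit <- fit_learner(learner, features, task, train_idx, grid[chosen],
                         seed = derive_seed(seed, "refit", k),
                         maxit = maxit, tol = tol)
    n_fits <- n_fits + 1L
    used <- union(used, train_idx)
    metric <- eval_metric(task,
                          score_learner(learner, refit, features, test_idx),
                          test_idx)
    folds[[k]] <- data.frame(fold = k, hyperparameter = grid[chosen],
                             metric = metric)
    models[[k]] <- refit
    trained_ids[[k]] <- task$sample_ids[used]
  }

  folds <- do.call(rbind, folds)
  structure(list(task_id = task$task_id, config = config, learner = learner,
                 folds = folds, mean_metric = mean(folds$metric),
                 models = models,
                 audit = list(n_fits = n_fits,
                              expected_fits = count_models(K, length(grid)),
                              trained_ids = trained_ids,
                              heldout_ids = lapply(seq_len(K), function(k)
                                task$sample_ids[plan$outer == k]))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result %s [%s]: mean metric %.4f over %d folds (%d fits)\n",
              x$task_id, x$learner, x$mean_metric, nrow(x$folds),
              x$audit$n_fits))
  invisible(x)
}

#' Flatten cv_result objects into a records table
#'
#' @param results list of `cv_result` objects.
#' @param n_samples optional named vector of task sample counts used as
#'   aggregation weights.
#' @return data.frame with one row per result (task, config descriptor,
#'   learner, mean metric) suitable for [shift_by_task_median()].
#' @export
cv_records <- function(results, n_samples = NULL) {
  out <- do.call(rbind, lapply(results, function(r) {
    cfg <- r$config
    data.frame(task_id = r$task_id,
               gene_set = cfg$gene_set %||% NA_character_,
               normalization = cfg$normalization %||% NA_character_,
               embedder = cfg$embedder %||% NA_character_,
               learner = r$learner,
               value = r$mean_metric,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(n_samples)) out$n_samples <- n_samples[out$task_id]
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
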