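#' Hyperparameter grids of the benchmarking design
#'
#' LR and Cox: 10 l2 penalties logarithmically spaced over \[1e-6, 1e3\].
#' RF: 7 maximum depths logarithmically spaced over \[2, 128\]. kNN:
#' k in \{1, 3, 5, 7, 9\}.
#'
#' @param kind one of `"LR"`, `"RF"`, `"kNN"`, `"CoxPH"`.
#' @return numeric vector of hyperparameter values.
#' @export
hyper_grid <- function(kind = c("LR", "RF", "kNN", "CoxPH")) {
  kind <- match.arg(kind)
  switch(kind,
         LR = ,
         CoxPH = 10^seq(-6, 3, length.out = 10),
         RF = 2^seq(1, 7, length.out = 7),
         kNN = c(1, 3, 5, 7, 9))
}

new_model <- function(kind, hyper, fit, coefficients = NULL,
                      classes = NULL) {
  structure(list(kind = kind, hyper = hyper, fit = fit,
                 coefficients = coefficients, classes = classes),
            class = "phenobench_model")
}

#' @export
print.phenobench_model <- function(x, ...) {
  cat(sprintf("phenobench_model [%s], hyperparameter = %s\n", x$kind,
              format(x$hyper)))
  invisible(x)
}

#' Fit an l2-regularized multinomial logistic regression
#'
#' A single-layer softmax model minimizing mean cross-entropy plus
#' `l2_penalty * ||W||^2` (intercepts unpenalized) by accelerated first-order
#' descent with backtracking line search, so it remains usable at p >> n.
#' The fit is deterministic: full-batch gradients from a zero start.
#'
#' @param X numeric feature matrix, samples x features.
#' @param y factor (or coercible) of class labels; at least 2 observed
#'   classes.
#' @param l2_penalty nonnegative l2 penalty on the weights.
#' @param maxit,tol iteration cap and gradient infinity-norm tolerance.
#' @return a `phenobench_model` of kind `"LR"` with a p x K coefficient
#'   matrix.
#' @export
fit_logistic <- function(X, y, l2_penalty, maxit = 500, tol = 1e-6) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (nlevels(y) < 2) stop("y must contain at least 2 classes")
  if (l2_penalty < 0) stop("l2 penalty must be nonnegative")
  K <- nlevels(y)
  res <- cpp_logistic_fit(X, as.integer(y) - 1L, K, l2_penalty,
                          as.integer(maxit), tol)
  p <- ncol(X)
  W <- matrix(res$theta[seq_len(p * K)], p, K)
  b <- res$theta[p * K + seq_len(K)]
  rownames(W) <- colnames(X)
  colnames(W) <- levels(y)
  new_model("LR", l2_penalty,
            fit = list(W = W, b = b, trace = res$trace,
                       iterations = res$iterations),
            coefficients = W, classes = levels(y))
}

#' Fit a 100-tree random forest at a fixed maximum depth
#'
#' @param X feature matrix; `y` factor of labels.
#' @param y class labels.
#' @param max_depth maximum tree depth (>= 1).
#' @param seed RNG seed making the forest reproducible.
#' @return a `phenobench_model` of kind `"RF"`.
#' @export
fit_rf <- function(X, y, max_depth, seed = 1) {
  if (max_depth < 1) stop("max_depth must be >= 1")
  X <- as.data.frame(as.matrix(X))
  names(X) <- paste0("f", seq_along(X))
  y <- droplevels(as.factor(y))
  rf <- ranger::ranger(x = X, y = y, num.trees = 100,
                       max.depth = as.integer(max_depth),
                       probability = TRUE, seed = seed,
                       num.threads = 1)
  new_model("RF", max_depth, fit = rf, classes = levels(y))
}

#' Fit a k-nearest-neighbor classifier
#'
#' Majority vote over the k nearest training samples in Euclidean distance.
#'
#' @param X feature matrix; `y` factor of labels.
#' @param y class labels.
#' @param k neighbor count, at most the number of training samples.
#' @return a `phenobench_model` of kind `"kNN"` (stores the training set).
#' @export
fit_knn <- function(X, y, k) {
  X <- as.matrix(X)
  y <- droplevels(as.factor(y))
  if (k > nrow(X)) stop("k exceeds the number of training samples")
  new_model("kNN", k, fit = list(X = X, y = y), classes = levels(y))
}

#' Efron-corrected Cox partial log-likelihood
#'
#' Returns the negative log pseudolikelihood and its exact gradient at
#' `beta`. Tied event times are handled by the Efron correction, which
#' distributes the tied subjects' risk-set contribution evenly; with no ties
#' the value equals the standard Cox partial likelihood.
#'
#' @param beta coefficient vector.
#' @param X feature matrix, samples x features.
#' @param times positive follow-up times.
#' @param events 0/1 event indicators; at least one event required.
#' @return list with `value` (negative log pseudolikelihood) and `gradient`.
#' @export
efron_pseudolikelihood <- function(beta, X, times, events) {
  X <- as.matrix(X)
  if (sum(events) < 1) stop("at least one event is required")
  res <- cpp_efron_neglik(X, as.numeric(times), as.numeric(events),
                          as.numeric(beta))
  n <- nrow(X)
  list(value = res$value * n, gradient = as.numeric(res$gradient) * n)
}

#' Fit an l2-regularized Cox model via the Efron pseudolikelihood
#'
#' Minimizes the mean negative Efron pseudolikelihood plus
#' `l2_penalty * ||beta||^2` by accelerated first-order descent with
#' backtracking line search; no Hessian is ever formed, so the fit handles
#' p >> n. Risk scores are `X %*% beta`.
#'
#' @param X feature matrix.
#' @param times,events survival times and 0/1 event indicators.
#' @param l2_penalty nonnegative l2 penalty.
#' @param maxit,tol iteration cap and gradient infinity-norm tolerance.
#' @return a `phenobench_model` of kind `"CoxPH"`.
#' @export
fit_cox_efron <- function(X, times, events, l2_penalty, maxit = 500,
                          tol = 1e-6) {
  X <- as.matrix(X)
  if (sum(events) < 1) stop("at least one event is required")
  if (l2_penalty < 0) stop("l2 penalty must be nonnegative")
  res <- cpp_cox_fit(X, as.numeric(times), as.numeric(events), l2_penalty,
                     as.integer(maxit), tol)
  beta <- as.numeric(res$theta)
  names(beta) <- colnames(X)
  new_model("CoxPH", l2_penalty,
            fit = list(beta = beta, trace = res$trace,
                       iterations = res$iterations),
            coefficients = beta)
}

#' Predict scores from a fitted model
#'
#' LR and RF return class-probability matrices; kNN returns vote-fraction
#' probabilities; CoxPH returns the linear risk score.
#'
#' @param model a `phenobench_model`.
#' @param X feature matrix.
#' @return probability matrix (classification) or numeric risk vector
#'   (survival).
#' @export
predict_model <- function(model, X) {
  X <- as.matrix(X)
  kind <- switch(model$kind, `single-gene-LR` = "LR",
                 `single-gene-Cox` = "CoxPH", model$kind)
  switch(kind,
    LR = {
      eta <- sweep(X %*% model$fit$W, 2, model$fit$b, "+")
      eta <- sweep(eta, 1, apply(eta, 1, max), "-")
      p <- exp(eta)
      p / rowSums(p)
    },
    RF = {
      Xd <- as.data.frame(X)
      names(Xd) <- paste0("f", seq_along(Xd))
      stats::predict(model$fit, data = Xd, num.threads = 1)$predictions
    },
    kNN = {
      pred <- class::knn(model$fit$X, X, model$fit$y, k = model$hyper,
                         prob = TRUE, use.all = TRUE)
      win <- attr(pred, "prob")
      out <- matrix(0, nrow(X), length(model$classes),
                    dimnames = list(NULL, model$classes))
      for (i in seq_len(nrow(X))) {
        out[i, as.character(pred[i])] <- win[i]
        rest <- setdiff(model$classes, as.character(pred[i]))
        out[i, rest] <- (1 - win[i]) / length(rest)
      }
      out
    },
    CoxPH = as.numeric(X %*% model$fit$beta),
    stop("unknown model kind: ", model$kind))
}
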