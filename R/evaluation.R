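#' Area under the ROC curve
#'
#' Mann-Whitney rank formulation with midrank tie handling: the fraction of
#' (positive, negative) pairs in which the positive sample receives the
#' higher score, ties counting one half.
#'
#' @param scores numeric scores, larger = more likely positive.
#' @param labels 0/1, logical, or two-level factor; the second level (or 1 /
#'   TRUE) is the positive class.
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores)                       # midranks for ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification accuracy
#'
#' @param predicted,labels aligned vectors of class labels.
#' @return fraction of exact matches.
#' @export
accuracy <- function(predicted, labels) {
  stopifnot(length(predicted) == length(labels))
  mean(as.character(predicted) == as.character(labels))
}

#' Harrell's concordance index
#'
#' Over all pairs whose ordering is determined (the earlier time belongs to
#' an event, or both are events with distinct times), the fraction in which
#' the higher risk score is assigned to the earlier failure; tied risk
#' scores count one half. Invariant under strictly monotone transforms of
#' the risk scores.
#'
#' @param risk numeric risk scores, larger = earlier expected failure.
#' @param time positive follow-up times.
#' @param event 0/1 event indicator (0 = censored).
#' @return C-index in \[0, 1\].
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  stopifnot(length(time) == n, length(event) == n)
  num <- 0
  den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    # subject i failed at time[i]; comparable with anyone observed longer
    comp <- time > time[i] | (time == time[i] & event == 0)
    den <- den + sum(comp)
    num <- num + sum(risk[i] > risk[comp]) + 0.5 * sum(risk[i] == risk[comp])
  }
  if (den == 0) stop("no comparable pair to compute a concordance index")
  num / den
}

#' Shift metrics by the per-task median
#'
#' Removes between-task variance before aggregation by subtracting, from
#' every record, the median metric of all records on the same task. Negative
#' shifted values mean the configuration underperformed the task median.
#'
#' @param records data.frame with at least columns `task_id` and `value`.
#' @return the input with an added `shifted` column.
#' @export
shift_by_task_median <- function(records) {
  stopifnot(all(c("task_id", "value") %in% names(records)))
  med <- stats::ave(records$value, records$task_id, FUN = stats::median)
  records$shifted <- records$value - med
  records
}

#' Sample-weighted average of shifted scores
#'
#' @param shifted numeric shifted metrics.
#' @param weights positive weights, normally the task sample counts, damping
#'   fluctuations from small tasks.
#' @return weighted mean.
#' @export
weighted_average <- function(shifted, weights) {
  if (length(shifted) == 0) stop("empty input")
  stopifnot(length(weights) == length(shifted))
  if (any(weights <= 0)) stop("weights must be positive")
  sum(weights * shifted) / sum(weights)
}

#' Coefficient-rank feature importance
#'
#' For each of the K outer-fold linear models, genes are ranked by the
#' magnitude of their regression coefficient (rank 1 = largest), the rank is
#' divided by the number of genes, and the normalized ranks are averaged
#' across folds. For multiclass models the largest coefficient magnitude
#' across classes represents the gene. Ties are broken by gene order, so the
#' result is deterministic.
#'
#' @param models list of fitted linear models (kind `"LR"` or `"CoxPH"`), one
#'   per outer fold, with aligned gene order.
#' @param signed rank signed coefficients instead of magnitudes.
#' @return data.frame with `gene` and `mean_normalized_rank` in (0, 1\].
#' @export
feature_importance <- function(models, signed = FALSE) {
  coefs <- lapply(models, function(m) {
    if (!inherits(m, "phenobench_model") || !m$kind %in% c("LR", "CoxPH"))
      stop("feature importance requires linear models (LR or CoxPH)")
    b <- m$coefficients
    if (is.matrix(b)) apply(abs(b), 1, max) else b
  })
  p <- length(coefs[[1]])
  ranks <- vapply(coefs, function(b) {
    key <- if (signed) b else abs(b)
    # rank 1 = largest; ties broken by gene order
    rank(-key, ties.method = "first") / p
  }, numeric(p))
  genes <- names(coefs[[1]])
  if (is.null(genes)) genes <- paste0("g", seq_len(p))
  data.frame(gene = genes, mean_normalized_rank = rowMeans(ranks),
             stringsAsFactors = FALSE)
}
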