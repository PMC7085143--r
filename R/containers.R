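#' Construct a count matrix container
#'
#' The universal input of the pipeline: gene-level read counts for a set of
#' samples, together with the gene lengths needed for TPM normalization.
#'
#' @param counts integer matrix, samples x genes, nonnegative.
#' @param gene_ids character vector of gene identifiers (one per column).
#' @param gene_lengths numeric vector of gene lengths in bases, strictly
#'   positive.
#' @param sample_ids character vector of sample identifiers (one per row).
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, gene_ids = colnames(counts),
                         gene_lengths, sample_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("s", seq_len(nrow(counts)))
  stopifnot(length(gene_ids) == ncol(counts),
            length(sample_ids) == nrow(counts),
            length(gene_lengths) == ncol(counts))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (any(gene_lengths <= 0)) stop("gene lengths must be strictly positive")
  dimnames(counts) <- list(sample_ids, gene_ids)
  structure(list(counts = counts, gene_lengths = as.numeric(gene_lengths)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d samples x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a normalized expression matrix
#'
#' @param values numeric matrix, samples x genes.
#' @param normalization one of `"TPM"`, `"CLR"`, `"Z-score"`, `"Z-ternary"`.
#' @param gene_set the gene set the columns cover: `"all"`, `"O"` or `"OT"`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values,
                              normalization = c("TPM", "CLR", "Z-score",
                                                "Z-ternary"),
                              gene_set = c("all", "O", "OT")) {
  normalization <- match.arg(normalization)
  gene_set <- match.arg(gene_set)
  structure(list(values = as.matrix(values), normalization = normalization,
                 gene_set = gene_set),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s, gene set %s]: %d samples x %d genes\n",
              x$normalization, x$gene_set, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Construct a sample metadata table
#'
#' @param sample_id,tissue,study,accession character vectors, one entry per
#'   sample.
#' @param is_cell_line,is_single_cell logical flags per sample;
#'   `is_single_cell` marks samples from single-cell studies.
#' @return A data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, tissue, study, accession,
                            is_cell_line = FALSE, is_single_cell = FALSE) {
  out <- data.frame(sample_id = as.character(sample_id),
                    tissue = as.character(tissue),
                    study = as.character(study),
                    accession = as.character(accession),
                    is_cell_line = rep_len(is_cell_line, length(sample_id)),
                    is_single_cell = rep_len(is_single_cell,
                                             length(sample_id)),
                    stringsAsFactors = FALSE)
  class(out) <- c("sample_metadata", "data.frame")
  out
}

#' Construct a gene annotation table
#'
#' Gene-set membership flags. The OT set (transcription factors with Gene
#' Ontology annotation) is nested in the O set (genes with GO biological
#' process or molecular function annotation).
#'
#' @param gene_id character vector.
#' @param in_O,in_OT logical membership flags; `in_OT` must imply `in_O`.
#' @return A data.frame of class `gene_annotation`.
#' @export
gene_annotation <- function(gene_id, in_O, in_OT) {
  if (any(in_OT & !in_O)) stop("OT genes must be a subset of O genes")
  out <- data.frame(gene_id = as.character(gene_id), in_O = in_O,
                    in_OT = in_OT, stringsAsFactors = FALSE)
  class(out) <- c("gene_annotation", "data.frame")
  out
}

#' Construct a predictive task specification
#'
#' @param task_id character scalar.
#' @param task_type one of `"binary"`, `"multiclass"`, `"survival"`.
#' @param group allocation of the task: `"train"`, `"validate"` or `"test"`.
#' @param sample_ids character vector of member samples.
#' @param labels factor of class labels (classification tasks).
#' @param time,event numeric survival time (> 0) and 0/1 event indicator
#'   (survival tasks).
#' @return An object of class `task_spec`.
#' @export
task_spec <- function(task_id, task_type = c("binary", "multiclass",
                                             "survival"),
                      group = c("train", "validate", "test"),
                      sample_ids, labels = NULL, time = NULL, event = NULL) {
  task_type <- match.arg(task_type)
  group <- match.arg(group)
  if (task_type == "survival") {
    stopifnot(length(time) == length(sample_ids),
              length(event) == length(sample_ids))
    if (any(time <= 0)) stop("survival times must be positive")
    if (!all(event %in% c(0, 1))) stop("event indicator must be 0/1")
  } else {
    labels <- as.factor(labels)
    stopifnot(length(labels) == length(sample_ids))
    if (task_type == "binary" && nlevels(droplevels(labels)) != 2)
      stop("binary task must have exactly 2 observed classes")
  }
  structure(list(task_id = task_id, task_type = task_type, group = group,
                 sample_ids = as.character(sample_ids), labels = labels,
                 time = time, event = event),
            class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf("task_spec %s [%s, %s]: %d samples\n", x$task_id, x$task_type,
              x$group, length(x$sample_ids)))
  invisible(x)
}
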