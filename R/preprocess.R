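#' Five-rule sample quality control
#'
#' A sample is removed if it matches at least one of five exclusion criteria:
#' (1) it is annotated as a cell line; (2) its study is a single-cell study;
#' (3) its reported tissue is absent from the reference tissue set (missing
#' tissue labels count as a match); (4) its accession occurs more than once;
#' (5) more than 30\% of the genes in the O gene set have a zero count. The
#' criteria are non-exclusive: one sample can match several, and the
#' per-criterion counts report every match.
#'
#' @param data a [count_matrix()].
#' @param meta a [sample_metadata()] aligned to `data` rows.
#' @param annot a [gene_annotation()] aligned to `data` columns.
#' @param reference_tissues character vector of admissible tissue labels.
#' @param zero_fraction_threshold samples with a strictly larger zero-count
#'   fraction over O genes are removed; default 0.30.
#' @return list with `keep` (logical mask over samples), `criterion_counts`
#'   (integer vector of length 5, non-exclusive match counts) and
#'   `matches` (5-column logical matrix of per-sample criterion matches).
#' @export
qc_filter <- function(data, meta, annot, reference_tissues,
                      zero_fraction_threshold = 0.30) {
  n <- nrow(data$counts)
  if (nrow(meta) != n)
    stop("metadata rows do not match the count matrix samples")
  if (nrow(annot) != ncol(data$counts))
    stop("gene annotation does not match the count matrix genes")

  tissue_known <- !is.na(meta$tissue) & nzchar(meta$tissue)
  o_counts <- data$counts[, annot$in_O, drop = FALSE]
  zero_frac <- rowMeans(o_counts == 0)

  matches <- cbind(
    cell_line      = as.logical(meta$is_cell_line),
    single_cell    = as.logical(meta$is_single_cell),
    unknown_tissue = !(tissue_known & meta$tissue %in% reference_tissues),
    duplicate_accession = meta$accession %in%
      meta$accession[duplicated(meta$accession)],
    high_zero_fraction  = zero_frac > zero_fraction_threshold
  )
  list(keep = rowSums(matches) == 0,
       criterion_counts = colSums(matches),
       matches = matches)
}

#' Restrict an expression or count matrix to a gene set
#'
#' Columns are subset in place, preserving order. Normalized values are taken
#' as-is: normalization is always computed over all genes first and is never
#' recomputed after restriction, so e.g. a CLR matrix restricted to O genes
#' need not have zero row sums.
#'
#' @param data a [count_matrix()] or [expression_matrix()].
#' @param annot a [gene_annotation()] aligned to the columns of `data`.
#' @param which one of `"all"`, `"O"`, `"OT"`.
#' @return object of the same class restricted to the selected genes.
#' @export
select_gene_set <- function(data, annot, which = c("all", "O", "OT")) {
  which <- match.arg(which)
  keep <- switch(which, all = rep(TRUE, nrow(annot)), O = annot$in_O,
                 OT = annot$in_OT)
  if (!any(keep)) stop("selected gene set is empty")
  if (inherits(data, "count_matrix")) {
    out <- data
    out$counts <- data$counts[, keep, drop = FALSE]
    out$gene_lengths <- data$gene_lengths[keep]
    out
  } else if (inherits(data, "expression_matrix")) {
    expression_matrix(data$values[, keep, drop = FALSE],
                      normalization = data$normalization, gene_set = which)
  } else stop("unsupported input class")
}

#' Transcripts-per-million normalization
#'
#' Per sample: `tpm_i = 1e6 * (counts_i / length_i) / sum_j (counts_j /
#' length_j)`, so each row sums to one million. With `pseudocount > 0` the
#' pseudocount is added to every raw count before length normalization
#' whenever the sample contains a zero; this keeps the subsequent log
#' transform finite while leaving zero-free samples untouched.
#'
#' @param data a [count_matrix()].
#' @param pseudocount added to the counts of samples containing zeros before
#'   normalization; set to 0 to disable.
#' @return an [expression_matrix()] with normalization `"TPM"`.
#' @export
to_tpm <- function(data, pseudocount = 0) {
  counts <- data$counts
  all_zero <- rowSums(counts) == 0
  if (any(all_zero))
    stop("sample(s) with all-zero counts: ",
         paste(rownames(counts)[all_zero], collapse = ", "))
  if (pseudocount > 0) {
    has_zero <- rowSums(counts == 0) > 0
    counts[has_zero, ] <- counts[has_zero, , drop = FALSE] + pseudocount
  }
  rate <- sweep(counts, 2, data$gene_lengths, "/")
  tpm <- 1e6 * rate / rowSums(rate)
  expression_matrix(tpm, normalization = "TPM", gene_set = "all")
}

#' Centered log-ratio transform
#'
#' Per sample: `clr_i = log(tpm_i) - mean_j log(tpm_j)` (natural log), mapping
#' the compositional TPM vector to an unconstrained space with zero row sums.
#' Zeros must have been handled upstream (see [to_tpm()]'s pseudocount).
#'
#' @param data an [expression_matrix()] with normalization `"TPM"`.
#' @return an [expression_matrix()] with normalization `"CLR"`.
#' @export
to_clr <- function(data) {
  stopifnot(inherits(data, "expression_matrix"))
  if (data$normalization != "TPM")
    stop("CLR is computed from TPM input")
  v <- data$values
  if (any(v < 0)) stop("negative TPM values")
  if (any(v == 0))
    stop("zero TPM values; apply a pseudocount in to_tpm() first")
  lg <- log(v)
  out <- expression_matrix(lg - rowMeans(lg), normalization = "CLR",
                           gene_set = data$gene_set)
  dimnames(out$values) <- dimnames(v)
  out
}

#' Build a per-tissue CLR reference
#'
#' Per-tissue, per-gene mean and standard deviation of CLR expression over
#' healthy reference samples (the population standard deviation, floored at
#' `epsilon` so genes that are constant in the reference cannot produce
#' infinite Z-scores).
#'
#' @param clr_data an [expression_matrix()] with normalization `"CLR"`.
#' @param meta a [sample_metadata()] aligned to `clr_data`.
#' @param reference_mask logical mask selecting the healthy reference samples.
#' @param epsilon lower floor for the standard deviation.
#' @return object of class `tissue_reference` with matrices `mean` and `sd`
#'   (tissue x gene).
#' @export
build_tissue_reference <- function(clr_data, meta, reference_mask,
                                   epsilon = 1e-6) {
  stopifnot(inherits(clr_data, "expression_matrix"),
            clr_data$normalization == "CLR")
  v <- clr_data$values[reference_mask, , drop = FALSE]
  tis <- meta$tissue[reference_mask]
  cnt <- table(tis)
  if (any(cnt < 2))
    stop("tissue(s) with fewer than 2 reference samples: ",
         paste(names(cnt)[cnt < 2], collapse = ", "))
  tissues <- sort(unique(tis))
  mu <- t(vapply(tissues, function(t) colMeans(v[tis == t, , drop = FALSE]),
                 numeric(ncol(v))))
  s2 <- t(vapply(tissues, function(t) {
    x <- v[tis == t, , drop = FALSE]
    colMeans(x^2) - colMeans(x)^2            # population variance
  }, numeric(ncol(v))))
  sd <- pmax(sqrt(pmax(s2, 0)), epsilon)
  rownames(mu) <- rownames(sd) <- tissues
  colnames(mu) <- colnames(sd) <- colnames(v)
  structure(list(mean = mu, sd = sd, epsilon = epsilon),
            class = "tissue_reference")
}

#' Tissue-referenced Z-score normalization
#'
#' Standardizes each sample's CLR values by the mean and standard deviation
#' of the same gene in healthy reference samples of the same tissue:
#' `z_i = (clr_i - mean(clr, tissue)_i) / std(clr, tissue)_i`.
#'
#' @param clr_data an [expression_matrix()] with normalization `"CLR"`.
#' @param meta a [sample_metadata()] aligned to `clr_data`.
#' @param ref a `tissue_reference` from [build_tissue_reference()].
#' @return an [expression_matrix()] with normalization `"Z-score"`.
#' @export
to_zscore <- function(clr_data, meta, ref) {
  stopifnot(inherits(clr_data, "expression_matrix"),
            clr_data$normalization == "CLR",
            inherits(ref, "tissue_reference"))
  v <- clr_data$values
  unknown <- !(meta$tissue %in% rownames(ref$mean))
  if (any(unknown))
    stop("sample(s) with tissue absent from the reference: ",
         paste(sprintf("%s (%s)", meta$sample_id[unknown],
                       meta$tissue[unknown]), collapse = ", "))
  z <- (v - ref$mean[meta$tissue, , drop = FALSE]) /
    ref$sd[meta$tissue, , drop = FALSE]
  dimnames(z) <- dimnames(v)
  expression_matrix(z, normalization = "Z-score", gene_set = clr_data$gene_set)
}

#' Ternarize Z-scores
#'
#' Discretizes tissue-referenced Z-scores into down-regulated (-1, Z < -2),
#' normal (0, -2 <= Z <= 2) and up-regulated (+1, Z > 2). The boundary values
#' map to 0. Already-ternarized input is returned unchanged, so the
#' operation is idempotent.
#'
#' @param z_data an [expression_matrix()] with normalization `"Z-score"`.
#' @param threshold the +/- cut point, default 2.
#' @return an [expression_matrix()] with normalization `"Z-ternary"` and
#'   values in \{-1, 0, 1\}.
#' @export
to_zternary <- function(z_data, threshold = 2) {
  stopifnot(inherits(z_data, "expression_matrix"))
  if (z_data$normalization == "Z-ternary") return(z_data)
  if (z_data$normalization != "Z-score")
    stop("ternarization applies to Z-score input")
  v <- z_data$values
  t3 <- (v > threshold) - (v < -threshold)
  dimnames(t3) <- dimnames(v)
  expression_matrix(t3, normalization = "Z-ternary", gene_set = z_data$gene_set)
}

#' Run the full normalization chain
#'
#' counts -> TPM -> CLR -> Z-score -> Z-ternary, each stage consuming its
#' declared predecessor. Returns all four normalizations over all genes;
#' restrict to gene sets afterwards with [select_gene_set()].
#'
#' @param data a [count_matrix()] (QC-passing samples).
#' @param meta a [sample_metadata()] aligned to `data`.
#' @param reference_mask logical mask of healthy reference samples used for
#'   the tissue reference.
#' @param pseudocount see [to_tpm()].
#' @param epsilon see [build_tissue_reference()].
#' @return named list of four [expression_matrix()] objects (`TPM`, `CLR`,
#'   `Z-score`, `Z-ternary`) plus the `reference`.
#' @export
normalize_all <- function(data, meta, reference_mask, pseudocount = 0.5,
                          epsilon = 1e-6) {
  tpm <- to_tpm(data, pseudocount = pseudocount)
  clr <- to_clr(tpm)
  ref <- build_tissue_reference(clr, meta, reference_mask, epsilon = epsilon)
  z <- to_zscore(clr, meta, ref)
  zt <- to_zternary(z)
  list(TPM = tpm, CLR = clr, `Z-score` = z, `Z-ternary` = zt,
       reference = ref)
}
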