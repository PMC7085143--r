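# Synthetic compendium generator. Emulates the statistical structure the
# pipeline assumes: compositional counts driven by tissue-specific
# log-expression profiles, heavy-tailed library sizes, nested gene sets,
# planted linear signals in CLR space for classification, proportional-
# hazards signals with calibrated censoring for survival, and samples
# violating each QC rule. All distributional choices are stand-ins for the
# real compendium and are documented in the methods vignette.

#' Blueprint for one synthetic predictive task
#'
#' @param type `"binary"`, `"multiclass"` or `"survival"`.
#' @param n_samples samples in the task.
#' @param n_signal_genes number of genes with nonzero planted effect (s).
#' @param effect_size magnitude of each nonzero CLR-space (classification)
#'   or log-hazard (survival) coefficient; 0 plants no signal.
#' @param group train/validate/test allocation.
#' @param n_classes class count for multiclass tasks.
#' @param signal_set gene set the signal genes are drawn from (`"all"`,
#'   `"O"`, `"OT"`).
#' @return a task blueprint list.
#' @export
task_blueprint <- function(type = c("binary", "multiclass", "survival"),
                           n_samples = 300, n_signal_genes = 20,
                           effect_size = 1,
                           group = c("train", "validate", "test"),
                           n_classes = 3, signal_set = "all") {
  list(type = match.arg(type), n_samples = n_samples,
       n_signal_genes = n_signal_genes, effect_size = effect_size,
       group = match.arg(group), n_classes = n_classes,
       signal_set = signal_set)
}

#' Configuration of the synthetic compendium
#'
#' Defaults describe the desk-scale study conditions: 5 tissues, 2000 genes
#' of which 600 carry Gene Ontology annotation (O) and 100 of those are
#' transcription factors (OT), 2000 unlabeled samples, log-normal library
#' sizes around one million reads, and per-sample log-expression noise of
#' 0.5.
#'
#' @param n_tissues,n_genes,genes_in_O,genes_in_OT,n_unlabeled counts;
#'   gene sets must nest (`genes_in_OT <= genes_in_O <= n_genes`).
#' @param tasks list of [task_blueprint()]s.
#' @param library_size_mean mean reads per sample.
#' @param library_size_sdlog log-scale sd of the library sizes.
#' @param noise_sd per-sample, per-gene log-expression deviation.
#' @param tissue_sd spread of tissue profiles around the shared baseline.
#' @param censoring_fraction target fraction of censored survival subjects,
#'   in \[0, 1).
#' @param qc_violation_counts named counts of samples to plant per QC
#'   criterion (`cell_line`, `single_cell`, `unknown_tissue`,
#'   `duplicate_accession`, `high_zero`).
#' @param seed RNG seed; the whole dataset is a deterministic function of
#'   the configuration.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(n_tissues = 5, n_genes = 2000,
                              genes_in_O = 600, genes_in_OT = 100,
                              n_unlabeled = 2000,
                              tasks = list(task_blueprint()),
                              library_size_mean = 1e6,
                              library_size_sdlog = 0.5,
                              noise_sd = 0.5, tissue_sd = 1,
                              censoring_fraction = 0.3,
                              qc_violation_counts = c(
                                cell_line = 0, single_cell = 0,
                                unknown_tissue = 0,
                                duplicate_accession = 0, high_zero = 0),
                              seed = 1) {
  stopifnot(genes_in_OT <= genes_in_O, genes_in_O <= n_genes,
            n_tissues > 0, n_genes > 0, n_unlabeled > 0,
            censoring_fraction >= 0, censoring_fraction < 1)
  for (b in tasks) {
    avail <- switch(b$signal_set, all = n_genes, O = genes_in_O,
                    OT = genes_in_OT)
    if (b$n_signal_genes > avail)
      stop("n_signal_genes exceeds the size of gene set ", b$signal_set)
  }
  structure(list(n_tissues = n_tissues, n_genes = n_genes,
                 genes_in_O = genes_in_O, genes_in_OT = genes_in_OT,
                 n_unlabeled = n_unlabeled, tasks = tasks,
                 library_size_mean = library_size_mean,
                 library_size_sdlog = library_size_sdlog,
                 noise_sd = noise_sd, tissue_sd = tissue_sd,
                 censoring_fraction = censoring_fraction,
                 qc_violation_counts = qc_violation_counts, seed = seed),
            class = "simulation_config")
}

# counts for a block of samples: softmax composition at the drawn library
# size, so each row sums exactly to its library size
draw_counts <- function(eta, lib) {
  t(vapply(seq_len(nrow(eta)), function(i) {
    pr <- exp(eta[i, ] - max(eta[i, ]))
    as.integer(stats::rmultinom(1, size = lib[i], prob = pr))
  }, integer(ncol(eta))))
}

#' Generate a synthetic compendium with known ground truth
#'
#' Counts follow a documented hierarchy: per-tissue mean log-expression plus
#' a per-sample Gaussian deviation (shifted by label x effect vector for
#' labeled classification samples), pushed through a softmax to a
#' composition and drawn from a multinomial at the sample's log-normal
#' library size. Survival times are exponential with log-hazard equal to
#' the effect vector dotted with the sample's CLR expression, censored by an
#' independent uniform horizon calibrated numerically to the requested
#' censoring fraction. QC-violating samples are planted afterwards via
#' [inject_qc_violations()].
#'
#' @param config a [simulation_config()].
#' @return list with `data` ([count_matrix()]), `meta`
#'   ([sample_metadata()]), `annot` ([gene_annotation()]), `tasks` (list of
#'   [task_spec()]), `truth` (per-task effect vectors and tissue profiles)
#'   and `qc_injected` (ids of planted QC violators).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- local_rng_seed(config$seed)
  on.exit(restore_rng(old))
  p <- config$n_genes
  gene_ids <- sprintf("g%04d", seq_len(p))
  gene_lengths <- pmax(round(stats::rlnorm(p, log(1500), 0.7)), 100)

  in_O <- seq_len(p) %in% sample.int(p, config$genes_in_O)
  in_OT <- in_O & (seq_len(p) %in%
                     sample(which(in_O), config$genes_in_OT))
  annot <- gene_annotation(gene_ids, in_O, in_OT)

  tissues <- paste0("tissue", seq_len(config$n_tissues))
  baseline <- stats::rnorm(p, 0, 1.5)
  mu <- t(vapply(tissues, function(t)
    baseline + stats::rnorm(p, 0, config$tissue_sd), numeric(p)))
  rownames(mu) <- tissues
  colnames(mu) <- gene_ids

  lib_meanlog <- log(config$library_size_mean) -
    config$library_size_sdlog^2 / 2
  lib_sizes <- numeric(0)
  draw_lib <- function(n) {
    l <- pmax(round(stats::rlnorm(n, lib_meanlog,
                                  config$library_size_sdlog)), 1000)
    lib_sizes <<- c(lib_sizes, l)
    l
  }

  # ---- unlabeled pool (healthy reference) ----
  n_u <- config$n_unlabeled
  u_tissue <- tissues[((seq_len(n_u) - 1L) %% config$n_tissues) + 1L]
  eta_u <- mu[u_tissue, , drop = FALSE] +
    matrix(stats::rnorm(n_u * p, 0, config$noise_sd), n_u, p)
  blocks <- list(counts = draw_counts(eta_u, draw_lib(n_u)))
  meta <- data.frame(sample_id = sprintf("U%05d", seq_len(n_u)),
                     tissue = u_tissue,
                     study = paste0("study_", u_tissue),
                     accession = sprintf("ACC_U%05d", seq_len(n_u)),
                     is_cell_line = FALSE, is_single_cell = FALSE,
                     is_reference = TRUE, stringsAsFactors = FALSE)

  # ---- labeled tasks ----
  tasks <- list()
  effects <- list()
  for (ti in seq_along(config$tasks)) {
    b <- config$tasks[[ti]]
    task_id <- sprintf("task%02d_%s", ti, b$type)
    n <- b$n_samples
    tissue <- tissues[((ti - 1L) %% config$n_tissues) + 1L]
    ids <- sprintf("T%02d_%04d", ti, seq_len(n))

    pool <- switch(b$signal_set, all = seq_len(p), O = which(in_O),
                   OT = which(in_OT))
    beta <- numeric(p)
    if (b$effect_size > 0 && b$n_signal_genes > 0) {
      sig <- sample(pool, b$n_signal_genes)
      beta[sig] <- b$effect_size *
        sample(c(-1, 1), b$n_signal_genes, replace = TRUE)
    }
    names(beta) <- gene_ids
    effects[[task_id]] <- beta

    noise <- matrix(stats::rnorm(n * p, 0, config$noise_sd), n, p)
    if (b$type == "survival") {
      eta <- mu[rep(tissue, n), , drop = FALSE] + noise
      clr <- eta - rowMeans(eta)        # CLR of softmax(eta) is exact
      h <- as.numeric(clr %*% beta)
      h <- h - mean(h)
      t_true <- stats::rexp(n, rate = exp(h))
      if (config$censoring_fraction > 0) {
        u <- stats::runif(n)
        tau <- stats::uniroot(function(tau)
          mean(tau * u < t_true) - config$censoring_fraction,
          lower = 1e-9, upper = 1e9, tol = 1e-10)$root
        cens <- tau * u
        time <- pmin(t_true, cens)
        event <- as.numeric(t_true <= cens)
      } else {
        time <- t_true
        event <- rep(1, n)
      }
      tasks[[task_id]] <- task_spec(task_id, "survival", b$group, ids,
                                    time = time, event = event)
    } else {
      k <- if (b$type == "binary") 2L else as.integer(b$n_classes)
      lab <- rep(seq_len(k) - 1L, length.out = n)
      lab <- lab[sample.int(n)]
      shift <- (lab / (k - 1) - 0.5)    # centered, linear in class index
      eta <- mu[rep(tissue, n), , drop = FALSE] + outer(shift, beta) + noise
      tasks[[task_id]] <- task_spec(task_id, b$type, b$group, ids,
                                    labels = factor(lab,
                                                    levels = seq_len(k) - 1L))
    }
    blocks$counts <- rbind(blocks$counts, draw_counts(eta, draw_lib(n)))
    meta <- rbind(meta, data.frame(
      sample_id = ids, tissue = tissue,
      study = paste0("study_", task_id),
      accession = sprintf("ACC_%s_%04d", task_id, seq_len(n)),
      is_cell_line = FALSE, is_single_cell = FALSE, is_reference = FALSE,
      stringsAsFactors = FALSE))
  }

  data <- count_matrix(blocks$counts, gene_ids, gene_lengths,
                       meta$sample_id)
  md <- sample_metadata(meta$sample_id, meta$tissue, meta$study,
                        meta$accession, meta$is_cell_line,
                        meta$is_single_cell)
  md$is_reference <- meta$is_reference

  injected <- NULL
  if (any(config$qc_violation_counts > 0)) {
    # plant violations only among non-reference unlabeled spares: reserve
    # the tail of the unlabeled pool so QC never removes task samples
    eligible <- which(md$is_reference)
    eligible <- utils::tail(eligible, sum(config$qc_violation_counts) * 2)
    inj <- inject_qc_violations(data, md, config$qc_violation_counts,
                                annot, eligible = eligible)
    data <- inj$data
    md <- inj$meta
    injected <- inj$injected
  }

  list(data = data, meta = md, annot = annot, tasks = tasks,
       library_sizes = stats::setNames(lib_sizes, meta$sample_id),
       truth = list(effects = effects, tissue_mean_log = mu,
                    tissue_clr_sd = matrix(config$noise_sd,
                                           config$n_tissues, p,
                                           dimnames = dimnames(mu))),
       qc_injected = injected)
}

#' Plant QC-violating samples
#'
#' Marks or modifies existing samples so that exactly the requested number
#' matches each of the five QC criteria. Different criteria are planted on
#' different samples by default, but matches may overlap if `eligible` is
#' short: the criteria are non-exclusive.
#'
#' @param data a [count_matrix()].
#' @param meta its [sample_metadata()].
#' @param counts named counts per criterion (`cell_line`, `single_cell`,
#'   `unknown_tissue`, `duplicate_accession`, `high_zero`);
#'   `duplicate_accession` needs at least 2.
#' @param annot a [gene_annotation()] (needed for the high-zero criterion).
#' @param eligible integer indices of samples that may be modified; defaults
#'   to all.
#' @return list with modified `data`, `meta` and `injected` (named list of
#'   affected sample ids per criterion).
#' @export
inject_qc_violations <- function(data, meta, counts, annot,
                                 eligible = seq_len(nrow(meta))) {
  want <- c(cell_line = 0, single_cell = 0, unknown_tissue = 0,
            duplicate_accession = 0, high_zero = 0)
  want[names(counts)] <- counts
  if (sum(want) > length(eligible))
    stop("requested more QC violations than eligible samples")
  if (want["duplicate_accession"] == 1)
    stop("a duplicate-accession group needs at least 2 samples")
  pool <- eligible
  # planted violators are no longer clean reference material
  drop_ref <- function(i) {
    if ("is_reference" %in% names(meta)) meta$is_reference[i] <<- FALSE
    i
  }
  take <- function(k) {
    if (k == 0) return(integer(0))
    got <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    got
  }
  injected <- list()

  i <- drop_ref(take(want[["cell_line"]]))
  meta$is_cell_line[i] <- TRUE
  injected$cell_line <- meta$sample_id[i]

  i <- drop_ref(take(want[["single_cell"]]))
  meta$is_single_cell[i] <- TRUE
  injected$single_cell <- meta$sample_id[i]

  i <- drop_ref(take(want[["unknown_tissue"]]))
  meta$tissue[i] <- "unmatched_tissue"
  injected$unknown_tissue <- meta$sample_id[i]

  i <- drop_ref(take(want[["duplicate_accession"]]))
  if (length(i) >= 2) meta$accession[i] <- meta$accession[i[1]]
  injected$duplicate_accession <- meta$sample_id[i]

  i <- drop_ref(take(want[["high_zero"]]))
  if (length(i) > 0) {
    o_idx <- which(annot$in_O)
    n_zero <- ceiling(0.35 * length(o_idx))   # safely above the 30% rule
    for (s in i) data$counts[s, o_idx[seq_len(n_zero)]] <- 0L
  }
  injected$high_zero <- meta$sample_id[i]

  list(data = data, meta = meta, injected = injected)
}

#' Write a synthetic dataset to delimited text
#'
#' Counts go to `counts.tsv.gz` (genes x samples; first columns gene id and
#' length, then one column per sample), metadata to `metadata.tsv`, task
#' labels to `task_<id>.tsv`, and ground-truth effects to
#' `truth_effects.tsv`.
#'
#' @param dataset output of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cm <- dataset$data
  counts <- data.table::data.table(gene_id = colnames(cm$counts),
                                   length = cm$gene_lengths,
                                   t(cm$counts))
  paths <- file.path(dir, "counts.tsv.gz")
  data.table::fwrite(counts, paths, sep = "\t", compress = "gzip")
  data.table::fwrite(dataset$meta, file.path(dir, "metadata.tsv"),
                     sep = "\t")
  for (t in dataset$tasks) {
    df <- if (t$task_type == "survival")
      data.frame(sample_id = t$sample_ids, time = t$time, event = t$event)
    else data.frame(sample_id = t$sample_ids, label = t$labels)
    f <- file.path(dir, paste0("task_", t$task_id, ".tsv"))
    data.table::fwrite(df, f, sep = "\t")
    paths <- c(paths, f)
  }
  eff <- do.call(rbind, lapply(names(dataset$truth$effects), function(id)
    data.frame(task_id = id, gene_id = names(dataset$truth$effects[[id]]),
               effect = unname(dataset$truth$effects[[id]]))))
  data.table::fwrite(eff, file.path(dir, "truth_effects.tsv"), sep = "\t")
  invisible(c(paths, file.path(dir, c("metadata.tsv", "truth_effects.tsv"))))
}

#' Read a counts table written by [write_dataset()]
#'
#' @param path path to `counts.tsv.gz`.
#' @return a [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  dt <- utils::read.delim(con, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- dt$gene_id
  lengths <- dt$length
  m <- t(as.matrix(dt[, -(1:2), drop = FALSE]))
  colnames(m) <- genes
  count_matrix(m, genes, lengths, rownames(m))
}
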