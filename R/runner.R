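# Configuration-driven orchestration: simulate -> qc -> normalize -> gene
# sets -> embed -> nested CV -> aggregation, with fit-count audit.

#' Assemble a run configuration
#'
#' @param simulation a [simulation_config()] describing the synthetic
#'   compendium.
#' @param gene_sets,normalizations,embedders,classifiers,survival_learner
#'   design axes; SDAE/VAE are admissible only with the O/OT gene sets.
#' @param latent_dim embedder latent dimension.
#' @param embed_spec a [train_spec()] for the neural embedders.
#' @param K nested-CV fold count.
#' @param seed master seed; stage seeds are derived from it.
#' @param maxit,tol first-order fitter settings.
#' @param out_dir optional output directory for results CSV; completed
#'   cells found there are reused on rerun.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = simulation_config(),
                       gene_sets = c("all", "O", "OT"),
                       normalizations = c("TPM", "CLR", "Z-score",
                                          "Z-ternary"),
                       embedders = c("identity", "pca"),
                       classifiers = c("LR", "RF", "kNN"),
                       survival_learner = "CoxPH",
                       latent_dim = 32, embed_spec = train_spec(),
                       K = 5, seed = 1, maxit = 300, tol = 1e-5,
                       out_dir = NULL) {
  structure(list(simulation = simulation, gene_sets = gene_sets,
                 normalizations = normalizations, embedders = embedders,
                 classifiers = classifiers,
                 survival_learner = survival_learner,
                 latent_dim = latent_dim, embed_spec = embed_spec, K = K,
                 seed = seed, maxit = maxit, tol = tol, out_dir = out_dir),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Scalar fields map directly onto [run_config()]; a `simulation` block maps
#' onto [simulation_config()] with `tasks` as a list of
#' [task_blueprint()] fields.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$simulation %||% list()
  if (!is.null(sim_args$tasks))
    sim_args$tasks <- lapply(sim_args$tasks, function(b)
      do.call(task_blueprint, b))
  y$simulation <- do.call(simulation_config, sim_args)
  if (!is.null(y$embed_spec))
    y$embed_spec <- do.call(train_spec, y$embed_spec)
  do.call(run_config, y)
}

config_plan <- function(config, tasks) {
  experiment_plan(tasks = tasks, gene_sets = config$gene_sets,
                  normalizations = config$normalizations,
                  embedders = config$embedders,
                  classifiers = config$classifiers,
                  survival_learner = config$survival_learner,
                  K = config$K)
}

#' Enumerate a run without training
#'
#' @param config a `run_config`.
#' @return list with the plan cells, result count and model-fit count.
#' @export
dry_run <- function(config) {
  blue <- config$simulation$tasks
  tasks <- data.frame(
    task_id = sprintf("task%02d_%s", seq_along(blue),
                      vapply(blue, `[[`, "", "type")),
    task_type = vapply(blue, `[[`, "", "type"),
    stringsAsFactors = FALSE)
  e <- enumerate_plan(config_plan(config, tasks))
  c(e, list(cells = admissible_cells(config_plan(config, tasks))))
}

fit_embedder <- function(kind, pool, d, spec) {
  switch(kind,
         identity = identity_embedder(ncol(pool)),
         pca = fit_pca_stochastic(pool, min(d, ncol(pool), nrow(pool)),
                                  spec),
         sdae = fit_sdae(pool, min(d, ncol(pool)), spec),
         vae = fit_vae(pool, min(d, ncol(pool)), spec),
         stop("unknown embedder kind: ", kind))
}

#' Run a full benchmarking experiment
#'
#' Executes the pipeline end to end on the configured synthetic compendium:
#' generation, QC, the four normalizations, gene-set restriction, embedder
#' fitting on the unlabeled pool (frozen before any supervised stage),
#' nested cross-validation for every admissible plan cell, and
#' median-shifted aggregation. The audited fit count is checked against the
#' plan enumeration and reported.
#'
#' @param config a `run_config`.
#' @return list with `records` (one row per result, incl. shifted metric),
#'   `results` (the `cv_result` objects), `summary` (sample-weighted mean
#'   shifted metric per configuration), `audit` and `qc`.
#' @export
run_experiment <- function(config) {
  stopifnot(inherits(config, "run_config"))
  ds <- generate_dataset(config$simulation)

  ref_tissues <- unique(ds$meta$tissue[ds$meta$is_reference])
  qc <- qc_filter(ds$data, ds$meta, ds$annot, ref_tissues)
  keep <- qc$keep
  data <- ds$data
  data$counts <- data$counts[keep, , drop = FALSE]
  meta <- ds$meta[keep, , drop = FALSE]

  norms <- normalize_all(data, meta, meta$is_reference)
  pool_mask <- meta$is_reference
  n_samples <- vapply(ds$tasks, function(t) length(t$sample_ids),
                      numeric(1))
  names(n_samples) <- vapply(ds$tasks, `[[`, "", "task_id")

  cells <- admissible_cells(config_plan(config, ds$tasks))
  results <- list()
  total_fits <- 0L
  prev <- read_previous_records(config$out_dir)

  for (ci in seq_len(nrow(cells))) {
    gs <- cells$gene_set[ci]
    nm <- cells$normalization[ci]
    em <- cells$embedder[ci]
    expr <- select_gene_set(norms[[nm]], ds$annot, gs)
    emb <- fit_embedder(em, expr$values[pool_mask, , drop = FALSE],
                        config$latent_dim, config$embed_spec)
    for (t in ds$tasks) {
      rows <- match(t$sample_ids, rownames(expr$values))
      feat <- encode(emb, expr$values[rows, , drop = FALSE])
      kinds <- if (t$task_type == "survival") config$survival_learner else
        config$classifiers
      for (l in kinds) {
        key <- paste(t$task_id, gs, nm, em, l, sep = "|")
        if (key %in% prev) next
        r <- nested_cv_run(feat, t, l,
                           plan = make_folds(t, K = config$K,
                                             seed = derive_seed(
                                               config$seed, "folds",
                                               t$task_id)),
                           seed = derive_seed(config$seed, key),
                           maxit = config$maxit, tol = config$tol,
                           config = list(gene_set = gs,
                                         normalization = nm,
                                         embedder = em))
        total_fits <- total_fits + r$audit$n_fits
        results[[key]] <- r
      }
    }
  }

  if (length(results) == 0 && length(prev) > 0) {
    records <- utils::read.csv(file.path(config$out_dir, "results.csv"),
                               stringsAsFactors = FALSE)
  } else {
    records <- cv_records(results, n_samples)
    records <- shift_by_task_median(records)
  }
  parts <- split(records, records[c("gene_set", "normalization",
                                    "embedder", "learner")], drop = TRUE)
  summary <- do.call(rbind, lapply(parts, function(d)
    data.frame(gene_set = d$gene_set[1], normalization = d$normalization[1],
               embedder = d$embedder[1], learner = d$learner[1],
               mean_shifted = weighted_average(d$shifted, d$n_samples),
               stringsAsFactors = FALSE)))
  rownames(summary) <- NULL

  expected <- enumerate_plan(config_plan(config, ds$tasks))$n_models
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(records,
                     file.path(config$out_dir, "results.csv"),
                     row.names = FALSE)
  }
  list(records = records, results = results, summary = summary,
       audit = list(n_fits = total_fits, expected_fits = expected,
                    matches = length(prev) == 0 &&
                      total_fits == expected),
       qc = qc)
}

read_previous_records <- function(out_dir) {
  if (is.null(out_dir)) return(character(0))
  f <- file.path(out_dir, "results.csv")
  if (!file.exists(f)) return(character(0))
  prev <- utils::read.csv(f, stringsAsFactors = FALSE)
  paste(prev$task_id, prev$gene_set, prev$normalization, prev$embedder,
        prev$learner, sep = "|")
}
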