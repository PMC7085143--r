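# The benchmark's 50 predictive tasks and the experiment-plan bookkeeping.

#' The 50 predictive tasks of the benchmark
#'
#' The task roster of the full-scale study: 18 TCGA binary tasks (10 tumor
#' stage, 8 tumor grade), 6 SRA clinical tasks (3 binary, 3 three-class),
#' 13 TCGA overall-survival tasks and 13 TCGA progression-free-interval
#' tasks, each with its train/validate/test allocation and sample count.
#' These rows are design inputs: plan enumeration and the divided-task rule
#' are computed from them.
#'
#' @return data.frame with columns `task_id`, `project`, `category`,
#'   `task_type`, `group`, `n_samples`.
#' @export
benchmark_tasks <- function() {
  row <- function(project, category, type, group, n)
    data.frame(task_id = paste(project, category), project = project,
               category = category, task_type = type, group = group,
               n_samples = n, stringsAsFactors = FALSE)
  stage <- rbind(
    row("COAD", "stage", "binary", "train", 505),
    row("KIRC", "stage", "binary", "train", 544),
    row("LIHC", "stage", "binary", "train", 374),
    row("LUAD", "stage", "binary", "train", 542),
    row("SKCM", "stage", "binary", "train", 249),
    row("STAD", "stage", "binary", "train", 416),
    row("THCA", "stage", "binary", "train", 513),
    row("UCEC", "stage", "binary", "train", 554),
    row("LUSC", "stage", "binary", "validate", 504),
    row("BRCA", "stage", "binary", "test", 1134))
  grade <- rbind(
    row("CESC", "grade", "binary", "train", 306),
    row("KIRC", "grade", "binary", "train", 544),
    row("LGG",  "grade", "binary", "train", 532),
    row("LIHC", "grade", "binary", "train", 374),
    row("PAAD", "grade", "binary", "train", 179),
    row("STAD", "grade", "binary", "train", 416),
    row("UCEC", "grade", "binary", "train", 554),
    row("HNSC", "grade", "binary", "test", 504))
  sra <- rbind(
    row("GSE65832", "clinical", "binary", "train", 40),
    row("GSE66207", "clinical", "multiclass", "train", 20),
    row("GSE72819", "clinical", "binary", "validate", 69),
    row("GSE47944", "clinical", "multiclass", "validate", 63),
    row("GSE50244", "clinical", "multiclass", "validate", 76),
    row("GSE67785", "clinical", "binary", "test", 28))
  os <- rbind(
    row("CESC", "OS", "survival", "train", 304),
    row("COAD", "OS", "survival", "train", 455),
    row("ESCA", "OS", "survival", "train", 184),
    row("KIRP", "OS", "survival", "train", 289),
    row("LUAD", "OS", "survival", "train", 507),
    row("OV",   "OS", "survival", "train", 420),
    row("PAAD", "OS", "survival", "train", 178),
    row("SARC", "OS", "survival", "train", 259),
    row("STAD", "OS", "survival", "train", 409),
    row("UCEC", "OS", "survival", "train", 540),
    row("HNSC", "OS", "survival", "validate", 501),
    row("BLCA", "OS", "survival", "test", 407),
    row("LUSC", "OS", "survival", "test", 495))
  pfi <- rbind(
    row("CESC", "PFI", "survival", "train", 304),
    row("COAD", "PFI", "survival", "train", 455),
    row("ESCA", "PFI", "survival", "train", 184),
    row("KIRP", "PFI", "survival", "train", 288),
    row("LUAD", "PFI", "survival", "train", 507),
    row("OV",   "PFI", "survival", "train", 420),
    row("PAAD", "PFI", "survival", "train", 178),
    row("SARC", "PFI", "survival", "train", 259),
    row("STAD", "PFI", "survival", "train", 411),
    row("UCEC", "PFI", "survival", "train", 540),
    row("HNSC", "PFI", "survival", "validate", 501),
    row("BLCA", "PFI", "survival", "test", 408),
    row("LUSC", "PFI", "survival", "test", 496))
  rbind(stage, grade, sra, os, pfi)
}

#' Describe an experiment plan
#'
#' A plan crosses tasks with gene sets, normalizations, embedder kinds and
#' learners, subject to two admissibility rules: the SDAE and VAE embedders
#' pair only with the O and OT gene sets, and survival tasks pair only with
#' the Cox learner.
#'
#' @param tasks data.frame with at least a `task_type` column (e.g.
#'   [benchmark_tasks()]), or a list of [task_spec()] objects.
#' @param gene_sets,normalizations,embedders design axes.
#' @param classifiers learners applied to classification tasks.
#' @param survival_learner learner applied to survival tasks.
#' @param K fold count of the nested cross-validation.
#' @param grid_sizes named hyperparameter grid sizes.
#' @return object of class `experiment_plan`.
#' @export
experiment_plan <- function(tasks = benchmark_tasks(),
                            gene_sets = c("all", "O", "OT"),
                            normalizations = c("TPM", "CLR", "Z-score",
                                               "Z-ternary"),
                            embedders = c("identity", "pca", "sdae", "vae"),
                            classifiers = c("LR", "RF", "kNN"),
                            survival_learner = "CoxPH",
                            K = 5,
                            grid_sizes = c(LR = 10, RF = 7, kNN = 5,
                                           CoxPH = 10)) {
  if (!is.data.frame(tasks))
    tasks <- data.frame(task_id = vapply(tasks, `[[`, "", "task_id"),
                        task_type = vapply(tasks, `[[`, "", "task_type"),
                        stringsAsFactors = FALSE)
  structure(list(tasks = tasks, gene_sets = gene_sets,
                 normalizations = normalizations, embedders = embedders,
                 classifiers = classifiers,
                 survival_learner = survival_learner, K = K,
                 grid_sizes = grid_sizes),
            class = "experiment_plan")
}

# gene-set x embedder combinations admitted by the design
admissible_cells <- function(plan) {
  cells <- expand.grid(gene_set = plan$gene_sets, embedder = plan$embedders,
                       normalization = plan$normalizations,
                       stringsAsFactors = FALSE)
  deep <- cells$embedder %in% c("sdae", "vae")
  cells[!deep | cells$gene_set %in% c("O", "OT"), , drop = FALSE]
}

#' Enumerate an experiment plan
#'
#' Counts the results (one per admissible task x gene set x normalization x
#' embedder x learner tuple) and the individual model fits their nested
#' cross-validation requires (`K(KN+1)` per result, with N the learner's
#' grid size). On the full benchmark design this reproduces 3920 results
#' and 807600 model fits.
#'
#' @param plan an [experiment_plan()].
#' @return list with `n_results`, `n_models`, and the per-task-type
#'   breakdown.
#' @export
enumerate_plan <- function(plan) {
  stopifnot(inherits(plan, "experiment_plan"))
  cells <- admissible_cells(plan)
  n_cells <- nrow(cells)
  types <- plan$tasks$task_type
  n_class <- sum(types %in% c("binary", "multiclass"))
  n_surv <- sum(types == "survival")

  fits <- function(kind) count_models(plan$K, plan$grid_sizes[[kind]])
  class_results <- n_class * n_cells * length(plan$classifiers)
  surv_results <- n_surv * n_cells * length(plan$survival_learner)
  class_models <- n_class * n_cells *
    sum(vapply(plan$classifiers, fits, numeric(1)))
  surv_models <- n_surv * n_cells * fits(plan$survival_learner)

  list(n_results = class_results + surv_results,
       n_models = class_models + surv_models,
       breakdown = data.frame(
         task_type = c("classification", "survival"),
         n_tasks = c(n_class, n_surv),
         n_results = c(class_results, surv_results),
         n_models = c(class_models, surv_models)))
}

#' @export
print.experiment_plan <- function(x, ...) {
  e <- enumerate_plan(x)
  cat(sprintf("experiment_plan: %d tasks, %d results, %d model fits\n",
              nrow(x$tasks), e$n_results, e$n_models))
  invisible(x)
}
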