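# Shared fixtures, generated once per test run and cached in an environment
# so heavy simulations are not repeated across files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a tiny hand-checkable count matrix: 4 samples x 6 genes
tiny_counts <- function() {
  set.seed(42)
  m <- matrix(rpois(24, 50) + 1L, 4, 6)
  count_matrix(m, paste0("g", 1:6), c(100, 200, 150, 300, 250, 120),
               paste0("s", 1:4))
}

tiny_meta <- function() {
  sample_metadata(paste0("s", 1:4), rep("liver", 4), rep("study1", 4),
                  paste0("acc", 1:4))
}

tiny_annot <- function() {
  gene_annotation(paste0("g", 1:6),
                  in_O = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE),
                  in_OT = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
}

# small compendium with one strong binary task, reused across files
small_sim <- function() fixture("small_sim", {
  cfg <- simulation_config(
    n_tissues = 3, n_genes = 200, genes_in_O = 80, genes_in_OT = 20,
    n_unlabeled = 150,
    tasks = list(task_blueprint("binary", 120, 10, 2, "train"),
                 task_blueprint("survival", 120, 10, 2, "train",
                                signal_set = "OT")),
    seed = 101)
  ds <- generate_dataset(cfg)
  norms <- normalize_all(ds$data, ds$meta, ds$meta$is_reference)
  list(cfg = cfg, ds = ds, norms = norms)
})

# brute-force AUC by pair enumeration (independent oracle)
brute_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  tot <- 0
  for (i in pos) for (j in neg)
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  tot / (length(pos) * length(neg))
}

# brute-force Harrell's C by pair enumeration (independent oracle)
brute_cindex <- function(risk, time, event) {
  num <- 0; den <- 0; n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    # pair is comparable if the earlier of the two observed times is an event
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    } else if (time[i] == time[j] && event[i] == 1 && event[j] == 0) {
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  num / den
}

# semi-supervised training fixture: pool = reference samples plus the
# first halves of the divided tasks
semisup_fixture <- function() fixture("semisup_fixture", {
  sim <- small_sim()
  split <- split_divided_tasks(sim$ds$tasks, threshold = 100, seed = 5)
  expr <- select_gene_set(sim$norms$CLR, sim$ds$annot, "O")
  pool_ids <- c(sim$ds$meta$sample_id[sim$ds$meta$is_reference],
                split$halves[[1]]$first)
  pool <- expr$values[match(pool_ids, rownames(expr$values)), ]
  list(sim = sim, split = split, expr = expr, pool = pool)
})

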