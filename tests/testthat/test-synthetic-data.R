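test_that("generation is a deterministic function of the configuration", {
  cfg <- simulation_config(n_tissues = 2, n_genes = 60, genes_in_O = 30,
                           genes_in_OT = 10, n_unlabeled = 40,
                           tasks = list(task_blueprint("binary", 40, 5, 1,
                                                       "train")),
                           seed = 55)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$data$counts, b$data$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$tasks[[1]]$labels, b$tasks[[1]]$labels)
  expect_identical(a$truth$effects, b$truth$effects)
})

test_that("counts are compositional: rows sum to the drawn library sizes", {
  sim <- small_sim()
  expect_true(all(sim$ds$data$counts >= 0))
  expect_identical(unname(rowSums(sim$ds$data$counts)),
                   unname(sim$ds$library_sizes))
})

test_that("gene sets nest and invalid signal requests are rejected", {
  sim <- small_sim()
  expect_true(all(!sim$ds$annot$in_OT | sim$ds$annot$in_O))
  expect_equal(sum(sim$ds$annot$in_O), 80)
  expect_equal(sum(sim$ds$annot$in_OT), 20)

  expect_error(simulation_config(
    n_genes = 50, genes_in_O = 20, genes_in_OT = 5,
    tasks = list(task_blueprint("binary", 40, 10, 1, signal_set = "OT"))),
    "exceeds")
})

test_that("planted effect vectors have exactly s nonzero entries", {
  sim <- small_sim()
  expect_equal(sum(sim$ds$truth$effects[[1]] != 0), 10)
  expect_equal(sum(sim$ds$truth$effects[[2]] != 0), 10)
  # survival signal restricted to the OT set
  ot <- sim$ds$annot$gene_id[sim$ds$annot$in_OT]
  expect_true(all(names(which(sim$ds$truth$effects[[2]] != 0)) %in% ot))
})

test_that("survival censoring hits the requested fraction", {
  cfg <- simulation_config(n_tissues = 2, n_genes = 100, genes_in_O = 40,
                           genes_in_OT = 10, n_unlabeled = 30,
                           tasks = list(task_blueprint("survival", 400, 5,
                                                       0.5, "train")),
                           censoring_fraction = 0.4, seed = 7)
  ds <- generate_dataset(cfg)
  t <- ds$tasks[[1]]
  expect_equal(mean(t$event == 0), 0.4, tolerance = 0.05)
  expect_true(all(t$time > 0))
})

test_that("QC violations are planted in exactly the requested numbers", {
  cfg <- simulation_config(n_tissues = 2, n_genes = 60, genes_in_O = 30,
                           genes_in_OT = 10, n_unlabeled = 60,
                           tasks = list(),
                           qc_violation_counts = c(cell_line = 3,
                                                   single_cell = 2,
                                                   unknown_tissue = 1,
                                                   duplicate_accession = 2,
                                                   high_zero = 1),
                           seed = 8)
  ds <- generate_dataset(cfg)
  ref_tissues <- unique(ds$meta$tissue[ds$meta$is_reference])
  qc <- qc_filter(ds$data, ds$meta, ds$annot, ref_tissues)
  expect_equal(unname(qc$criterion_counts),
               c(3, 2, 1, 2, 1))

  # the planted high-zero sample really exceeds 30% zeros among O genes
  hz <- ds$qc_injected$high_zero
  frac <- mean(ds$data$counts[match(hz, rownames(ds$data$counts)),
                              ds$annot$in_O] == 0)
  expect_gt(frac, 0.30)

  # the duplicated pair shares one accession
  dup <- ds$qc_injected$duplicate_accession
  accs <- ds$meta$accession[match(dup, ds$meta$sample_id)]
  expect_equal(length(unique(accs)), 1)
  expect_equal(length(dup), 2)
})

test_that("a duplicate-accession request of one sample is rejected", {
  sim <- small_sim()
  expect_error(inject_qc_violations(sim$ds$data, sim$ds$meta,
                                    c(duplicate_accession = 1),
                                    sim$ds$annot),
               "at least 2")
})

test_that("datasets round-trip through the TSV writers", {
  cfg <- simulation_config(n_tissues = 2, n_genes = 30, genes_in_O = 10,
                           genes_in_OT = 4, n_unlabeled = 15,
                           tasks = list(task_blueprint("binary", 30, 3, 1,
                                                       "train")),
                           seed = 3)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  rt <- read_count_matrix(file.path(dir, "counts.tsv.gz"))
  expect_equal(unname(rt$counts), unname(ds$data$counts))
  expect_equal(rt$gene_lengths, ds$data$gene_lengths)
})
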