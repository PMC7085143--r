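test_that("TPM normalization matches the closed form and sums to 1e6", {
  cm <- count_matrix(matrix(c(10, 10), 1, 2), c("a", "b"), c(1, 1), "s1")
  expect_equal(as.numeric(to_tpm(cm)$values), c(5e5, 5e5))

  cm2 <- count_matrix(matrix(c(10, 10), 1, 2), c("a", "b"), c(1, 2), "s1")
  expect_equal(as.numeric(to_tpm(cm2)$values),
               c(666666.67, 333333.33), tolerance = 1e-6)

  tpm <- to_tpm(tiny_counts())
  expect_equal(rowSums(tpm$values), rep(1e6, 4), tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("all-zero samples are rejected by name", {
  m <- matrix(c(0, 0, 0, 5, 2, 1), 2, 3, byrow = TRUE)
  cm <- count_matrix(m, paste0("g", 1:3), c(1, 1, 1), c("bad", "ok"))
  expect_error(to_tpm(cm), "bad")
})

test_that("CLR has zero row sums, known values, and scale invariance", {
  em <- expression_matrix(matrix(rep(250, 8), 2, 4), "TPM")
  expect_true(all(to_clr(em)$values == 0))

  em2 <- expression_matrix(matrix(c(5e5, 2.5e5, 2.5e5), 1, 3), "TPM")
  expect_equal(as.numeric(to_clr(em2)$values),
               c(0.4621, -0.2310, -0.2310), tolerance = 1e-3)

  set.seed(3)
  v <- matrix(rexp(30) + 0.1, 5, 6)
  a <- to_clr(expression_matrix(v, "TPM"))$values
  b <- to_clr(expression_matrix(7.3 * v, "TPM"))$values
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(rowSums(a), rep(0, 5), tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("qc_filter applies the five rules non-exclusively", {
  set.seed(9)
  n <- 11
  m <- matrix(rpois(n * 6, 30) + 1L, n, 6)
  cm <- count_matrix(m, paste0("g", 1:6), rep(100, 6), paste0("s", 1:n))
  meta <- sample_metadata(paste0("s", 1:n), rep("liver", n), rep("st", n),
                          paste0("acc", 1:n))
  meta$is_cell_line[1] <- TRUE
  res <- qc_filter(cm, meta, tiny_annot(), "liver")
  expect_equal(sum(res$keep), 10)
  expect_equal(unname(res$criterion_counts["cell_line"]), 1)

  # one sample matches both high-zero (>30% of the 4 O genes) and the
  # duplicate-accession rule; it is removed once, both counts include it
  meta2 <- meta; cm2 <- cm
  cm2$counts[2, 1:2] <- 0L               # 2/4 = 50% zeros among O genes
  meta2$accession[2] <- meta2$accession[3]
  res2 <- qc_filter(cm2, meta2, tiny_annot(), "liver")
  expect_equal(sum(!res2$keep), 3)        # s1, s2, s3
  expect_equal(unname(res2$criterion_counts["high_zero_fraction"]), 1)
  expect_equal(unname(res2$criterion_counts["duplicate_accession"]), 2)

  # exactly 30% zeros is kept: rule is strictly 'more than 30%'
  cm3 <- count_matrix(matrix(rpois(10, 30) + 1L, 1, 10), paste0("g", 1:10),
                      rep(100, 10), "sx")
  cm3$counts[1, 1:3] <- 0L               # 3/10 of O genes
  annot10 <- gene_annotation(paste0("g", 1:10), rep(TRUE, 10),
                             rep(FALSE, 10))
  metax <- sample_metadata("sx", "liver", "st", "accx")
  expect_true(qc_filter(cm3, metax, annot10, "liver")$keep)
})

test_that("qc removal equals the brute-force union of criterion matches", {
  set.seed(17)
  for (rep in 1:5) {
    n <- 30
    m <- matrix(rpois(n * 6, 20) + 1L, n, 6)
    cm <- count_matrix(m, paste0("g", 1:6), rep(100, 6), paste0("s", 1:n))
    meta <- sample_metadata(paste0("s", 1:n),
                            sample(c("liver", "alien"), n, TRUE),
                            rep("st", n),
                            sample(paste0("acc", 1:25), n, TRUE),
                            is_cell_line = runif(n) < 0.2,
                            is_single_cell = runif(n) < 0.1)
    zero_rows <- sample(n, 5)
    cm$counts[zero_rows, 1:2] <- 0L
    res <- qc_filter(cm, meta, tiny_annot(), "liver")
    union_set <- Reduce(union, apply(res$matches, 2, which))
    expect_equal(sum(!res$keep), length(union_set))
    expect_equal(res$criterion_counts, colSums(res$matches))
  }
})

test_that("gene-set restriction subsets without renormalizing", {
  cm <- tiny_counts()
  expect_identical(select_gene_set(cm, tiny_annot(), "all")$counts,
                   cm$counts)
  ot <- select_gene_set(cm, tiny_annot(), "OT")
  expect_equal(ncol(ot$counts), 2)
  expect_equal(ot$gene_lengths, cm$gene_lengths[1:2])

  clr <- to_clr(to_tpm(cm, pseudocount = 0.5))
  sub <- select_gene_set(clr, tiny_annot(), "O")
  expect_equal(sub$gene_set, "O")
  expect_gt(max(abs(rowSums(sub$values))), 1e-6)   # not recomputed

  empty <- gene_annotation(paste0("g", 1:6), rep(FALSE, 6), rep(FALSE, 6))
  expect_error(select_gene_set(cm, empty, "O"), "empty")
})

test_that("tissue reference recovers moments and floors the std", {
  v <- matrix(rep(c(1, 2, 3), 2), 2, 3, byrow = TRUE)
  em <- expression_matrix(v, "CLR")
  meta <- sample_metadata(c("a", "b"), c("liver", "liver"), "st",
                          c("x", "y"))
  ref <- build_tissue_reference(em, meta, c(TRUE, TRUE))
  expect_equal(as.numeric(ref$mean["liver", ]), c(1, 2, 3))
  expect_equal(as.numeric(ref$sd["liver", ]), rep(1e-6, 3))

  expect_error(build_tissue_reference(em, meta, c(TRUE, FALSE)),
               "fewer than 2")

  # sample-moment oracle at n = 500
  set.seed(5)
  mu <- c(-1, 0, 2); sd <- c(0.5, 1, 2)
  big <- sapply(1:3, function(j) rnorm(500, mu[j], sd[j]))
  ref2 <- build_tissue_reference(
    expression_matrix(big, "CLR"),
    sample_metadata(paste0("s", 1:500), rep("lung", 500), "st",
                    paste0("a", 1:500)),
    rep(TRUE, 500))
  expect_equal(as.numeric(ref2$mean["lung", ]), mu, tolerance = 0.15)
  expect_equal(as.numeric(ref2$sd["lung", ]), sd, tolerance = 0.15)
})

test_that("Z-score standardizes against the tissue reference", {
  ref <- structure(list(mean = matrix(c(1, 2), 1, 2,
                                      dimnames = list("liver", NULL)),
                        sd = matrix(c(0.5, 2), 1, 2,
                                    dimnames = list("liver", NULL)),
                        epsilon = 1e-6),
                   class = "tissue_reference")
  meta <- sample_metadata("s1", "liver", "st", "a1")
  at_mean <- to_zscore(expression_matrix(matrix(c(1, 2), 1, 2), "CLR"),
                       meta, ref)
  expect_equal(as.numeric(at_mean$values), c(0, 0))
  plus_sd <- to_zscore(expression_matrix(matrix(c(1.5, 4), 1, 2), "CLR"),
                       meta, ref)
  expect_equal(as.numeric(plus_sd$values), c(1, 1))

  meta_bad <- sample_metadata("s1", "brain", "st", "a1")
  expect_error(to_zscore(expression_matrix(matrix(c(1, 2), 1, 2), "CLR"),
                         meta_bad, ref), "brain")
})

test_that("Z-scores of reference samples have mean 0 and sd 1 per tissue", {
  sim <- small_sim()
  z <- sim$norms$`Z-score`$values[sim$ds$meta$is_reference, ]
  tis <- sim$ds$meta$tissue[sim$ds$meta$is_reference]
  for (t in unique(tis)) {
    zt <- z[tis == t, ]
    expect_lt(max(abs(colMeans(zt))), 0.05)
    expect_equal(mean(apply(zt, 2, sd)), 1, tolerance = 0.05)
  }
})

test_that("ternarization thresholds as declared and is idempotent", {
  z <- expression_matrix(matrix(c(-3, 0, 2.5, 2, -2, 1.99), 2, 3), "Z-score")
  t3 <- to_zternary(z)
  expect_equal(as.numeric(t3$values), c(-1, 0, 1, 0, 0, 0))
  expect_true(all(t3$values %in% c(-1, 0, 1)))
  expect_identical(to_zternary(t3)$values, t3$values)

  allsmall <- to_zternary(expression_matrix(matrix(runif(6, -2, 2), 2, 3),
                                            "Z-score"))
  expect_true(all(allsmall$values == 0))
})
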