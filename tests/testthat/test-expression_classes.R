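test_that("category rules reproduce the worked classification examples", {
  expect_equal(as.character(classify_category(10, 4, 1, 1)), "mitosis")
  expect_equal(as.character(classify_category(1, 3, 1, 0.5)), "meiosisI")
  expect_equal(as.character(classify_category(1, 3, 3, 2.5)), "persistent")
  expect_equal(as.character(classify_category(5, 4, 4, 4)), "unclassified")
  # ties at exactly the fold threshold do not qualify
  expect_equal(as.character(classify_category(8, 4, 1, 1)), "unclassified")
  out <- classify_category(0, 0, 0, 0)
  expect_equal(as.character(out), "unclassified")
  expect_true(attr(out, "silent"))
  expect_error(classify_category(-1, 1, 1, 1), "non-negative")
})

test_that("classification is scale-invariant and categories are exclusive", {
  set.seed(20)
  for (i in 1:200) {
    v <- rlnorm(4, 1, 1.5)
    k <- runif(1, 0.01, 100)
    a <- as.character(classify_category(v[1], v[2], v[3], v[4]))
    b <- as.character(classify_category(k * v[1], k * v[2], k * v[3],
                                        k * v[4]))
    expect_identical(a, b)
    # at most one named category can claim the gene: check by testing the
    # defining predicates independently
    fold <- 2
    mit <- v[1] > fold * v[2]
    mei <- v[2] > fold * v[1] && v[2] > fold * v[3]
    per <- v[2] > fold * v[1] && v[3] / v[2] >= 0.5 && v[3] / v[2] <= 2 &&
      v[4] / v[2] >= 0.5 && v[4] / v[2] <= 2
    expect_lte(mit + mei + per, 1)
    expect_equal(a, c("mitosis", "meiosisI", "persistent",
                      "unclassified")[which(c(mit, mei, per, TRUE))[1]])
  }
})

test_that("BH adjustment matches the textbook step-up procedure", {
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
  set.seed(33)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_fdr(p)
    expect_equal(q, bh_step_up_oracle(p))
    # permutation equivariance
    o <- sample(length(p))
    expect_equal(bh_fdr(p[o]), q[o])
    # q-values non-decreasing in the p-value ranking, capped at 1
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q <= 1))
  }
})

test_that("the DE filter applies both thresholds strictly", {
  expect_true(de_filter(0.4, 0.01))
  expect_false(de_filter(0.5, 0.01))
  expect_false(de_filter(0.4, 0.05))
  expect_false(de_filter(0.6, 0.2))
  th <- de_thresholds(max_fold = 0.8, max_fdr = 0.1)
  expect_true(de_filter(0.79, 0.09, th))
})

test_that("de_test recovers planted folds and handles degenerate groups", {
  genes <- sprintf("g%02d", 1:20)
  mk <- function(means, reps = 3) {
    m <- matrix(rep(round(means), reps), ncol = reps,
                dimnames = list(genes, NULL))
    storage.mode(m) <- "integer"
    m
  }
  spikes <- matrix(1000L, 2, 6,
                   dimnames = list(c("ERCC-1", "ERCC-2"), NULL))
  means <- seq(100, 2000, length.out = 20)
  counts <- rbind(cbind(mk(means), mk(means * 0.2)), spikes)
  colnames(counts) <- sprintf("s%d", 1:6)
  meta <- data.frame(sample_id = colnames(counts),
                     cell_type = "primary_spermatocyte", genotype =
                       rep(c("control", "mutant"), each = 3),
                     n_cells = 100L, rel_volume = 1, replicate = rep(1:3, 2),
                     stringsAsFactors = FALSE)
  ct <- count_table(counts, startsWith(rownames(counts), "ERCC-"), meta)
  res <- de_test(ct)
  expect_true(all(abs(res$fold_change - 0.2) / 0.2 < 0.05))
  # zero within-group variance with separated means: degenerate p = 0
  expect_true(all(res$p_value == 0))

  # identical groups: fold exactly 1, p exactly 1
  counts2 <- rbind(cbind(mk(means), mk(means)), spikes)
  colnames(counts2) <- sprintf("s%d", 1:6)
  ct2 <- count_table(counts2, startsWith(rownames(counts2), "ERCC-"), meta)
  res2 <- de_test(ct2)
  expect_true(all(res2$fold_change == 1))
  expect_true(all(res2$p_value == 1))

  # mutant all zeros: pseudocount keeps the fold above 0 but below 1
  counts3 <- rbind(cbind(mk(means), mk(rep(0, 20))), spikes)
  colnames(counts3) <- sprintf("s%d", 1:6)
  ct3 <- count_table(counts3, startsWith(rownames(counts3), "ERCC-"), meta)
  res3 <- de_test(ct3)
  expect_true(all(res3$fold_change > 0 & res3$fold_change < 1))

  meta1 <- meta[c(1, 4:6), ]
  ct4 <- count_table(counts[, c(1, 4:6)],
                     startsWith(rownames(counts), "ERCC-"), meta1)
  expect_error(de_test(ct4), "replicates")
})

test_that("de_test p-values agree with stats::t.test on noisy genes", {
  set.seed(55)
  genes <- sprintf("g%02d", 1:10)
  counts <- rbind(
    matrix(rnbinom(60, mu = 500, size = 10), nrow = 10,
           dimnames = list(genes, NULL)),
    matrix(1000L, 1, 6, dimnames = list("ERCC-1", NULL)))
  colnames(counts) <- sprintf("s%d", 1:6)
  storage.mode(counts) <- "integer"
  meta <- data.frame(sample_id = colnames(counts),
                     cell_type = "primary_spermatocyte",
                     genotype = rep(c("control", "mutant"), each = 3),
                     n_cells = 100L, rel_volume = 1,
                     replicate = rep(1:3, 2), stringsAsFactors = FALSE)
  ct <- count_table(counts, startsWith(rownames(counts), "ERCC-"), meta)
  res <- de_test(ct)
  norm <- counts[1:10, ]  # spike sums equal, so normalization is identity
  for (g in c(1, 5, 10)) {
    a <- log2(norm[g, 1:3] + 0.5)
    b <- log2(norm[g, 4:6] + 0.5)
    expect_equal(res$p_value[g], t.test(a, b)$p.value, tolerance = 1e-12)
  }
})

test_that("the DE filter is conservative under the global null", {
  # planted fold 1.0 everywhere, negative-binomial noise, BH at 0.05
  n_false <- 0L; n_total <- 0L
  for (sd in 1:8) {
    cfg <- sim_config(n_genes = 500L, chrom_sizes = c(chr1 = 2e7),
                      seed = sd, de_fraction = 0, dispersion = 0.05)
    ann <- gen_annotation(cfg)
    truth <- gen_truth(ann, cfg)
    res <- de_test(gen_de_dataset(ann, truth, cfg))
    q <- bh_fdr(res$p_value)
    n_false <- n_false + sum(q < 0.05)
    n_total <- n_total + length(q)
  }
  se <- sqrt(0.05 * 0.95 / n_total)
  expect_lte(n_false / n_total, 0.05 + 3 * se)
})
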