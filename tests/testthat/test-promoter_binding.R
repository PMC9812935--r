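test_that("signed distances follow gene orientation", {
  expect_equal(signed_distance(1000, "+", 1000), 0)
  expect_equal(signed_distance(1000, "+", 1300), 300)
  expect_equal(signed_distance(1000, "-", 1300), -300)
  expect_equal(signed_distance(1000, "-", 700), 300)
  expect_error(signed_distance(1000, ".", 700), "strand")
})

test_that("nearest summit minimizes |distance| with deterministic ties", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                     tss = 1000L, gene_length = 500L, biotype = NA,
                     stringsAsFactors = FALSE)
  pk <- make_peaks("chr1", c(450L, 1600L))
  res <- nearest_summit(gene, pk)
  expect_equal(res$distance, -550)
  expect_equal(res$peak$summit, 450L)

  # equidistant: upstream wins
  pk2 <- make_peaks("chr1", c(300L, 1700L))
  expect_equal(nearest_summit(gene, pk2)$distance, -700)
  # equidistant and equal summits: smaller start wins
  pk3 <- rbind(make_peaks("chr1", 900L, start = 800L, end = 1001L),
               make_peaks("chr1", 900L, start = 700L, end = 1001L))
  expect_equal(nearest_summit(gene, pk3)$peak$start, 700L)
  # minus strand: upstream means summit > tss
  gene_m <- transform(gene, strand = "-")
  expect_equal(nearest_summit(gene_m, pk2)$distance, -700)
  expect_equal(nearest_summit(gene_m, pk2)$peak$summit, 1700L)

  expect_null(nearest_summit(gene, pk[0, ]))
  expect_null(nearest_summit(gene, make_peaks("chr2", 1000L)))
})

test_that("the promoter window is inclusive at its boundary", {
  gene <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                     tss = 1000L, gene_length = 500L, biotype = NA,
                     stringsAsFactors = FALSE)
  expect_true(has_promoter_peak(gene, make_peaks("chr1", 1000L)))
  expect_true(has_promoter_peak(gene, make_peaks("chr1", 1500L), 500))
  expect_true(has_promoter_peak(gene, make_peaks("chr1", 500L), 500))
  expect_false(has_promoter_peak(gene, make_peaks("chr1", 1501L), 500))
  expect_false(has_promoter_peak(gene, make_peaks("chr1", 499L), 500))
})

test_that("evidence combination matches the stated per-TF rules", {
  expect_true(combine_evidence("TCFL5", c(TRUE, TRUE), c(FALSE, FALSE, FALSE)))
  expect_true(combine_evidence("TCFL5", c(TRUE, FALSE), c(TRUE, TRUE, FALSE)))
  expect_false(combine_evidence("TCFL5", c(TRUE, FALSE), c(TRUE, FALSE, FALSE)))
  expect_false(combine_evidence("TCFL5", c(FALSE, FALSE), c(TRUE, TRUE, TRUE)))
  expect_true(combine_evidence("A-MYB", c(FALSE, TRUE), TRUE))
  expect_false(combine_evidence("A-MYB", c(FALSE, TRUE), FALSE))

  # exhaustive agreement with the hand-written rule oracles
  grid2 <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE))
  grid3 <- expand.grid(a = c(TRUE, FALSE), b = c(TRUE, FALSE),
                       c = c(TRUE, FALSE))
  for (i in seq_len(nrow(grid2))) {
    cr <- unlist(grid2[i, ])
    for (j in seq_len(nrow(grid3))) {
      ch <- unlist(grid3[j, ])
      expect_identical(combine_evidence("TCFL5", cr, ch),
                       tcfl5_rule_oracle(cr, ch))
    }
    for (ch1 in c(TRUE, FALSE)) {
      expect_identical(combine_evidence("A-MYB", cr, ch1),
                       amyb_rule_oracle(cr, ch1))
    }
  }

  expect_error(combine_evidence("TCFL5", c(TRUE, TRUE, TRUE),
                                c(TRUE, TRUE, FALSE)), "expected 2")
  expect_error(combine_evidence("NANOG", c(TRUE, TRUE), TRUE), "rule")
})

test_that("interval-index window assignment equals the exhaustive scan", {
  set.seed(77)
  for (rep in 1:10) {
    n_genes <- 100L
    n_peaks <- sample(c(10L, 300L, 2000L), 1)
    ann <- data.frame(gene_id = sprintf("g%03d", 1:n_genes),
                      chrom = sample(c("chr1", "chr2"), n_genes, TRUE),
                      strand = sample(c("+", "-"), n_genes, TRUE),
                      tss = sample.int(1e6, n_genes),
                      gene_length = 1000L, biotype = NA,
                      stringsAsFactors = FALSE)
    pk <- make_peaks(sample(c("chr1", "chr2"), n_peaks, TRUE),
                     sample.int(1e6, n_peaks, replace = TRUE))
    for (i in seq_len(n_genes)) {
      gene <- ann[i, ]
      brute <- any(pk$chrom == gene$chrom &
                     abs(pk$summit - gene$tss) <= 500)
      expect_identical(has_promoter_peak(gene, pk, 500L), brute)
    }
  }
})

test_that("strand flips negate distances but never change membership", {
  set.seed(88)
  for (i in 1:50) {
    tss <- sample.int(1e5, 1)
    summits <- sample.int(1e5, 20)
    dp <- signed_distance(tss, "+", summits)
    dm <- signed_distance(tss, "-", summits)
    expect_equal(dp, -dm)
    gene_p <- data.frame(gene_id = "g", chrom = "chr1", strand = "+",
                         tss = tss, gene_length = 1L, biotype = NA)
    gene_m <- transform(gene_p, strand = "-")
    pk <- make_peaks("chr1", summits)
    w <- sample.int(2000, 1)
    expect_identical(has_promoter_peak(gene_p, pk, w),
                     has_promoter_peak(gene_m, pk, w))
    # enlarging the window never revokes membership
    if (has_promoter_peak(gene_p, pk, w))
      expect_true(has_promoter_peak(gene_p, pk, w + sample.int(1000, 1)))
  }
})

test_that("binding calls recover planted truth on clean synthetic data", {
  cfg <- sim_config(n_genes = 300L, chrom_sizes = c(chr1 = 1e7, chr2 = 1e7),
                    seed = 21L, jitter_bp = 300L, replicate_dropout = 0,
                    dispersion = 0, decoys_per_gene = 1)
  ann <- gen_annotation(cfg)
  truth <- gen_truth(ann, cfg)
  pks <- gen_peaks(ann, truth, cfg)
  calls <- call_binding(ann, pks)
  for (tf in c("TCFL5", "A-MYB")) {
    sub <- calls[calls$tf == tf, ]
    tb <- truth[[paste0("bound_", tf)]][match(sub$gene_id, truth$gene_id)]
    expect_equal(sum(sub$bound & tb) / sum(tb), 1, label = tf)
    expect_equal(sum(!sub$bound & !tb) / sum(!tb), 1, label = tf)
  }

  # zero jitter: median |nearest distance| among bound genes is 0
  cfg0 <- sim_config(n_genes = 300L, chrom_sizes = c(chr1 = 1e7),
                     seed = 22L, jitter_bp = 0L, replicate_dropout = 0,
                     decoys_per_gene = 0.2)
  ann0 <- gen_annotation(cfg0)
  truth0 <- gen_truth(ann0, cfg0)
  calls0 <- call_binding(ann0, gen_peaks(ann0, truth0, cfg0))
  s <- binding_summary(calls0)
  expect_equal(s$per_tf$median_abs_distance, c(0, 0))

  expect_equal(nrow(call_binding(ann[0, ], pks)), 0L)
})

test_that("undeclared replicates in a peak set are rejected", {
  ann <- tiny_genes()
  pk <- make_peaks("chr1", 1000L, tf = "TCFL5", assay = "cutrun",
                   replicate = 3L)
  expect_error(call_binding(ann, pk), "beyond the declared")
})

test_that("binding summaries report per-category bound fractions", {
  ann <- tiny_genes()
  pk <- rbind(make_peaks("chr1", 1000L, replicate = 1L),
              make_peaks("chr1", 1000L, replicate = 2L),
              make_peaks("chr1", 1000L, tf = "A-MYB", replicate = 1L),
              make_peaks("chr1", 1000L, tf = "A-MYB", replicate = 2L))
  calls <- call_binding(ann, pk)
  categ <- data.frame(gene_id = c("gA", "gB", "gC"),
                      category = c("mitosis", "mitosis", "meiosisI"),
                      stringsAsFactors = FALSE)
  s <- binding_summary(calls, categ)
  tcf <- s$per_category[s$per_category$tf == "TCFL5", ]
  expect_equal(tcf$fraction_bound[tcf$category == "mitosis"], 0.5)
  expect_equal(tcf$fraction_bound[tcf$category == "meiosisI"], 0)
})
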