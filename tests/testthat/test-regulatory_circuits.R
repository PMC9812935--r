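test_that("graphs are assembled from bound genes with merged provenance", {
  calls <- data.frame(
    gene_id = rep(c("g1", "g2"), 2),
    tf = rep(c("TCFL5", "A-MYB"), each = 2),
    n_cutrun = 2L, n_chip = 0L,
    bound = c(TRUE, FALSE, TRUE, TRUE),
    nearest_distance = 0, stringsAsFactors = FALSE)
  g <- build_graph(calls, c("TCFL5", "A-MYB"))
  expect_equal(nrow(g$edges), 3L)
  expect_true(all(g$edges$sign == "+"))

  # no bound genes: nodes only
  calls0 <- transform(calls, bound = FALSE)
  g0 <- build_graph(calls0, c("TCFL5", "A-MYB"))
  expect_equal(nrow(g0$edges), 0L)
  expect_setequal(g0$nodes, c("TCFL5", "A-MYB"))

  # duplicate user edge collapses with both provenances
  g2 <- build_graph(calls, c("TCFL5", "A-MYB"),
                    user_edges = data.frame(source = "TCFL5", target = "g1",
                                            sign = "+"))
  e <- g2$edges[g2$edges$source == "TCFL5" & g2$edges$target == "g1", ]
  expect_equal(nrow(e), 1L)
  expect_equal(e$provenance, "binding_call+user_asserted")

  expect_error(build_graph(calls, c("TCFL5", "SOX30")), "SOX30")
})

test_that("feedforward loops are typed by the standard taxonomy", {
  e <- data.frame(source = c("X", "X", "Y"), target = c("Y", "Z", "Z"),
                  sign = "+", provenance = "user_asserted",
                  stringsAsFactors = FALSE)
  res <- find_coherent_ffls(graph_from_edges(e))
  expect_equal(nrow(res$ffls), 1L)
  expect_equal(res$ffls$type, "C1")
  expect_true(res$ffls$coherent)

  # X->Y:+, Y->Z:-, X->Z:- is coherent type C3
  e2 <- e; e2$sign <- c("+", "-", "-")
  res2 <- find_coherent_ffls(graph_from_edges(e2))
  expect_equal(res2$ffls$type, "C3")
  expect_true(res2$ffls$coherent)
  # X->Y:+, Y->Z:+, X->Z:- is incoherent
  e3 <- e; e3$sign <- c("+", "-", "+")
  expect_false(find_coherent_ffls(graph_from_edges(e3))$ffls$coherent)

  # a bare chain is no loop
  chain <- e[c(1, 3), ]
  expect_equal(nrow(find_coherent_ffls(graph_from_edges(chain))$ffls), 0L)
})

test_that("triad enumeration equals brute force on random signed graphs", {
  for (sd in 1:20) {
    edges <- random_signed_graph(20L, 0.2, seed = 1000 + sd)
    res <- find_coherent_ffls(graph_from_edges(edges))
    got <- res$ffls[, c("x", "y", "z", "sign_xy", "sign_yz", "sign_xz")]
    rownames(got) <- NULL
    want <- ffl_brute_force(edges)
    expect_equal(got, want)
    # coherence definition re-checked independently
    prod <- ifelse(res$ffls$sign_xy == res$ffls$sign_yz, "+", "-")
    expect_equal(res$ffls$coherent, prod == res$ffls$sign_xz)
  }
})

test_that("autoregulation and mutual positive feedback are reported", {
  e <- data.frame(source = c("A", "A", "B", "B", "C"),
                  target = c("A", "B", "A", "C", "B"),
                  sign = c("+", "+", "+", "-", "-"),
                  provenance = "user_asserted", stringsAsFactors = FALSE)
  res <- find_coherent_ffls(graph_from_edges(e))
  expect_equal(res$autoregulation$node, "A")
  expect_equal(nrow(res$mutual_feedback), 2L)
  ab <- res$mutual_feedback[res$mutual_feedback$a == "A", ]
  expect_true(ab$positive)
  bc <- res$mutual_feedback[res$mutual_feedback$a == "B", ]
  expect_false(bc$positive)
})

test_that("the asserted meiotic architecture forms coherent loops over shared targets", {
  targets <- sprintf("t%d", 1:5)
  e <- rbind(
    data.frame(source = "STRA8", target = "A-Myb", sign = "+"),
    data.frame(source = "MEIOSIN", target = "A-Myb", sign = "+"),
    data.frame(source = "MEIOSIN", target = "Tcfl5", sign = "+"),
    data.frame(source = "A-Myb", target = "Tcfl5", sign = "+"),
    data.frame(source = "A-Myb", target = targets, sign = "+"),
    data.frame(source = "Tcfl5", target = targets, sign = "+"))
  e$provenance <- "user_asserted"
  res <- find_coherent_ffls(graph_from_edges(e))
  loops <- res$coherent
  for (t in targets) {
    hit <- loops[loops$x == "A-Myb" & loops$y == "Tcfl5" & loops$z == t, ]
    expect_equal(nrow(hit), 1L, label = t)
    expect_equal(hit$type, "C1")
  }
  # MEIOSIN -> A-Myb -> Tcfl5 with the direct MEIOSIN -> Tcfl5 edge
  expect_true(any(loops$x == "MEIOSIN" & loops$y == "A-Myb" &
                    loops$z == "Tcfl5"))
})

test_that("binding enrichment builds the 2x2 test correctly", {
  # perfectly independent table: statistic 0
  uni <- sprintf("g%02d", 1:40)
  gs <- uni[1:20]
  bs <- uni[c(1:10, 21:30)]
  res <- binding_enrichment(gs, bs, uni)
  expect_equal(res$statistic, 0)
  expect_equal(unname(as.vector(res$table)), c(10, 10, 10, 10))

  # closed form n(ad-bc)^2 / (row and column products) on [[20,10],[10,20]]
  uni2 <- sprintf("g%02d", 1:60)
  gs2 <- uni2[1:30]
  bs2 <- uni2[c(1:20, 31:40)]
  res2 <- binding_enrichment(gs2, bs2, uni2)
  expect_equal(res2$statistic, 60 * (20 * 20 - 10 * 10)^2 /
                 (30 * 30 * 30 * 30))
  expect_equal(round(res2$statistic, 4), 6.6667)
  expect_equal(res2$p_value,
               stats::pchisq(res2$statistic, 1, lower.tail = FALSE))
  expect_true(is.na(res2$exact_p))  # all expected cells >= 5

  # invariance to transposition of the table roles
  res2t <- binding_enrichment(bs2, gs2, uni2)
  expect_equal(res2t$statistic, res2$statistic)

  # small expected counts trigger the exact companion p-value
  uni3 <- sprintf("g%02d", 1:30)
  res3 <- binding_enrichment(uni3[1:3], uni3[c(1:3, 10:12)], uni3)
  expect_false(is.na(res3$exact_p))
  expect_equal(res3$exact_p,
               stats::fisher.test(res3$table)$p.value)

  # degenerate margin: flagged, statistic zero
  expect_warning(res4 <- binding_enrichment(uni3, uni3[1:5], uni3),
                 "degenerate")
  expect_equal(res4$statistic, 0)
  expect_true(res4$degenerate)

  expect_error(binding_enrichment(c("x"), c("x"), c("x")), "universe")
  expect_error(binding_enrichment(c("zz"), uni3[1], uni3), "subset")
})

test_that("motif scanning handles both strands and rejects bad patterns", {
  hits <- scan_motif("TACGACGA", "WANSWCGW", both_strands = FALSE)
  expect_equal(hits$position, 0L)
  expect_equal(hits$strand, "+")
  expect_equal(nrow(scan_motif("GGGGGGGG", "WANSWCGW")), 0L)
  rc <- scan_motif("TCGTCGTA", "WANSWCGW")
  expect_equal(rc$position, 0L)
  expect_equal(rc$strand, "-")
  expect_error(scan_motif("ACGT", "WXNS"), "IUPAC")
  expect_error(scan_motif("ACGU", "WANS"), "nucleotide")
  # pattern longer than sequence: no hits, no error
  expect_equal(nrow(scan_motif("ACG", "WANSWCGW")), 0L)
  # an N in the sequence is fully ambiguous
  expect_equal(scan_motif("NNNNNNNN", "WANSWCGW",
                          both_strands = FALSE)$position, 0L)
})

test_that("motif scanning matches a regex-expansion oracle on random sequences", {
  set.seed(99)
  patterns <- c("WANSWCGW", "ACGT", "NRYK")
  for (i in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
    for (pat in patterns) {
      hits <- scan_motif(seq, pat, both_strands = TRUE)
      plus <- iupac_regex_hits(seq, pat)
      # minus-strand oracle: pattern matched on the reverse complement,
      # mapped back to plus-strand coordinates of the match start
      rc_hits <- iupac_regex_hits(revcomp_chr(seq), pat)
      minus <- sort(nchar(seq) - rc_hits - nchar(pat))
      expect_equal(hits$position[hits$strand == "+"], plus, label = pat)
      expect_equal(hits$position[hits$strand == "-"], minus, label = pat)
    }
  }
})
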