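# Shared fixtures and independent oracles for the test suite.

tiny_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(1000L, 5000L, 2000L),
    gene_length = c(500L, 1500L, 1000L),
    biotype = "protein_coding",
    stringsAsFactors = FALSE)
}

make_peaks <- function(chrom, summit, tf = "TCFL5", assay = "cutrun",
                       replicate = 1L, start = summit - 150L,
                       end = summit + 151L, score = 10) {
  data.frame(chrom = chrom, start = start, end = end, summit = summit,
             score = score, tf = tf, assay = assay,
             replicate = as.integer(replicate), stringsAsFactors = FALSE)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Textbook Benjamini-Hochberg step-up, written directly from its
# definition: sorted q_i = min_{j >= i} p_(j) * m / j, capped at 1.
bh_step_up_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(ps[i:m] * m / (i:m), 1)
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# IUPAC -> regex character classes; overlapping matches via lookahead.
iupac_regex_hits <- function(sequence, pattern) {
  classes <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
               S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]",
               B = "[CGT]", D = "[AGT]", H = "[ACT]", V = "[ACG]",
               N = "[ACGT]")
  rx <- paste0("(?=", paste(classes[strsplit(pattern, "")[[1]]],
                            collapse = ""), ")")
  m <- gregexpr(rx, sequence, perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m) - 1L
}

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", s), "")[[1]]),
        collapse = "")
}

# Evidence-rule oracles transcribed directly from the stated rules.
tcfl5_rule_oracle <- function(cutrun, chip) {
  (sum(cutrun) == 2) ||
    (sum(cutrun) >= 1 && sum(chip) >= 2)
}
amyb_rule_oracle <- function(cutrun, chip) {
  (sum(cutrun) == 2) ||
    (sum(cutrun) >= 1 && sum(chip) >= 1)
}

# Brute-force enumeration of feedforward-loop triads by triple loop.
ffl_brute_force <- function(edges) {
  key <- paste0(edges$source, "\r", edges$target)
  sign_of <- setNames(edges$sign, key)
  nodes <- unique(c(edges$source, edges$target))
  out <- list()
  for (x in nodes) for (y in nodes) for (z in nodes) {
    if (x == y || y == z || x == z) next
    kxy <- paste0(x, "\r", y); kyz <- paste0(y, "\r", z)
    kxz <- paste0(x, "\r", z)
    if (kxy %in% key && kyz %in% key && kxz %in% key) {
      out[[length(out) + 1L]] <- data.frame(
        x = x, y = y, z = z, sign_xy = sign_of[[kxy]],
        sign_yz = sign_of[[kyz]], sign_xz = sign_of[[kxz]],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(x = character(), y = character(), z = character(),
                      sign_xy = character(), sign_yz = character(),
                      sign_xz = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$x, res$y, res$z), ]
  rownames(res) <- NULL
  res
}

random_signed_graph <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- expand.grid(source = nodes, target = nodes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  keep <- runif(nrow(pairs)) < p_edge
  e <- pairs[keep, ]
  e$sign <- sample(c("+", "-"), nrow(e), replace = TRUE)
  e$provenance <- "user_asserted"
  rownames(e) <- NULL
  e
}

graph_from_edges <- function(edges) {
  structure(list(nodes = unique(c(edges$source, edges$target)),
                 edges = edges),
            class = "regulatory_graph")
}
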