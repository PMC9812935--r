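# Signed TF -> target regulatory graphs: feedforward-loop and feedback
# enumeration, gene-set binding enrichment, and IUPAC consensus motif
# scanning.

#' Build a signed regulatory graph from binding calls
#'
#' An edge `(tf, gene, sign)` exists for every bound gene of every TF;
#' binding-derived edges default to activating (`+`), the interpretation
#' the circuit analysis takes for A-MYB and TCFL5. User-asserted edges
#' (e.g. STRA8 -> A-Myb from re-analyzed external ChIP-seq) can be
#' merged; duplicate source/target pairs collapse into one edge with
#' both provenances, and a sign conflict is an error.
#'
#' @param binding_calls Output of [call_binding()].
#' @param tf_list TFs whose calls become edges; each must appear in the
#'   calls.
#' @param sign_map Optional named vector of `"+"`/`"-"` per TF.
#' @param user_edges Optional data frame `source`, `target`, `sign`.
#' @return Object of class `regulatory_graph` with `nodes` and `edges`.
#' @export
build_graph <- function(binding_calls, tf_list, sign_map = NULL,
                        user_edges = NULL) {
  if (is.null(sign_map))
    sign_map <- stats::setNames(rep("+", length(tf_list)), tf_list)
  edges <- list()
  for (tf in tf_list) {
    sub <- binding_calls[binding_calls$tf == tf, , drop = FALSE]
    if (nrow(sub) == 0L)
      stopf("no binding calls for transcription factor '%s'", tf)
    b <- sub[sub$bound, , drop = FALSE]
    if (nrow(b))
      edges[[tf]] <- data.frame(source = tf, target = b$gene_id,
                                sign = unname(sign_map[[tf]] %||% "+"),
                                provenance = "binding_call",
                                stringsAsFactors = FALSE)
  }
  e <- if (length(edges)) do.call(rbind, edges)
  else data.frame(source = character(), target = character(),
                  sign = character(), provenance = character(),
                  stringsAsFactors = FALSE)
  if (!is.null(user_edges)) {
    miss <- setdiff(c("source", "target", "sign"), names(user_edges))
    if (length(miss))
      stopf("user_edges lacks column(s): %s", paste(miss, collapse = ", "))
    e <- rbind(e, data.frame(source = user_edges$source,
                             target = user_edges$target,
                             sign = user_edges$sign,
                             provenance = "user_asserted",
                             stringsAsFactors = FALSE))
  }
  if (!all(e$sign %in% c("+", "-")))
    stopf("edge signs must be '+' or '-'")
  key <- edge_key(e$source, e$target)
  if (anyDuplicated(key)) {
    parts <- split(e, key)
    e <- do.call(rbind, lapply(parts, function(g) {
      if (length(unique(g$sign)) > 1)
        stopf("conflicting signs for edge %s -> %s", g$source[1], g$target[1])
      data.frame(source = g$source[1], target = g$target[1],
                 sign = g$sign[1],
                 provenance = paste(sort(unique(g$provenance)),
                                    collapse = "+"),
                 stringsAsFactors = FALSE)
    }))
  }
  e <- e[order(e$source, e$target), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = sort(unique(c(tf_list, e$source, e$target))),
                 edges = e),
            class = "regulatory_graph")
}

#' @export
print.regulatory_graph <- function(x, ...) {
  cat(sprintf("regulatory_graph: %d nodes, %d signed edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

mult_sign <- function(s1, s2) ifelse(s1 == s2, "+", "-")

# paste0 recycles zero-length inputs against the length-1 separator, so
# an empty edge list must short-circuit to character(0).
edge_key <- function(a, b) {
  if (length(a) == 0L) return(character(0))
  paste0(a, "\r", b)
}

# Standard 8-type feedforward-loop taxonomy keyed by the signs of
# X->Y, Y->Z, X->Z. Coherent types: the direct edge sign equals the
# product of the indirect path's signs.
ffl_type <- function(sxy, syz, sxz) {
  map <- c("+++" = "C1", "-+-" = "C2", "+--" = "C3", "--+" = "C4",
           "++-" = "I1", "-++" = "I2", "+-+" = "I3", "---" = "I4")
  unname(map[paste0(sxy, syz, sxz)])
}

#' Enumerate feedforward loops and feedback motifs
#'
#' Finds every ordered triad of distinct nodes `(X, Y, Z)` with edges
#' `X -> Y`, `Y -> Z`, and `X -> Z`. A triad is coherent when
#' `sign(X -> Z) = sign(X -> Y) * sign(Y -> Z)`; each triad is labeled
#' with the standard 8-type taxonomy (C1-C4 coherent, I1-I4 incoherent).
#' Self-edges are reported separately as autoregulation, and 2-node
#' mutual edge pairs as feedback loops (flagged `positive` when both
#' directions activate).
#'
#' @param graph A [build_graph()] result.
#' @return `list(ffls, coherent, autoregulation, mutual_feedback)`.
#' @export
find_coherent_ffls <- function(graph) {
  e <- graph$edges
  auto <- e[e$source == e$target, c("source", "sign"), drop = FALSE]
  names(auto) <- c("node", "sign")
  rownames(auto) <- NULL
  en <- e[e$source != e$target, , drop = FALSE]
  key <- edge_key(en$source, en$target)
  sign_of <- stats::setNames(en$sign, key)

  rev_key <- edge_key(en$target, en$source)
  has_rev <- rev_key %in% key
  mut <- en[has_rev & en$source < en$target, , drop = FALSE]
  mutual <- data.frame(a = mut$source, b = mut$target,
                       sign_ab = mut$sign,
                       sign_ba = unname(sign_of[edge_key(mut$target,
                                                         mut$source)]),
                       stringsAsFactors = FALSE)
  mutual$positive <- mutual$sign_ab == "+" & mutual$sign_ba == "+"
  rownames(mutual) <- NULL

  ffls <- data.frame(x = character(), y = character(), z = character(),
                     sign_xy = character(), sign_yz = character(),
                     sign_xz = character(), coherent = logical(),
                     type = character(), stringsAsFactors = FALSE)
  if (nrow(en)) {
    j <- merge(data.frame(x = en$source, y = en$target, sxy = en$sign,
                          stringsAsFactors = FALSE),
               data.frame(y = en$source, z = en$target, syz = en$sign,
                          stringsAsFactors = FALSE),
               by = "y")
    j <- j[j$x != j$z, , drop = FALSE]
    if (nrow(j)) {
      sxz <- unname(sign_of[edge_key(j$x, j$z)])
      ok <- !is.na(sxz)
      j <- j[ok, , drop = FALSE]
      sxz <- sxz[ok]
      if (nrow(j)) {
        ffls <- data.frame(x = j$x, y = j$y, z = j$z, sign_xy = j$sxy,
                           sign_yz = j$syz, sign_xz = sxz,
                           coherent = sxz == mult_sign(j$sxy, j$syz),
                           type = ffl_type(j$sxy, j$syz, sxz),
                           stringsAsFactors = FALSE)
        ffls <- ffls[order(ffls$x, ffls$y, ffls$z), , drop = FALSE]
        rownames(ffls) <- NULL
      }
    }
  }
  list(ffls = ffls, coherent = ffls[ffls$coherent, , drop = FALSE],
       autoregulation = auto, mutual_feedback = mutual)
}

#' Gene-set binding enrichment
#'
#' Builds the 2x2 table (in-set vs out-of-set) x (bound vs unbound) over
#' an explicit gene universe and applies Pearson's chi-square test
#' without continuity correction. When any expected cell is below 5, an
#' exact hypergeometric p-value (Fisher's test) is reported alongside.
#' The universe is never inferred; degenerate margins (e.g. the gene set
#' equal to the universe) return a zero statistic with a warning.
#'
#' @param gene_set Genes of interest (subset of `universe`).
#' @param bound_set Bound genes (subset of `universe`).
#' @param universe All genes under consideration (>= 2).
#' @return `list(statistic, df, p_value, table, exact_p, degenerate)`.
#' @export
binding_enrichment <- function(gene_set, bound_set, universe) {
  universe <- unique(universe)
  if (length(universe) < 2) stopf("universe must contain at least 2 genes")
  if (!all(gene_set %in% universe))
    stopf("gene_set must be a subset of the universe")
  if (!all(bound_set %in% universe))
    stopf("bound_set must be a subset of the universe")
  in_set <- factor(universe %in% gene_set, levels = c(TRUE, FALSE))
  bound <- factor(universe %in% bound_set, levels = c(TRUE, FALSE))
  tab <- table(in_set = in_set, bound = bound)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warnf("degenerate 2x2 margin; enrichment undefined")
    return(list(statistic = 0, df = 1L, p_value = NA_real_, table = tab,
                exact_p = NA_real_, degenerate = TRUE))
  }
  ch <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  exact_p <- if (any(ch$expected < 5))
    stats::fisher.test(tab)$p.value else NA_real_
  list(statistic = unname(ch$statistic), df = 1L,
       p_value = unname(ch$p.value), table = tab, exact_p = exact_p,
       degenerate = FALSE)
}

iupac_codes <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' IUPAC consensus motif
#'
#' @param iupac Non-empty string over the IUPAC nucleotide alphabet,
#'   e.g. the TCFL5 consensus `"WANSWCGW"`.
#' @param name Motif name.
#' @export
motif_pattern <- function(iupac, name = "motif") {
  iupac <- toupper(iupac)
  if (!nzchar(iupac)) stopf("motif pattern must be non-empty")
  bad <- setdiff(strsplit(iupac, "")[[1]], names(iupac_codes))
  if (length(bad))
    stopf("invalid IUPAC symbol in pattern: %s", paste(bad, collapse = ", "))
  structure(list(iupac = iupac, name = name), class = "motif_pattern")
}

#' The TCFL5 consensus binding site
#'
#' `WANSWCGW` (W = A/T, S = G/C, N = any base).
#' @export
tcfl5_consensus <- function() motif_pattern("WANSWCGW", "TCFL5-consensus")

#' Scan a sequence for an IUPAC consensus motif
#'
#' Reports every 0-based offset where the degenerate pattern matches
#' (hit/no-hit; degenerate positions are not scored). Minus-strand hits
#' are matches of the pattern against the reverse complement, reported
#' at the plus-strand coordinate of the match start. An `N` in the
#' sequence is fully ambiguous and may pair with any pattern symbol.
#'
#' @param sequence Nucleotide string over `A,C,G,T,N`
#'   (case-insensitive).
#' @param pattern A [motif_pattern()] or IUPAC string.
#' @param both_strands Scan the minus strand too (default `TRUE`).
#' @return Data frame `position` (0-based), `strand`.
#' @export
scan_motif <- function(sequence, pattern, both_strands = TRUE) {
  if (!inherits(pattern, "motif_pattern")) pattern <- motif_pattern(pattern)
  sequence <- toupper(sequence)
  seq_chars <- unique(strsplit(sequence, "")[[1]])
  bad <- setdiff(seq_chars, c("A", "C", "G", "T", "N"))
  if (length(bad))
    stopf("sequence contains non-nucleotide symbol(s): %s",
          paste(bad, collapse = ", "))
  empty <- data.frame(position = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (nchar(pattern$iupac) > nchar(sequence)) return(empty)
  s <- Biostrings::DNAString(sequence)
  p <- Biostrings::DNAString(pattern$iupac)
  plus <- Biostrings::start(Biostrings::matchPattern(p, s,
                                                     fixed = FALSE)) - 1L
  hits <- data.frame(position = plus, strand = rep("+", length(plus)),
                     stringsAsFactors = FALSE)
  if (both_strands) {
    rc <- Biostrings::reverseComplement(p)
    minus <- Biostrings::start(Biostrings::matchPattern(rc, s,
                                                        fixed = FALSE)) - 1L
    hits <- rbind(hits, data.frame(position = minus,
                                   strand = rep("-", length(minus)),
                                   stringsAsFactors = FALSE))
  }
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
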