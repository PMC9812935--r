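# Stage-specific expression categories and the differential-expression
# filter with Benjamini-Hochberg FDR control.

#' Category classification rules
#'
#' `fold` is the "more than twice" threshold (strict: ties at exactly
#' the fold do not qualify). `unchanged_band` quantifies "essentially
#' unchanged" as a ratio-to-primary-spermatocyte interval, inclusive at
#' both ends.
#'
#' @param fold Fold threshold (> 1), default 2.
#' @param unchanged_band Length-2 numeric, default `c(0.5, 2)`.
#' @export
category_rules <- function(fold = 2, unchanged_band = c(0.5, 2)) {
  if (fold <= 1) stopf("fold must be > 1")
  if (length(unchanged_band) != 2 || unchanged_band[1] >= 1 ||
      unchanged_band[2] <= 1)
    stopf("unchanged_band must straddle 1")
  structure(list(fold = fold, unchanged_band = unchanged_band),
            class = "category_rules")
}

#' Differential-expression filter thresholds
#'
#' Both cuts are strict: `fold_change < max_fold` and `q_value <
#' max_fdr`.
#'
#' @param max_fold Maximum mutant/control fold change, default 0.5.
#' @param max_fdr Maximum BH-adjusted q-value, default 0.05.
#' @export
de_thresholds <- function(max_fold = 0.5, max_fdr = 0.05) {
  if (max_fold <= 0 || max_fold >= 1) stopf("max_fold must be in (0, 1)")
  if (max_fdr <= 0 || max_fdr >= 1) stopf("max_fdr must be in (0, 1)")
  structure(list(max_fold = max_fold, max_fdr = max_fdr),
            class = "de_thresholds")
}

#' Classify genes into stage-specific expression categories
#'
#' Given per-cell-type transcript concentrations, a gene is:
#' * `mitosis` if spermatogonia concentration exceeds `fold` times the
#'   primary-spermatocyte concentration;
#' * `meiosisI` if the primary-spermatocyte concentration exceeds `fold`
#'   times both the spermatogonia and secondary-spermatocyte
#'   concentrations;
#' * `persistent` if the primary-spermatocyte concentration exceeds
#'   `fold` times spermatogonia while the secondary-spermatocyte and
#'   round-spermatid ratios to primary both stay inside the unchanged
#'   band (inclusive);
#' * `unclassified` otherwise.
#'
#' The three named categories are mutually exclusive for any input:
#' mitosis and the other two impose contradictory spermatogonia
#' comparisons, and the secondary-spermatocyte condition separates
#' meiosisI from persistent. Genes silent in all four types are
#' unclassified and flagged in the `"silent"` attribute.
#'
#' @param c_sg,c_ps,c_ss,c_rs Concentrations in spermatogonia, primary
#'   spermatocytes, secondary spermatocytes, round spermatids.
#' @param rules A [category_rules()].
#' @return Character vector of labels with a logical `"silent"`
#'   attribute.
#' @export
classify_category <- function(c_sg, c_ps, c_ss, c_rs,
                              rules = category_rules()) {
  v <- cbind(c_sg, c_ps, c_ss, c_rs)  # recycles scalars
  if (any(v < 0, na.rm = TRUE) || any(is.na(v)))
    stopf("concentrations must be non-negative and non-missing")
  c_sg <- v[, 1]; c_ps <- v[, 2]; c_ss <- v[, 3]; c_rs <- v[, 4]
  fold <- rules$fold; band <- rules$unchanged_band
  mitosis <- c_sg > fold * c_ps
  meiosis <- (c_ps > fold * c_sg) & (c_ps > fold * c_ss)
  r_ss <- c_ss / c_ps
  r_rs <- c_rs / c_ps
  persistent <- (c_ps > fold * c_sg) &
    !is.na(r_ss) & r_ss >= band[1] & r_ss <= band[2] &
    !is.na(r_rs) & r_rs >= band[1] & r_rs <= band[2]
  persistent[is.na(persistent)] <- FALSE
  out <- rep("unclassified", nrow(v))
  out[mitosis] <- "mitosis"
  out[meiosis] <- "meiosisI"
  out[persistent] <- "persistent"
  attr(out, "silent") <- c_sg == 0 & c_ps == 0 & c_ss == 0 & c_rs == 0
  out
}

#' Classify every gene of an expression profile
#'
#' @param profile Long profile from [expression_profile()]; must contain
#'   all four germ-cell types.
#' @param rules A [category_rules()].
#' @param min_concentration Optional expression floor: genes whose
#'   maximum concentration across the four types is below it are left
#'   unclassified (default 0, no floor).
#' @return Data frame `gene_id`, `category`.
#' @export
classify_genes <- function(profile, rules = category_rules(),
                           min_concentration = 0) {
  types <- germ_cell_types()
  miss <- setdiff(types, unique(profile$cell_type))
  if (length(miss))
    stopf("profile lacks cell type(s): %s", paste(miss, collapse = ", "))
  ids <- unique(profile$gene_id)
  conc <- sapply(types, function(t) {
    sub <- profile[profile$cell_type == t, ]
    sub$concentration[match(ids, sub$gene_id)]
  })
  lab <- classify_category(conc[, 1], conc[, 2], conc[, 3], conc[, 4], rules)
  if (min_concentration > 0) {
    low <- apply(conc, 1, max) < min_concentration
    lab[low] <- "unclassified"
  }
  data.frame(gene_id = ids, category = as.character(lab),
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Standard step-up procedure: sorted `q_i = min_{j >= i} p_j * m / j`,
#' mapped back to input order and capped at 1.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Differential-expression filter
#'
#' `TRUE` iff `fold_change < max_fold` and `q_value < max_fdr`, both
#' strict.
#'
#' @param fold_change Mutant/control fold change (>= 0).
#' @param q_value BH-adjusted q-value in `[0, 1]`.
#' @param thresholds A [de_thresholds()].
#' @export
de_filter <- function(fold_change, q_value, thresholds = de_thresholds()) {
  if (any(fold_change < 0, na.rm = TRUE)) stopf("fold_change must be >= 0")
  if (any(q_value < 0 | q_value > 1, na.rm = TRUE))
    stopf("q_value must lie in [0, 1]")
  fold_change < thresholds$max_fold & q_value < thresholds$max_fdr
}

# Vectorized two-sided Welch test on rows of two matrices (log2 scale).
# Degenerate rows (zero variance in both groups) get p = 1 when the
# group means agree, p = 0 otherwise.
welch_rows_p <- function(a, b) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  p <- rep(NA_real_, length(ma))
  deg <- se2 == 0
  p[deg] <- ifelse(ma[deg] == mb[deg], 1, 0)
  ok <- !deg
  if (any(ok)) {
    tt <- (ma[ok] - mb[ok]) / sqrt(se2[ok])
    df <- se2[ok]^2 /
      ((va[ok] / na)^2 / (na - 1) + (vb[ok] / nb)^2 / (nb - 1))
    p[ok] <- 2 * stats::pt(-abs(tt), df)
  }
  p
}

#' Simple per-gene differential-expression test
#'
#' A deliberately plain DE engine so the pipeline is self-contained:
#' counts are normalized (spike-in scale factors by default, library
#' size otherwise), a pseudocount of 0.5 is added, the fold change is
#' the ratio of group means, and the p-value comes from a two-sided
#' Welch (unequal-variance) test on `log2(normalized + 0.5)`. It applies
#' no dispersion shrinkage; externally computed fold-change/p-value
#' tables can be fed directly to [bh_fdr()] and [de_filter()] instead.
#'
#' @param ct A [count_table()] whose metadata carries a `genotype`
#'   column with at least two replicates per genotype.
#' @param control,mutant Genotype labels.
#' @param normalization `"spikein"` or `"library_size"`.
#' @return Data frame `gene_id`, `fold_change`, `p_value`.
#' @export
de_test <- function(ct, control = "control", mutant = "mutant",
                    normalization = c("spikein", "library_size")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(ct, "count_table"))
  meta <- ct$meta
  ctrl_cols <- meta$sample_id[meta$genotype == control]
  mut_cols <- meta$sample_id[meta$genotype == mutant]
  if (length(ctrl_cols) < 2 || length(mut_cols) < 2)
    stopf("at least two replicates per genotype are required")
  gene <- ct$counts[!ct$spike_in, , drop = FALSE]
  sf <- if (normalization == "spikein") {
    s <- colSums(ct$counts[ct$spike_in, , drop = FALSE])
    if (any(s == 0))
      stopf("spike-in reads absent; use library_size normalization")
    s / mean(s)
  } else {
    s <- colSums(gene)
    s / mean(s)
  }
  norm <- sweep(gene, 2, sf, `/`)
  a <- norm[, ctrl_cols, drop = FALSE] + 0.5
  b <- norm[, mut_cols, drop = FALSE] + 0.5
  data.frame(gene_id = rownames(gene),
             fold_change = unname(rowMeans(b) / rowMeans(a)),
             p_value = unname(welch_rows_p(log2(a), log2(b))),
             stringsAsFactors = FALSE)
}
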