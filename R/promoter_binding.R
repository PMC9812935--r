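# Summit-to-TSS distances, promoter-window assignment, and the
# multi-replicate evidence rules that turn per-replicate peak sets into
# final bound/not-bound calls per transcription factor.

#' Default per-TF evidence rules
#'
#' A gene is bound by a TF if it has a peak within the promoter window
#' in every CUT&RUN replicate, or in at least one CUT&RUN replicate plus
#' at least `chip_min` ChIP-seq replicates. Defaults: TCFL5 requires
#' 2/2 CUT&RUN, or 1/2 CUT&RUN and 2/3 ChIP-seq; A-MYB requires 2/2
#' CUT&RUN, or 1/2 CUT&RUN and its single ChIP-seq replicate.
#' @export
default_tf_rules <- function() {
  list("TCFL5" = list(cutrun_total = 2L, chip_total = 3L, chip_min = 2L),
       "A-MYB" = list(cutrun_total = 2L, chip_total = 1L, chip_min = 1L))
}

#' Binding rules
#'
#' @param window_bp Promoter window half-width in bp; a summit within
#'   `|distance| <= window_bp` of the TSS counts (inclusive, "within the
#'   range of 500 bp" read as a closed interval).
#' @param tf_rules Per-TF evidence rules, see [default_tf_rules()].
#' @export
binding_rules <- function(window_bp = 500L, tf_rules = default_tf_rules()) {
  if (window_bp <= 0) stopf("window_bp must be > 0")
  for (tf in names(tf_rules)) {
    r <- tf_rules[[tf]]
    if (!all(c("cutrun_total", "chip_total", "chip_min") %in% names(r)))
      stopf("rule for '%s' must declare cutrun_total, chip_total, chip_min",
            tf)
  }
  structure(list(window_bp = as.integer(window_bp), tf_rules = tf_rules),
            class = "binding_rules")
}

#' Signed summit-to-TSS distance
#'
#' `summit - tss` on the `+` strand, `tss - summit` on the `-` strand,
#' so a positive distance is always downstream of the TSS in gene
#' orientation and a negative distance upstream. Caller must pre-filter
#' to the gene's chromosome.
#'
#' @param tss TSS coordinate(s).
#' @param strand `"+"` or `"-"`.
#' @param summit Summit coordinate(s).
#' @export
signed_distance <- function(tss, strand, summit) {
  strand <- check_strand(strand)
  ifelse(strand == "+", summit - tss, tss - summit)
}

# Minimum |summit - tss| against a sorted summit vector via interval
# index; Inf where no summit exists.
min_abs_dist <- function(tss, summits_sorted) {
  n <- length(summits_sorted)
  if (n == 0L) return(rep(Inf, length(tss)))
  i <- findInterval(tss, summits_sorted)
  left <- ifelse(i >= 1L, tss - summits_sorted[pmax(i, 1L)], Inf)
  right <- ifelse(i < n, summits_sorted[pmin(i + 1L, n)] - tss, Inf)
  pmin(left, right)
}

# Tie-broken nearest signed distance by exhaustive scan: minimize |d|,
# prefer upstream (negative d), then smaller peak start.
nearest_signed_distance <- function(tss, strand, summits, starts) {
  d <- if (strand == "+") summits - tss else tss - summits
  a <- abs(d)
  cand <- which(a == min(a))
  if (length(cand) > 1L) {
    neg <- cand[d[cand] < 0]
    if (length(neg)) cand <- neg
    cand <- cand[order(starts[cand])]
  }
  d[cand[1]]
}

#' Nearest peak summit to a gene's TSS
#'
#' Minimizes the absolute signed distance; equidistant summits are
#' resolved by preferring the upstream one (negative distance), then the
#' peak with the smaller start. Returns `NULL` when the TF has no peak
#' on the gene's chromosome.
#'
#' @param gene One-row gene-model data frame.
#' @param peaks Peak data frame.
#' @return `list(peak = <one-row data frame>, distance = <signed bp>)`
#'   or `NULL`.
#' @export
nearest_summit <- function(gene, peaks) {
  pk <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
  if (nrow(pk) == 0L) return(NULL)
  strand <- check_strand(gene$strand)
  d <- if (strand == "+") pk$summit - gene$tss else gene$tss - pk$summit
  a <- abs(d)
  cand <- which(a == min(a))
  if (length(cand) > 1L) {
    neg <- cand[d[cand] < 0]
    if (length(neg)) cand <- neg
    cand <- cand[order(pk$start[cand])]
  }
  list(peak = pk[cand[1], , drop = FALSE], distance = d[cand[1]])
}

#' Promoter-window membership
#'
#' `TRUE` iff some summit lies within `window_bp` of the TSS
#' (inclusive). Membership depends only on |distance|, so it is
#' strand-independent.
#'
#' @param gene One-row gene-model data frame.
#' @param peaks Peak data frame.
#' @param window_bp Window half-width, default 500.
#' @export
has_promoter_peak <- function(gene, peaks, window_bp = 500L) {
  pk <- peaks[peaks$chrom == gene$chrom, , drop = FALSE]
  if (nrow(pk) == 0L) return(FALSE)
  min_abs_dist(gene$tss, sort(pk$summit)) <= window_bp
}

# Vectorized window membership for all genes against one peak set.
window_hits <- function(annotation, peaks, window_bp) {
  hit <- logical(nrow(annotation))
  if (nrow(peaks) == 0L) return(hit)
  for (cn in unique(annotation$chrom)) {
    s <- sort(peaks$summit[peaks$chrom == cn])
    if (!length(s)) next
    gi <- which(annotation$chrom == cn)
    hit[gi] <- min_abs_dist(annotation$tss[gi], s) <= window_bp
  }
  hit
}

#' Combine replicate evidence into a bound/not-bound decision
#'
#' @param tf TF name with a configured rule.
#' @param cutrun Logical vector, one entry per CUT&RUN replicate.
#' @param chip Logical vector, one entry per ChIP-seq replicate.
#' @param rules A [binding_rules()]. Evidence vectors must match the
#'   declared replicate totals exactly; extra replicates are rejected
#'   rather than reinterpreted.
#' @export
combine_evidence <- function(tf, cutrun, chip, rules = binding_rules()) {
  r <- rules$tf_rules[[tf]]
  if (is.null(r)) stopf("no evidence rule configured for TF '%s'", tf)
  if (length(cutrun) != r$cutrun_total)
    stopf("%s: expected %d CUT&RUN replicates, got %d", tf, r$cutrun_total,
          length(cutrun))
  if (length(chip) != r$chip_total)
    stopf("%s: expected %d ChIP-seq replicates, got %d", tf, r$chip_total,
          length(chip))
  n_cr <- sum(cutrun)
  n_ch <- sum(chip)
  (n_cr == r$cutrun_total) || (n_cr >= 1L && n_ch >= r$chip_min)
}

#' Call TF binding for every gene
#'
#' For each configured TF, computes per-replicate promoter-window
#' evidence, applies the TF's evidence rule, and reports the signed
#' distance to the nearest summit among all of that TF's peaks (NA when
#' the TF has no peak on the gene's chromosome; such genes are simply
#' not bound, never errors).
#'
#' @param annotation Gene-model data frame.
#' @param peaks Peak data frame labeled by `tf`, `assay`, `replicate`.
#' @param rules A [binding_rules()].
#' @return Data frame `gene_id`, `tf`, `n_cutrun`, `n_chip`, `bound`,
#'   `nearest_distance` (one row per gene x TF).
#' @export
call_binding <- function(annotation, peaks, rules = binding_rules()) {
  out_cols <- data.frame(gene_id = character(), tf = character(),
                         n_cutrun = integer(), n_chip = integer(),
                         bound = logical(), nearest_distance = numeric(),
                         stringsAsFactors = FALSE)
  if (nrow(annotation) == 0L) return(out_cols)
  check_strand(annotation$strand)
  out <- list()
  for (tf in names(rules$tf_rules)) {
    r <- rules$tf_rules[[tf]]
    pk <- peaks[peaks$tf == tf, , drop = FALSE]
    ev <- function(assay, total) {
      reps <- unique(pk$replicate[pk$assay == assay])
      extra <- setdiff(reps, seq_len(total))
      if (length(extra))
        stopf("%s/%s peak set carries replicate %d beyond the declared %d",
              tf, assay, extra[1], total)
      m <- matrix(FALSE, nrow(annotation), total)
      for (j in seq_len(total)) {
        sub <- pk[pk$assay == assay & pk$replicate == j, , drop = FALSE]
        m[, j] <- window_hits(annotation, sub, rules$window_bp)
      }
      m
    }
    cr <- ev("cutrun", r$cutrun_total)
    ch <- ev("chip", r$chip_total)
    n_cr <- rowSums(cr)
    n_ch <- rowSums(ch)
    bound <- (n_cr == r$cutrun_total) | (n_cr >= 1L & n_ch >= r$chip_min)
    nd <- rep(NA_real_, nrow(annotation))
    by_chr <- split(seq_len(nrow(pk)), pk$chrom)
    for (cn in names(by_chr)) {
      pi <- by_chr[[cn]]
      summits <- pk$summit[pi]
      starts <- pk$start[pi]
      for (i in which(annotation$chrom == cn)) {
        nd[i] <- nearest_signed_distance(annotation$tss[i],
                                         annotation$strand[i],
                                         summits, starts)
      }
    }
    out[[tf]] <- data.frame(gene_id = annotation$gene_id, tf = tf,
                            n_cutrun = as.integer(n_cr),
                            n_chip = as.integer(n_ch), bound = bound,
                            nearest_distance = nd, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Summarize binding calls
#'
#' Per TF: genes bound and the median |nearest summit distance| among
#' bound genes. When category labels are supplied, also the per-category
#' bound counts and fractions.
#'
#' @param calls Output of [call_binding()].
#' @param categories Optional data frame `gene_id`, `category`.
#' @return `list(per_tf = ..., per_category = ...)`.
#' @export
binding_summary <- function(calls, categories = NULL) {
  tfs <- unique(calls$tf)
  per_tf <- do.call(rbind, lapply(tfs, function(tf) {
    sub <- calls[calls$tf == tf, ]
    data.frame(tf = tf, n_genes = nrow(sub), n_bound = sum(sub$bound),
               median_abs_distance = if (any(sub$bound))
                 stats::median(abs(sub$nearest_distance[sub$bound]),
                               na.rm = TRUE) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  per_category <- NULL
  if (!is.null(categories)) {
    m <- merge(calls, categories, by = "gene_id")
    per_category <- do.call(rbind, lapply(tfs, function(tf) {
      sub <- m[m$tf == tf, ]
      do.call(rbind, lapply(sort(unique(sub$category)), function(cat) {
        s2 <- sub[sub$category == cat, ]
        data.frame(tf = tf, category = cat, n_genes = nrow(s2),
                   n_bound = sum(s2$bound),
                   fraction_bound = sum(s2$bound) / nrow(s2),
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(per_category) <- NULL
  }
  list(per_tf = per_tf, per_category = per_category)
}
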