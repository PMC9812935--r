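# Absolute transcript quantification: RPKM, ERCC-calibrated molecules
# per cell, and cell-volume-corrected transcript concentration.

#' Spike-in calibration model
#'
#' Each library carries a known total number of spike-in molecules
#' (default 623291645, the loading of a 1:100 dilution of ERCC spike-in
#' mix 1), identified by a row-id prefix.
#'
#' @param total_spike_molecules Spike-in molecules loaded per sample.
#' @param spike_prefix Row-id prefix flagging spike-in rows.
#' @export
spikein_model <- function(total_spike_molecules = 623291645,
                          spike_prefix = "ERCC-") {
  if (total_spike_molecules <= 0)
    stopf("total_spike_molecules must be > 0")
  structure(list(total_spike_molecules = total_spike_molecules,
                 spike_prefix = spike_prefix),
            class = "spikein_model")
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = count / (total_mapped / 1e6) / (gene_length / 1e3)`.
#'
#' @param count Read count(s) for the gene.
#' @param gene_length Gene length in nucleotides (>= 1).
#' @param total_mapped Total uniquely mapped reads in the sample (>= 1).
#' @export
rpkm <- function(count, gene_length, total_mapped) {
  if (any(gene_length < 1)) stopf("gene_length must be >= 1")
  if (any(total_mapped < 1))
    stopf("total_mapped must be >= 1 (normalization undefined at 0)")
  count / (total_mapped / 1e6) / (gene_length / 1e3)
}

#' Absolute transcript abundance in molecules per cell
#'
#' `gene_reads * total_spike_molecules / (n_cells * spike_reads)`:
#' the known number of spike-in molecules converts the gene's read count
#' into molecule units, and dividing by the number of cells used to
#' prepare the library yields molecules per cell.
#'
#' @param gene_reads Reads mapped to the gene.
#' @param n_cells Cells used to prepare the library (>= 1).
#' @param spike_reads Reads mapped to spike-in sequences (>= 1).
#' @param model A [spikein_model()].
#' @export
molecules_per_cell <- function(gene_reads, n_cells, spike_reads,
                               model = spikein_model()) {
  if (any(n_cells < 1)) stopf("n_cells must be >= 1")
  if (any(spike_reads < 1))
    stopf("spike-in reads absent: molecule calibration undefined")
  # numeric multiplication up front: integer inputs would overflow here
  gene_reads * model$total_spike_molecules /
    (as.numeric(n_cells) * as.numeric(spike_reads))
}

#' Transcript concentration
#'
#' Molecules per cell corrected for cell volume: `molecules /
#' rel_volume`. Concentration, not raw molecules, is what makes
#' abundances comparable across cell types of very different sizes.
#'
#' @param molecules Molecules per cell.
#' @param rel_volume Relative cell volume (> 0).
#' @export
concentration <- function(molecules, rel_volume) {
  if (any(rel_volume <= 0)) stopf("rel_volume must be > 0")
  molecules / rel_volume
}

#' Per-gene, per-cell-type expression profile
#'
#' Computes RPKM, molecules per cell, and concentration for every gene
#' in every sample, then averages replicate samples within each cell
#' type (mean by default, median optionally; the averaging is applied to
#' the per-sample molecule estimates). RPKM uses the non-spike mapped
#' reads as its depth normalizer.
#'
#' @param ct A [count_table()].
#' @param genes Gene-model data frame covering every non-spike row.
#' @param model A [spikein_model()].
#' @param average `"mean"` or `"median"` across replicates.
#' @return Long data frame: `gene_id`, `cell_type`, `rpkm`,
#'   `molecules_per_cell`, `concentration`.
#' @export
expression_profile <- function(ct, genes, model = spikein_model(),
                               average = c("mean", "median")) {
  average <- match.arg(average)
  stopifnot(inherits(ct, "count_table"))
  counts <- ct$counts
  gene_counts <- counts[!ct$spike_in, , drop = FALSE]
  spike_counts <- counts[ct$spike_in, , drop = FALSE]
  miss <- setdiff(rownames(gene_counts), genes$gene_id)
  if (length(miss))
    stopf("count table row '%s' missing from the annotation", miss[1])
  gm <- genes[match(rownames(gene_counts), genes$gene_id), ]
  spike_reads <- colSums(spike_counts)
  if (any(spike_reads == 0))
    stopf("spike-in reads absent in sample '%s'",
          colnames(counts)[which(spike_reads == 0)[1]])
  total_mapped <- colSums(gene_counts)
  meta <- ct$meta

  rpkm_m <- rpkm(gene_counts,
                 matrix(gm$gene_length, nrow(gene_counts),
                        ncol(gene_counts)),
                 matrix(total_mapped, nrow(gene_counts), ncol(gene_counts),
                        byrow = TRUE))
  mpc_m <- sweep(gene_counts, 2,
                 model$total_spike_molecules / (meta$n_cells * spike_reads),
                 `*`)
  conc_m <- sweep(mpc_m, 2, meta$rel_volume, `/`)

  agg <- function(m) {
    sapply(unique(meta$cell_type), function(t) {
      cols <- which(meta$cell_type == t)
      if (average == "mean") rowMeans(m[, cols, drop = FALSE])
      else apply(m[, cols, drop = FALSE], 1, stats::median)
    })
  }
  types <- unique(meta$cell_type)
  r <- agg(rpkm_m); mp <- agg(mpc_m); cc <- agg(conc_m)
  out <- data.frame(
    gene_id = rep(rownames(gene_counts), times = length(types)),
    cell_type = rep(types, each = nrow(gene_counts)),
    rpkm = as.vector(r), molecules_per_cell = as.vector(mp),
    concentration = as.vector(cc), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
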