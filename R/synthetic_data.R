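# Seeded synthetic-data generator. Plants known ground truth (expression
# categories, TF binding, differential expression) so the analysis
# modules can be validated end to end. Truth is emitted alongside the
# data and is never read by the analysis code.

germ_cell_types <- function() {
  c("spermatogonia", "primary_spermatocyte", "secondary_spermatocyte",
    "round_spermatid")
}

#' Default TF replicate design
#'
#' Mirrors the study design the generator emulates: TCFL5 profiled by two
#' CUT&RUN replicates and three ChIP-seq replicates; A-MYB by two
#' CUT&RUN replicates and one ChIP-seq replicate.
#' @export
default_tf_design <- function() {
  data.frame(tf = c("TCFL5", "TCFL5", "A-MYB", "A-MYB"),
             assay = c("cutrun", "chip", "cutrun", "chip"),
             n_replicates = c(2L, 3L, 2L, 1L),
             stringsAsFactors = FALSE)
}

default_bound_fraction <- function() {
  list("TCFL5" = c(mitosis = 0.47, meiosisI = 0.59, persistent = 0.26,
                   unclassified = 0.30),
       "A-MYB" = c(mitosis = 0.20, meiosisI = 0.25, persistent = 0.15,
                   unclassified = 0.10))
}

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator in one validated object.
#' Defaults emulate the germ-cell study design: four FACS-purified cell
#' types, category proportions close to the reported gene-class sizes,
#' the TCFL5/A-MYB replicate structure, a 4-fold planted stage pattern
#' (comfortably above the 2-fold classification thresholds), and
#' promoter peaks jittered around the TSS.
#'
#' @param n_genes Number of genes to simulate.
#' @param chrom_sizes Named vector of chromosome lengths (bp).
#' @param seed Integer seed; every generator call derives its RNG stream
#'   from it, so identical configurations give identical data.
#' @param jitter_bp Planted summit offsets are uniform on
#'   `[-jitter_bp, +jitter_bp]`.
#' @param decoys_per_gene Expected decoy peaks per gene per replicate
#'   file; decoy summits always fall > 500 bp from every TSS.
#' @param replicate_dropout Probability that a truly bound gene loses its
#'   peak in one replicate.
#' @param dispersion Negative-binomial dispersion; `0` selects the exact
#'   noise-free mode (counts are rounded expected means).
#' @param spike_fraction Fraction of each sample's reads drawn from
#'   spike-in rows.
#' @param category_proportions Named proportions for
#'   mitosis/meiosisI/persistent/unclassified; must sum to 1.
#' @param bound_fraction Per-TF named vector of the fraction of genes in
#'   each category planted as bound; planted as exact counts
#'   (`round(fraction * n)`) so the configured fraction is the true one.
#' @param pattern_fold Planted fold for the stage-specific concentration
#'   patterns (default 4).
#' @param de_fraction Fraction of genes planted as differentially
#'   expressed in the two-genotype dataset.
#' @param de_fold Planted mutant/control fold for DE genes (default 0.2).
#' @param total_reads Sequencing depth per sample.
#' @param n_cells Cells used to prepare each library.
#' @param rel_volume Named relative cell volumes per cell type. The real
#'   volumes are not published; these defaults (spermatocytes largest)
#'   are arbitrary and configurable.
#' @param n_replicates Expression replicates per cell type.
#' @param n_spikes Number of distinct spike-in species.
#' @param tss_spacing Minimum TSS spacing (bp); genes are placed on this
#'   grid so one gene's planted peak can never fall in another gene's
#'   promoter window.
#' @param tf_design Replicate design, see [default_tf_design()].
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L,
                       chrom_sizes = c(chr1 = 60e6, chr2 = 60e6),
                       seed = 1L,
                       jitter_bp = 100L,
                       decoys_per_gene = 0.5,
                       replicate_dropout = 0,
                       dispersion = 0.05,
                       spike_fraction = 0.05,
                       category_proportions = c(mitosis = 0.41,
                                                meiosisI = 0.04,
                                                persistent = 0.07,
                                                unclassified = 0.48),
                       bound_fraction = default_bound_fraction(),
                       pattern_fold = 4,
                       de_fraction = 0.15,
                       de_fold = 0.2,
                       total_reads = 1e6,
                       n_cells = 50000L,
                       rel_volume = c(spermatogonia = 1,
                                      primary_spermatocyte = 2.5,
                                      secondary_spermatocyte = 1.5,
                                      round_spermatid = 1),
                       n_replicates = 2L,
                       n_spikes = 24L,
                       tss_spacing = 5000L,
                       tf_design = default_tf_design()) {
  if (n_genes < 0) stopf("n_genes must be >= 0")
  if (length(chrom_sizes) == 0 || is.null(names(chrom_sizes)))
    stopf("chrom_sizes must be a named, non-empty vector")
  if (jitter_bp < 0) stopf("jitter_bp must be >= 0")
  if (replicate_dropout < 0 || replicate_dropout > 1)
    stopf("replicate_dropout must be a probability in [0, 1]")
  if (dispersion < 0)
    stopf("dispersion must be >= 0 (0 selects the noise-free mode)")
  if (spike_fraction < 0 || spike_fraction >= 1)
    stopf("spike_fraction must be in [0, 1)")
  cats <- c("mitosis", "meiosisI", "persistent", "unclassified")
  if (!setequal(names(category_proportions), cats))
    stopf("category_proportions must be named %s", paste(cats, collapse = ", "))
  category_proportions <- category_proportions[cats]
  if (any(category_proportions < 0) ||
      abs(sum(category_proportions) - 1) > 1e-9)
    stopf("category_proportions must be non-negative and sum to 1")
  for (tf in names(bound_fraction)) {
    bf <- bound_fraction[[tf]]
    if (!all(cats %in% names(bf)) || any(bf < 0) || any(bf > 1))
      stopf("bound_fraction[['%s']] must give a probability per category", tf)
  }
  if (pattern_fold <= 1) stopf("pattern_fold must be > 1")
  if (de_fraction < 0 || de_fraction > 1)
    stopf("de_fraction must be in [0, 1]")
  if (de_fold <= 0) stopf("de_fold must be > 0")
  if (!all(germ_cell_types() %in% names(rel_volume)))
    stopf("rel_volume must name all four germ-cell types")
  if (any(rel_volume <= 0)) stopf("rel_volume must be > 0")
  if (n_replicates < 1) stopf("n_replicates must be >= 1")
  if (tss_spacing < 1) stopf("tss_spacing must be >= 1")
  structure(list(n_genes = as.integer(n_genes), chrom_sizes = chrom_sizes,
                 seed = as.integer(seed), jitter_bp = as.integer(jitter_bp),
                 decoys_per_gene = decoys_per_gene,
                 replicate_dropout = replicate_dropout,
                 dispersion = dispersion, spike_fraction = spike_fraction,
                 category_proportions = category_proportions,
                 bound_fraction = bound_fraction,
                 pattern_fold = pattern_fold, de_fraction = de_fraction,
                 de_fold = de_fold, total_reads = total_reads,
                 n_cells = as.integer(n_cells), rel_volume = rel_volume,
                 n_replicates = as.integer(n_replicates),
                 n_spikes = as.integer(n_spikes),
                 tss_spacing = as.integer(tss_spacing),
                 tf_design = tf_design),
            class = "sim_config")
}

#' Generate a synthetic gene annotation
#'
#' Places `n_genes` TSSs on a `tss_spacing` grid (no collisions, and
#' planted promoter peaks of one gene can never reach another gene's
#' promoter window), with uniformly random strands, gene lengths, and a
#' small fraction of miRNA biotypes. Deterministic given the seed.
#'
#' @param cfg A [sim_config()].
#' @return A gene-model data frame (same shape as [read_annotation()]).
#' @export
gen_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  margin <- 2L * cfg$tss_spacing
  slots <- pmax(floor((cfg$chrom_sizes - 2 * margin) / cfg$tss_spacing), 0)
  if (cfg$n_genes > sum(slots))
    stopf("n_genes = %d exceeds the %d placeable TSS positions",
          cfg$n_genes, sum(slots))
  if (cfg$n_genes == 0L) return(empty_gene_table())
  with_seed(cfg$seed + 101L, {
    n <- cfg$n_genes
    chrom <- sample(names(cfg$chrom_sizes), n, replace = TRUE,
                    prob = cfg$chrom_sizes / sum(cfg$chrom_sizes))
    # resolve per-chromosome overflow deterministically
    tab <- table(factor(chrom, levels = names(cfg$chrom_sizes)))
    over <- names(tab)[tab > slots[names(tab)]]
    while (length(over)) {
      cn <- over[1]
      excess <- sum(chrom == cn) - slots[[cn]]
      free <- names(tab)[tab < slots[names(tab)]]
      idx <- which(chrom == cn)[seq_len(excess)]
      chrom[idx] <- sample(free, excess, replace = TRUE)
      tab <- table(factor(chrom, levels = names(cfg$chrom_sizes)))
      over <- names(tab)[tab > slots[names(tab)]]
    }
    tss <- integer(n)
    for (cn in names(cfg$chrom_sizes)) {
      gi <- which(chrom == cn)
      if (!length(gi)) next
      pick <- sample.int(slots[[cn]], length(gi))
      tss[gi] <- margin + (pick - 1L) * cfg$tss_spacing
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    data.frame(gene_id = sprintf("g%05d", seq_len(n)), chrom = chrom,
               strand = strand, tss = tss,
               gene_length = sample(500:5000, n, replace = TRUE),
               biotype = ifelse(stats::runif(n) < 0.02, "miRNA",
                                "protein_coding"),
               stringsAsFactors = FALSE)
  })
}

#' Generate the planted truth table
#'
#' Assigns every gene one expression category (multinomial with the
#' configured proportions), per-TF bound flags (exact counts:
#' `round(fraction * n)` genes per category, sampled without
#' replacement), and a differential-expression flag with the planted
#' fold.
#'
#' @param annotation Gene models from [gen_annotation()].
#' @param cfg A [sim_config()].
#' @export
gen_truth <- function(annotation, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(annotation)
  with_seed(cfg$seed + 202L, {
    category <- sample(names(cfg$category_proportions), n, replace = TRUE,
                       prob = cfg$category_proportions)
    truth <- data.frame(gene_id = annotation$gene_id, category = category,
                        stringsAsFactors = FALSE)
    for (tf in names(cfg$bound_fraction)) {
      bound <- logical(n)
      for (cat in names(cfg$category_proportions)) {
        gi <- which(category == cat)
        k <- round(cfg$bound_fraction[[tf]][[cat]] * length(gi))
        if (k > 0) bound[sample(gi, k)] <- TRUE
      }
      truth[[paste0("bound_", tf)]] <- bound
    }
    de <- logical(n)
    k <- round(cfg$de_fraction * n)
    if (k > 0) de[sample.int(n, k)] <- TRUE
    truth$de <- de
    truth$de_fold <- ifelse(de, cfg$de_fold, 1)
    truth
  })
}

# Decoy summits uniform on the genome but rejected inside any promoter
# window (|summit - TSS| <= 500) so decoys can never create a binding call.
gen_decoy_summits <- function(n_dec, chrom_sizes, tss_by_chrom,
                              window = 500L) {
  chrom <- character(0); summit <- integer(0)
  guard <- 0L
  while (length(summit) < n_dec && guard < 100L) {
    need <- n_dec - length(summit)
    cn <- sample(names(chrom_sizes), need, replace = TRUE,
                 prob = chrom_sizes / sum(chrom_sizes))
    pos <- floor(stats::runif(need, 1000, chrom_sizes[cn] - 1000))
    ok <- logical(need)
    for (c2 in unique(cn)) {
      i <- which(cn == c2)
      tss <- tss_by_chrom[[c2]]
      if (is.null(tss) || length(tss) == 0L) { ok[i] <- TRUE; next }
      d <- min_abs_dist(pos[i], tss)
      ok[i] <- d > window
    }
    chrom <- c(chrom, cn[ok]); summit <- c(summit, as.integer(pos[ok]))
    guard <- guard + 1L
  }
  list(chrom = chrom[seq_len(min(n_dec, length(summit)))],
       summit = summit[seq_len(min(n_dec, length(summit)))])
}

#' Generate per-replicate peak sets with planted binding
#'
#' For every truly bound gene and every replicate that survives dropout,
#' one peak is planted whose summit sits at `TSS + U(-jitter_bp,
#' +jitter_bp)`. Decoy peaks (expected `decoys_per_gene * n_genes` per
#' replicate file) are placed with summits more than 500 bp from every
#' TSS. The replicate structure follows `cfg$tf_design`.
#'
#' @param annotation,truth,cfg Generator inputs.
#' @return A peak data frame (same shape as [read_peaks()]).
#' @export
gen_peaks <- function(annotation, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!all(annotation$gene_id %in% truth$gene_id))
    stopf("truth table must cover every annotated gene")
  if (cfg$jitter_bp > 500)
    warnf("jitter_bp = %d exceeds the 500 bp promoter window; planted peaks may fall outside it",
          cfg$jitter_bp)
  ord <- match(annotation$gene_id, truth$gene_id)
  tss_by_chrom <- lapply(split(annotation$tss, annotation$chrom), sort)
  half <- 150L
  with_seed(cfg$seed + 303L, {
    out <- list()
    for (d in seq_len(nrow(cfg$tf_design))) {
      tf <- cfg$tf_design$tf[d]
      assay <- cfg$tf_design$assay[d]
      bound <- truth[[paste0("bound_", tf)]][ord]
      idx <- which(bound)
      for (rep_i in seq_len(cfg$tf_design$n_replicates[d])) {
        keep <- idx[stats::runif(length(idx)) >= cfg$replicate_dropout]
        nk <- length(keep)
        offs <- if (cfg$jitter_bp > 0 && nk > 0)
          sample.int(2L * cfg$jitter_bp + 1L, nk, replace = TRUE) -
            cfg$jitter_bp - 1L
        else rep(0L, nk)
        summit <- annotation$tss[keep] + offs
        planted <- if (nk > 0) data.frame(
          chrom = annotation$chrom[keep],
          start = pmax(summit - half, 0L), end = summit + half + 1L,
          summit = summit,
          score = round(stats::runif(nk, 5, 100), 2),
          tf = tf, assay = assay, replicate = rep_i,
          stringsAsFactors = FALSE) else empty_peak_table()
        n_dec <- round(cfg$decoys_per_gene * nrow(annotation))
        if (n_dec > 0) {
          dec <- gen_decoy_summits(n_dec, cfg$chrom_sizes, tss_by_chrom)
          nd <- length(dec$summit)
          if (nd > 0) {
            decoys <- data.frame(
              chrom = dec$chrom,
              start = pmax(dec$summit - half, 0L),
              end = dec$summit + half + 1L,
              summit = dec$summit,
              score = round(stats::runif(nd, 5, 100), 2),
              tf = tf, assay = assay, replicate = rep_i,
              stringsAsFactors = FALSE)
            planted <- rbind(planted, decoys)
          }
        }
        out[[length(out) + 1L]] <- planted
      }
    }
    res <- do.call(rbind, out)
    if (is.null(res)) res <- empty_peak_table()
    rownames(res) <- NULL
    res$replicate <- as.integer(res$replicate)
    res
  })
}

# Concentration multipliers per category across the four cell types, in
# the order of germ_cell_types(). The planted fold sits well above the
# 2x classification thresholds so noise-free recovery is exact.
category_pattern_matrix <- function(fold) {
  m <- rbind(mitosis = c(fold, 1, 1, 1),
             meiosisI = c(1, fold, 1, 1),
             persistent = c(1, fold, fold, fold),
             unclassified = c(1, 1, 1, 1))
  colnames(m) <- germ_cell_types()
  m
}

# Fixed spike-in mix proportions spanning ~3 orders of magnitude.
spike_mix_proportions <- function(n_spikes) {
  p <- 2^seq(0, 10, length.out = n_spikes)
  p / sum(p)
}

# Largest-remainder apportionment: integer counts summing exactly to total.
apportion <- function(prop, total) {
  x <- prop / sum(prop) * total
  f <- floor(x)
  rem <- as.integer(round(total - sum(f)))
  if (rem > 0) {
    o <- order(x - f, decreasing = TRUE)
    f[o[seq_len(rem)]] <- f[o[seq_len(rem)]] + 1
  }
  as.integer(f)
}

nb_or_round <- function(mu, dispersion) {
  if (dispersion == 0) as.integer(round(mu))
  else as.integer(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion))
}

#' Generate stage-profiled expression counts
#'
#' Builds a gene x sample count table over the four germ-cell types with
#' the planted per-category concentration patterns (e.g. mitosis genes:
#' spermatogonia concentration `pattern_fold` times that of primary
#' spermatocytes), converted to per-cell molecule counts through the
#' configured relative cell volumes, and allocated
#' `(1 - spike_fraction) * total_reads` gene reads per sample. Spike-in
#' rows receive exactly `spike_fraction * total_reads` reads in
#' noise-free mode. Counts are negative-binomial draws, or rounded means
#' when `dispersion = 0`.
#'
#' @param annotation,truth,cfg Generator inputs.
#' @return A list with `counts` (a [count_table()]) and
#'   `planted_molecules` (gene x cell-type matrix of the true
#'   molecules-per-cell values implied by the allocation; useful as the
#'   calibration oracle).
#' @export
gen_counts <- function(annotation, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(annotation)
  types <- germ_cell_types()
  with_seed(cfg$seed + 404L, {
    base <- stats::rlnorm(n, meanlog = log(50), sdlog = 1)
    mult <- category_pattern_matrix(cfg$pattern_fold)
    cat <- truth$category[match(annotation$gene_id, truth$gene_id)]
    conc <- base * mult[cat, , drop = FALSE]           # n x 4
    mol <- sweep(conc, 2, cfg$rel_volume[types], `*`)  # molecules per cell
    spike_total <- round(cfg$spike_fraction * cfg$total_reads)
    gene_budget <- cfg$total_reads - spike_total
    spike_prop <- spike_mix_proportions(cfg$n_spikes)
    spike_ids <- sprintf("ERCC-%05d", seq_len(cfg$n_spikes))

    samples <- expand.grid(replicate = seq_len(cfg$n_replicates),
                           cell_type = types, stringsAsFactors = FALSE)
    samples <- samples[order(match(samples$cell_type, types),
                             samples$replicate), ]
    sample_id <- sprintf("%s_rep%d", samples$cell_type, samples$replicate)

    # One global reads-per-molecule scale for all samples, so read counts
    # stay proportional to molecule numbers across cell types (the premise
    # of spike-in calibration); per-sample gene totals then average
    # gene_budget rather than hitting it exactly.
    kappa <- gene_budget / mean(colSums(mol))
    mu_by_type <- kappa * mol
    counts <- matrix(0L, n + cfg$n_spikes, nrow(samples),
                     dimnames = list(c(annotation$gene_id, spike_ids),
                                     sample_id))
    for (s in seq_len(nrow(samples))) {
      mu <- mu_by_type[, samples$cell_type[s]]
      counts[seq_len(n), s] <- nb_or_round(mu, cfg$dispersion)
      counts[n + seq_len(cfg$n_spikes), s] <-
        if (cfg$dispersion == 0) apportion(spike_prop, spike_total)
        else nb_or_round(spike_prop * spike_total, cfg$dispersion)
    }
    planted <- mu_by_type * 623291645 / (cfg$n_cells * spike_total)
    dimnames(planted) <- list(annotation$gene_id, types)
    meta <- data.frame(sample_id = sample_id,
                       cell_type = samples$cell_type,
                       genotype = "wildtype",
                       n_cells = cfg$n_cells,
                       rel_volume = unname(cfg$rel_volume[samples$cell_type]),
                       replicate = samples$replicate,
                       stringsAsFactors = FALSE)
    list(counts = count_table(counts, startsWith(rownames(counts), "ERCC-"),
                              meta),
         planted_molecules = planted)
  })
}

#' Generate a two-genotype differential-expression dataset
#'
#' Planted-DE genes have mutant mean expression `de_fold` times the
#' control mean; all other genes share means. Spike-in reads are held
#' constant across samples, so spike-in normalization recovers the
#' planted fold exactly in noise-free mode.
#'
#' @param annotation,truth,cfg Generator inputs.
#' @param genotypes Character vector of exactly two genotype labels,
#'   control first.
#' @param n_replicates Replicates per genotype (>= 2).
#' @return A [count_table()] with `genotype` metadata.
#' @export
gen_de_dataset <- function(annotation, truth, cfg,
                           genotypes = c("control", "mutant"),
                           n_replicates = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  if (length(genotypes) != 2) stopf("exactly two genotypes are required")
  if (n_replicates < 2) stopf("at least 2 replicates per genotype required")
  n <- nrow(annotation)
  with_seed(cfg$seed + 505L, {
    base <- stats::rlnorm(n, meanlog = log(100), sdlog = 1)
    fold <- truth$de_fold[match(annotation$gene_id, truth$gene_id)]
    mu <- cbind(control = base, mutant = base * fold)
    colnames(mu) <- genotypes
    spike_total <- round(cfg$spike_fraction * cfg$total_reads)
    spike_prop <- spike_mix_proportions(cfg$n_spikes)
    spike_ids <- sprintf("ERCC-%05d", seq_len(cfg$n_spikes))
    samples <- expand.grid(replicate = seq_len(n_replicates),
                           genotype = genotypes, stringsAsFactors = FALSE)
    sample_id <- sprintf("%s_rep%d", samples$genotype, samples$replicate)
    counts <- matrix(0L, n + cfg$n_spikes, nrow(samples),
                     dimnames = list(c(annotation$gene_id, spike_ids),
                                     sample_id))
    for (s in seq_len(nrow(samples))) {
      counts[seq_len(n), s] <- nb_or_round(mu[, samples$genotype[s]],
                                           cfg$dispersion)
      counts[n + seq_len(cfg$n_spikes), s] <-
        if (cfg$dispersion == 0) apportion(spike_prop, spike_total)
        else nb_or_round(spike_prop * spike_total, cfg$dispersion)
    }
    meta <- data.frame(sample_id = sample_id,
                       cell_type = "primary_spermatocyte",
                       genotype = samples$genotype,
                       n_cells = cfg$n_cells,
                       rel_volume = unname(
                         cfg$rel_volume[["primary_spermatocyte"]]),
                       replicate = samples$replicate,
                       stringsAsFactors = FALSE)
    count_table(counts, startsWith(rownames(counts), "ERCC-"), meta)
  })
}
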