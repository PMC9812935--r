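# Shared configuration for the numbered analysis scripts: the study
# conditions simulated throughout (2,000 genes on two chromosomes,
# TCFL5/A-MYB replicate design, 300 bp summit jitter, noise-free counts
# for the planted-truth demonstrations).

library(meioreg)

study_cfg <- function(seed = 20260927L, ...) {
  args <- utils::modifyList(
    list(n_genes = 2000L, chrom_sizes = c(chr1 = 60e6, chr2 = 60e6),
         seed = seed, jitter_bp = 300L, replicate_dropout = 0,
         dispersion = 0, decoys_per_gene = 0.5),
    list(...))
  do.call(sim_config, args)
}

results_dir <- function(...) {
  d <- file.path("results", ...)
  dir.create(d, showWarnings = FALSE, recursive = TRUE)
  d
}
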