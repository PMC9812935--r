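#!/usr/bin/env Rscript
# Haploinsufficiency-style differential expression: spike-in-normalized
# fold changes between the two genotypes, Welch p-values, BH FDR, the
# fold < 0.5 & FDR < 0.05 filter, and the overlap of downregulated genes
# with TCFL5-bound promoters.

source("analysis/_config.R")
dir <- results_dir("sim")

de_ct <- read_counts(file.path(dir, "de_counts.tsv"),
                     file.path(dir, "de_meta.tsv"))
truth <- read.delim(file.path(dir, "truth.tsv"), check.names = FALSE)
calls <- read_result_table(file.path(results_dir(), "binding_calls.tsv"),
                           "binding")

de <- de_test(de_ct)
de$q_value <- bh_fdr(de$p_value)
de$passes <- de_filter(de$fold_change, de$q_value)
write_table(de, file.path(results_dir(), "de_results.tsv"), "de")

n_pass <- sum(de$passes)
cat(sprintf("%d genes pass the filter (mutant/control < 0.5, FDR < 0.05)\n",
            n_pass))
planted <- truth$de[match(de$gene_id, truth$gene_id)]
cat(sprintf("planted knockdown genes: %d; recovered: %d; spurious: %d\n",
            sum(planted), sum(de$passes & planted),
            sum(de$passes & !planted)))

bound_tcfl5 <- calls$gene_id[calls$tf == "TCFL5" & calls$bound]
overlap <- sum(de$gene_id[de$passes] %in% bound_tcfl5)
cat(sprintf("TCFL5 bound near the TSS of %d of %d downregulated genes\n",
            overlap, n_pass))
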