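#!/usr/bin/env Rscript
# Absolute quantification and stage-specific classification: read the
# simulated counts back from disk, convert them to ERCC-calibrated
# molecules per cell and volume-corrected concentrations, classify every
# gene (mitosis-specific / meiosis I-specific / persistent), and score
# the labels against the planted truth.

source("analysis/_config.R")
dir <- results_dir("sim")

ann <- read_annotation(file.path(dir, "genes.bed"), "bed6")
ct <- read_counts(file.path(dir, "counts.tsv"), file.path(dir, "meta.tsv"))
truth <- read.delim(file.path(dir, "truth.tsv"), check.names = FALSE)

profile <- expression_profile(ct, ann)
write.table(profile, file.path(results_dir(), "expression_profile.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

categories <- classify_genes(profile)
write_table(categories, file.path(results_dir(), "categories.tsv"),
            "categories")

tab <- table(categories$category)
cat("classified categories:\n")
print(tab)
acc <- mean(categories$category ==
              truth$category[match(categories$gene_id, truth$gene_id)])
cat(sprintf("agreement with planted truth: %.1f%%\n", 100 * acc))

ps <- profile[profile$cell_type == "primary_spermatocyte", ]
cat(sprintf("primary spermatocytes: median %.1f molecules per cell (median RPKM %.1f)\n",
            median(ps$molecules_per_cell), median(ps$rpkm)))
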