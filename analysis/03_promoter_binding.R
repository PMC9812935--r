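#!/usr/bin/env Rscript
# Promoter binding calls: load the per-replicate peak files through the
# manifest, apply the 500 bp promoter window and the per-TF replicate
# evidence rules, and summarize bound-gene counts, summit-to-TSS
# distances, and per-category bound fractions.

source("analysis/_config.R")
dir <- results_dir("sim")

ann <- read_annotation(file.path(dir, "genes.bed"), "bed6")
peaks <- read_peak_sets(file.path(dir, "peak_manifest.tsv"))
truth <- read.delim(file.path(dir, "truth.tsv"), check.names = FALSE)
categories <- read_result_table(file.path(results_dir(), "categories.tsv"),
                                "categories")

calls <- call_binding(ann, peaks)
write_table(calls, file.path(results_dir(), "binding_calls.tsv"), "binding")

s <- binding_summary(calls, categories)
cat("binding per TF:\n"); print(s$per_tf)
cat("\nbound fraction per expression category:\n"); print(s$per_category)

for (tf in unique(calls$tf)) {
  sub <- calls[calls$tf == tf, ]
  tb <- truth[[paste0("bound_", tf)]][match(sub$gene_id, truth$gene_id)]
  cat(sprintf("\n%s vs planted truth: sensitivity %.3f, specificity %.3f\n",
              tf, sum(sub$bound & tb) / sum(tb),
              sum(!sub$bound & !tb) / sum(!tb)))
}

# distance histogram (100 bp bins) for bound genes
bound <- calls[calls$bound & !is.na(calls$nearest_distance), ]
h <- table(tf = bound$tf, bin = 100 * floor(bound$nearest_distance / 100))
write.table(as.data.frame(h), file.path(results_dir(), "distance_hist.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
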