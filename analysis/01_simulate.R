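#!/usr/bin/env Rscript
# Generate the synthetic study dataset: gene annotation, per-replicate
# peak sets for TCFL5 (2 CUT&RUN + 3 ChIP) and A-MYB (2 CUT&RUN +
# 1 ChIP), stage-profiled expression counts with ERCC spike-in rows, a
# two-genotype dataset with planted 0.2-fold knockdown effects, and the
# truth table the later scripts score against.

source("analysis/_config.R")

cfg <- study_cfg()
dir <- results_dir("sim")

ann <- gen_annotation(cfg)
truth <- gen_truth(ann, cfg)
pks <- gen_peaks(ann, truth, cfg)
gc <- gen_counts(ann, truth, cfg)
de_ct <- gen_de_dataset(ann, truth, cfg)

# annotation as BED6
start <- ifelse(ann$strand == "+", ann$tss, ann$tss - ann$gene_length + 1L)
writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ann$chrom, start,
                   start + ann$gene_length, ann$gene_id, ann$strand),
           file.path(dir, "genes.bed"))

# peaks as narrowPeak, one file per TF/assay/replicate, plus a manifest
manifest <- unique(pks[, c("tf", "assay", "replicate")])
manifest$path <- file.path(dir, sprintf("%s_%s_rep%d.narrowPeak",
                                        gsub("-", "", manifest$tf),
                                        manifest$assay, manifest$replicate))
manifest$dialect <- "narrowpeak"
for (i in seq_len(nrow(manifest))) {
  sub <- pks[pks$tf == manifest$tf[i] & pks$assay == manifest$assay[i] &
               pks$replicate == manifest$replicate[i], ]
  writeLines(sprintf("%s\t%d\t%d\tpk%d\t%d\t.\t%g\t-1\t-1\t%d", sub$chrom,
                     sub$start, sub$end, seq_len(nrow(sub)),
                     round(sub$score), sub$score, sub$summit - sub$start),
             manifest$path[i])
}
write.table(manifest, file.path(dir, "peak_manifest.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

write_ct <- function(ct, cpath, mpath) {
  df <- data.frame(gene_id = rownames(ct$counts), ct$counts,
                   check.names = FALSE)
  write.table(df, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ct$meta, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
}
write_ct(gc$counts, file.path(dir, "counts.tsv"), file.path(dir, "meta.tsv"))
write_ct(de_ct, file.path(dir, "de_counts.tsv"),
         file.path(dir, "de_meta.tsv"))
write.table(truth, file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("simulated %d genes, %d peaks across %d peak files\n",
            nrow(ann), nrow(pks), nrow(manifest)))
cat(sprintf("planted categories: %s\n",
            paste(names(table(truth$category)), table(truth$category),
                  sep = "=", collapse = ", ")))
cat("outputs in", dir, "\n")
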