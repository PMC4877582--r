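#!/usr/bin/env Rscript
# Stage 3 — differential expression and sample clustering.
#
# Three pairwise comparisons (disease 1 vs control, disease 2 vs control,
# disease 1 vs disease 2) with a pooled-variance t-test on log2(FPKM + 1)
# and BH adjustment; common-DE mRNA intersection; average-linkage clustering
# of samples on 1 - PCC over the DE union and over the common-DE set.

library(lnckit)

d <- "results/sim"
groups <- read_groups(file.path(d, "groups.tsv"))
counts <- read_expression(file.path(d, "counts.tsv"), groups, "fragments")
lengths_tab <- read.delim(file.path(d, "lengths.tsv"))
totals_tab <- read.delim(file.path(d, "totals.tsv"))
fpkm <- compute_fpkm(counts,
                     setNames(lengths_tab$length, lengths_tab$transcript_id),
                     setNames(totals_tab$total, totals_tab$sample_id))
glab <- unique(unname(groups))          # disease1, disease2, control
truth <- read.delim(file.path(d, "ground_truth.tsv"))
mrna_ids <- truth$transcript_id[truth$type == "mRNA"]

de <- list()
for (cmp in list(c(glab[1], glab[3]), c(glab[2], glab[3]),
                 c(glab[1], glab[2]))) {
  nm <- paste0(cmp[1], "_vs_", cmp[2])
  de[[nm]] <- call_de(fpkm, cmp[1], cmp[2])
  with(de[[nm]], cat(sprintf(
    "%s: %d significant (%d up, %d down) of %d tested\n", nm,
    sum(significant), sum(significant & direction == "up"),
    sum(significant & direction == "down"), length(significant))))
  write.table(de[[nm]], file.path("results", paste0("de_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

sig_mrna <- lapply(de[1:2], function(x) {
  x$transcript_id[x$significant & x$transcript_id %in% mrna_ids]
})
common <- intersect_common_de(sig_mrna[[1]], sig_mrna[[2]])
cat("common dysregulated mRNAs across the two disease comparisons:",
    length(common), "\n")
write.table(data.frame(transcript_id = common), "results/common_de_mrna.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

de_union <- unique(unlist(lapply(de, function(x) {
  x$transcript_id[x$significant]
})))
hc <- hierarchical_cluster(fpkm, de_union)
cut3 <- cutree(hc, 3)
cat("clusters at k = 3 on the DE union vs true groups:\n")
print(table(cluster = cut3, group = groups[names(cut3)]))
if (length(common) >= 2) {
  cut2 <- cutree(hierarchical_cluster(fpkm, common), 2)
  cat("clusters at k = 2 on the common-DE signature (diseases merge):\n")
  print(table(cluster = cut2, group = groups[names(cut2)]))
}
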