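#!/usr/bin/env Rscript
# Stage 2 — lncRNA catalog construction.
#
# Reads the assembled models and references from results/sim/, computes FPKM,
# applies the five identification filters (length >= 200 nt, exon count,
# expression, same-strand coding overlap, coding potential), splits known
# from novel against the reference lncRNA annotation and assigns each lncRNA
# a positional class. Scores the catalog against the generator's truth.

library(lnckit)

d <- "results/sim"
groups <- read_groups(file.path(d, "groups.tsv"))
counts <- read_expression(file.path(d, "counts.tsv"), groups, "fragments")
lengths_tab <- read.delim(file.path(d, "lengths.tsv"))
totals_tab <- read.delim(file.path(d, "totals.tsv"))
scores_tab <- read.delim(file.path(d, "scores.tsv"))
fpkm <- compute_fpkm(counts,
                     setNames(lengths_tab$length, lengths_tab$transcript_id),
                     setNames(totals_tab$total, totals_tab$sample_id))

res <- build_catalog(read_gtf(file.path(d, "assembled.gtf")),
                     read_gtf(file.path(d, "coding_ref.gtf")),
                     read_gtf(file.path(d, "lnc_ref.gtf")),
                     fpkm,
                     scores = setNames(scores_tab$score,
                                       scores_tab$transcript_id))

cat("attrition through the filters:\n")
print(res$attrition)
st <- catalog_stats(res$catalog, fpkm)
print(st)

truth <- read.delim(file.path(d, "ground_truth.tsv"))
m <- match(res$catalog$transcript_id, truth$transcript_id)
cat(sprintf("class recovery %.0f%%, novelty recovery %.0f%% (n = %d)\n",
            100 * mean(res$catalog$positional_class == truth$true_class[m]),
            100 * mean(res$catalog$novelty == truth$true_novelty[m]),
            nrow(res$catalog)))

write.table(res$catalog, "results/catalog.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(res$attrition, "results/attrition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("catalog written to results/catalog.tsv\n")
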