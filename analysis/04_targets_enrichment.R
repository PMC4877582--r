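#!/usr/bin/env Rscript
# Stage 4 — lncRNA target prediction and gene-set enrichment.
#
# cis targets: protein-coding loci within 100 kb of a catalog lncRNA.
# trans targets: loci with |PCC| > 0.95 beyond 100 kb or on another
# chromosome. Neighbor-pair correlation analysis compares lncRNA:cis-mRNA,
# mRNA:cis-mRNA and random protein-coding pairs. Enrichment scores the DE
# mRNA loci against the simulated gene sets with the hypergeometric test.

library(lnckit)

d <- "results/sim"
groups <- read_groups(file.path(d, "groups.tsv"))
counts <- read_expression(file.path(d, "counts.tsv"), groups, "fragments")
lengths_tab <- read.delim(file.path(d, "lengths.tsv"))
totals_tab <- read.delim(file.path(d, "totals.tsv"))
fpkm <- compute_fpkm(counts,
                     setNames(lengths_tab$length, lengths_tab$transcript_id),
                     setNames(totals_tab$total, totals_tab$sample_id))
assembled <- read_gtf(file.path(d, "assembled.gtf"))
coding <- read_gtf(file.path(d, "coding_ref.gtf"))
catalog <- read.delim("results/catalog.tsv")
lnc_ann <- annotation_set(as.data.frame(
  assembled[assembled$transcript_id %in% catalog$transcript_id, ]))

cis <- cis_targets(lnc_ann, coding, expr = fpkm)
trans <- trans_targets(lnc_ann, coding, fpkm)
cat(sprintf("cis pairs: %d; trans pairs: %d\n", nrow(cis), nrow(trans)))
top <- cis[!is.na(cis$pcc), ]
top <- top[which.max(abs(top$pcc)), ]
cat(sprintf("top cis pair: %s ~ %s (distance %d bp, PCC %.2f)\n",
            top$lncrna_id, top$mrna_id, top$distance, top$pcc))
write.table(cis, "results/cis_targets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(trans, "results/trans_targets.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ncor <- neighbor_correlation_analysis(lnc_ann, coding, fpkm, seed = 1)
print(ncor)

truth <- read.delim(file.path(d, "ground_truth.tsv"))
de1 <- read.delim(list.files("results", "^de_.*vs_CTRL", full.names = TRUE)[1])
fg_tx <- de1$transcript_id[de1$significant &
                             de1$transcript_id %in%
                               truth$transcript_id[truth$type == "mRNA"]]
fg <- unique(truth$locus_id[truth$transcript_id %in% fg_tx])
bg <- unique(truth$locus_id[truth$type == "mRNA"])
enr <- hypergeometric_enrichment(fg, bg, read_gmt(file.path(d, "gene_sets.gmt")))
cat("top enriched terms (q < 0.05 marked):\n")
print(head(enr, 5), row.names = FALSE)
write.table(enr, "results/enrichment_de1.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
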