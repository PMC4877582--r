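# Catalog construction: filters with attrition, known/novel split,
# positional classification, summary statistics.

# a coding gene with 3 exons and generous introns, used as overlap bait
coding_fixture <- function() {
  make_ann(list(
    cod.1 = list(chrom = "chr1", strand = "+", gene = "gc", biotype = "protein_coding",
                 exons = list(c(10000, 10300), c(15000, 15200), c(20000, 20400)))
  ))
}

test_that("each filter removes its designated offender, in pipeline order", {
  coding <- coding_fixture()
  assembled_tx <- list(
    too_short = list(chrom = "chr1", exons = list(c(1000, 1150))),
    one_exon = list(chrom = "chr1", exons = list(c(2000, 2400))),
    silent = list(chrom = "chr1",
                  exons = list(c(3000, 3300), c(4000, 4300))),
    sense_olap = list(chrom = "chr1", strand = "+",
                      exons = list(c(10100, 10250), c(15050, 15150))),
    coding_like = list(chrom = "chr1",
                       exons = list(c(6000, 6300), c(7000, 7300))),
    survivor = list(chrom = "chr1",
                    exons = list(c(40000, 40400), c(41000, 41400)))
  )
  assembled <- make_ann(assembled_tx)
  v <- matrix(10, nrow = length(assembled_tx), ncol = 9,
              dimnames = list(names(assembled_tx), NULL))
  v["silent", ] <- 0.1
  expr <- make_expr(v)
  scores <- c(coding_like = 80, survivor = -10, too_short = -10,
              one_exon = -10, silent = -10, sense_olap = -10)
  res <- filter_candidates(assembled, coding, expr, scores = scores)
  expect_equal(res$candidates, "survivor")
  expect_equal(res$attrition$stage,
               c("min_length", "min_exons", "min_fpkm", "coding_overlap",
                 "coding_potential"))
  expect_equal(res$attrition$n_removed, rep(1L, 5))
  # attrition sums to input minus output
  expect_equal(sum(res$attrition$n_removed),
               nrow(transcripts(assembled)) - length(res$candidates))
})

test_that("transcripts missing from the expression matrix are named in the error", {
  assembled <- make_ann(list(t1 = list(exons = list(c(0, 400), c(600, 900)))))
  expr <- make_expr(matrix(1, 1, 9, dimnames = list("other", NULL)))
  expect_error(filter_candidates(assembled, coding_fixture(), expr), "t1")
})

test_that("reference-matched transcripts are exempt from the exon-count filter", {
  assembled <- make_ann(list(
    known1 = list(chrom = "chr1", exons = list(c(2000, 2600))),
    novel1 = list(chrom = "chr1", exons = list(c(5000, 5600)))
  ))
  lnc_ref <- make_ann(list(
    ref1 = list(chrom = "chr1", exons = list(c(2100, 2700)))
  ))
  expr <- make_expr(matrix(10, 2, 9, dimnames = list(c("known1", "novel1"), NULL)))
  res <- filter_candidates(assembled, coding_fixture(), expr, lnc_ref = lnc_ref,
                           scores = c(known1 = -5, novel1 = -5))
  expect_equal(res$candidates, "known1")
})

test_that("known/novel split uses intron chains and the 50% single-exon rule", {
  cands <- make_ann(list(
    chain_match = list(chrom = "chr1",
                       exons = list(c(100, 300), c(800, 1000))),
    no_overlap = list(chrom = "chr1", exons = list(c(5000, 5500))),
    single_60 = list(chrom = "chr1", exons = list(c(2000, 2500))),
    single_40 = list(chrom = "chr1", exons = list(c(3000, 3500)))
  ))
  lnc_ref <- make_ann(list(
    # same intron chain (300-800) with different terminal ends
    ref_chain = list(chrom = "chr1", exons = list(c(50, 300), c(800, 1100))),
    # 60% of the shorter transcript overlaps single_60
    ref_s60 = list(chrom = "chr1", exons = list(c(2200, 2700))),
    # only 40% overlaps single_40
    ref_s40 = list(chrom = "chr1", exons = list(c(3300, 3800)))
  ))
  lab <- split_known_novel(cands, lnc_ref)
  expect_equal(unname(lab[c("chain_match", "no_overlap",
                            "single_60", "single_40")]),
               c("known", "novel", "known", "novel"))
  # overlap fraction cross-checked against the base-count oracle
  ov <- oracle_overlap_bases(transcript_model(cands, "single_60"),
                             transcript_model(lnc_ref, "ref_s60"))
  expect_gte(ov, 0.5 * 500)
  # reflexivity: reference transcripts match themselves
  self <- split_known_novel(lnc_ref, lnc_ref)
  expect_true(all(self == "known"))
})

test_that("positional classification follows the antisense > intronic > lincRNA precedence", {
  coding <- coding_fixture()
  far <- make_model(exons = list(c(50000, 50500)))
  expect_equal(classify_lncrna(far, coding), "lincRNA")
  inside_intron <- make_model(strand = "+", exons = list(c(16000, 16400)))
  expect_equal(classify_lncrna(inside_intron, coding), "intronic")
  # opposite-strand exon contact wins even while inside the gene span
  anti <- make_model(strand = "-", exons = list(c(14800, 15100)))
  expect_equal(classify_lncrna(anti, coding), "antisense")
  # two exons in two different introns of one host: still intronic
  two_introns <- make_model(strand = "-",
                            exons = list(c(11000, 11300), c(16000, 16300)))
  expect_equal(classify_lncrna(two_introns, coding), "intronic")
})

test_that("classification matches the per-base oracle on random topologies", {
  set.seed(11)
  for (i in 1:200) {
    n_genes <- sample(1:3, 1)
    coding <- make_ann(stats::setNames(lapply(seq_len(n_genes), function(g) {
      m <- random_model(max_pos = 1000)
      list(chrom = "chr1", strand = m$strand, biotype = "protein_coding",
           exons = lapply(seq_len(nrow(m$exons)),
                          function(j) c(m$exons$start[j], m$exons$end[j])))
    }), paste0("g", seq_len(n_genes))))
    t <- random_model(max_pos = 1000)
    expect_equal(classify_lncrna(t, coding), oracle_classify(t, coding),
                 info = sprintf("topology %d", i))
  }
})

test_that("with no coding loci everything is lincRNA", {
  empty <- annotation_set(data.frame(transcript_id = character(),
                                     gene_id = character(),
                                     chrom = character(), start = numeric(),
                                     end = numeric()))
  set.seed(3)
  for (i in 1:20) {
    expect_equal(classify_lncrna(random_model(), empty), "lincRNA")
  }
})

test_that("catalog statistics are exact means and ratios", {
  catalog <- data.frame(
    transcript_id = c("a", "b", "c"),
    locus_id = c("l1", "l1", "l2"),
    novelty = c("novel", "novel", "known"),
    positional_class = c("lincRNA", "lincRNA", "antisense"),
    length = c(100, 200, 300),
    n_exons = c(1, 2, 3),
    stringsAsFactors = FALSE
  )
  st <- catalog_stats(catalog)
  expect_equal(st$mean_length, 200)
  expect_equal(st$mean_exons, 2)
  expect_equal(st$isoforms_per_locus, 1.5)
  expect_equal(sum(st$class_counts), st$n_transcripts)
  expect_error(catalog_stats(catalog[0, ]), "empty")
})

test_that("the ORF surrogate finds the longest start-to-stop frame", {
  # ATG + 3 codons + TAA in frame 0: ORF of 4 codons
  expect_equal(longest_orf_codons("ATGAAACCCGGGTAA"), 4L)
  expect_equal(longest_orf_codons("CCCCCCCCC"), 0L)
  # offset by one base: same ORF in frame 1
  expect_equal(longest_orf_codons("CATGAAACCCGGGTAA"), 4L)
})
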