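# Transcript models, GTF/BED I/O and interval arithmetic.

test_that("GTF exon lines are parsed with the 1-based-closed convention", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tsrc\texon\t301\t400\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    'chr1\tsrc\tCDS\t101\t190\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";'
  ), f)
  ann <- read_gtf(f)
  expect_equal(ann$start, c(100, 300))
  expect_equal(ann$end, c(200, 400))
  tx <- transcripts(ann)
  expect_equal(tx$n_exons, 2L)
  expect_equal(tx$length, 200)
})

test_that("malformed GTF lines are rejected with the line number", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\texon\t101\t200\t.\t+\t.\ttranscript_id "t1"; gene_id "g1";',
    "chr1\tonly\tthree"
  ), f)
  expect_error(read_gtf(f), "line 2")
  writeLines('chr1\tsrc\texon\t500\t400\t.\t+\t.\ttranscript_id "t"; gene_id "g";', f)
  expect_error(read_gtf(f), "end < start")
})

test_that("write_gtf / read_gtf round-trip preserves the exon set", {
  ann <- make_ann(list(
    t1 = list(chrom = "chr2", strand = "-", gene = "gA",
              exons = list(c(100, 200), c(500, 650))),
    t2 = list(chrom = "chr1", strand = "+", gene = "gB",
              exons = list(c(0, 120)))
  ))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  back <- read_gtf(f)
  key <- function(a) {
    a <- as.data.frame(a)
    a[order(a$transcript_id, a$start),
      c("transcript_id", "gene_id", "chrom", "start", "end", "strand")]
  }
  expect_equal(key(back), key(ann), ignore_attr = TRUE)
  # internal half-open (100, 200) prints as 1-based closed "101 200"
  expect_true(any(grepl("\t101\t200\t", readLines(f))))
  # empty set -> empty file, idempotent
  empty <- annotation_set(data.frame(transcript_id = character(),
                                     gene_id = character(),
                                     chrom = character(), start = numeric(),
                                     end = numeric()))
  write_gtf(empty, f)
  expect_length(readLines(f), 0)
  expect_equal(nrow(read_gtf(f)), 0)
})

test_that("read_gtf agrees with rtracklayer on a shared fixture", {
  skip_if_not_installed("rtracklayer")
  ann <- make_ann(list(
    t1 = list(chrom = "chr1", strand = "+",
              exons = list(c(99, 250), c(300, 401))),
    t2 = list(chrom = "chr2", strand = "-", exons = list(c(10, 1000)))
  ))
  f <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(ann, f)
  gr <- rtracklayer::import(f, format = "gtf")
  gr <- gr[gr$type == "exon"]
  got <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    id = gr$transcript_id)
  got <- got[order(got$id, got$start), ]
  ours <- as.data.frame(ann)[order(ann$transcript_id, ann$start), ]
  expect_equal(got$start, ours$start)
  expect_equal(got$end, ours$end)
  expect_equal(got$id, ours$transcript_id)
})

test_that("BED intervals pass through in their native half-open convention", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100", "chr2\t500\t800\tx\t0\t-", "chr1\t5\t6"), f)
  bed <- read_bed(f)
  expect_equal(nrow(bed), 3)
  expect_equal(bed$start, c(0, 500, 5))
  expect_equal(bed$end, c(100, 800, 6))
  expect_equal(bed$strand, c("*", "-", "*"))
  writeLines(character(), f)
  expect_equal(nrow(read_bed(f)), 0)
  writeLines("chr1\tfoo\tbar", f)
  expect_error(read_bed(f), "non-numeric")
})

test_that("genomic distance is the span gap, zero on overlap, Inf across chromosomes", {
  a <- make_model(exons = list(c(100, 200)))
  b <- make_model(exons = list(c(150, 300)))
  c_ <- make_model(exons = list(c(300, 400)))
  d <- make_model(chrom = "chr2", exons = list(c(300, 400)))
  expect_equal(genomic_distance(a, b), 0)
  expect_equal(genomic_distance(a, c_), 100)
  expect_equal(genomic_distance(a, d), Inf)
  # abutting half-open spans touch: distance 0
  expect_equal(genomic_distance(a, make_model(exons = list(c(200, 250)))), 0)
})

test_that("genomic distance is symmetric and zero iff spans meet", {
  set.seed(42)
  for (i in 1:50) {
    a <- random_model(); b <- random_model()
    expect_identical(genomic_distance(a, b), genomic_distance(b, a))
    touches <- max(a$start, b$start) <= min(a$end, b$end)
    expect_identical(genomic_distance(a, b) == 0, touches)
  }
})

test_that("exonic overlap respects strand mode and equals the per-base count", {
  plus <- make_model(strand = "+", exons = list(c(100, 200)))
  minus <- make_model(strand = "-", exons = list(c(150, 300)))
  expect_equal(exonic_overlap(plus, plus, "same"), 100)
  expect_equal(exonic_overlap(plus, minus, "opposite"), 50)
  expect_equal(exonic_overlap(plus, minus, "same"), 0)
  set.seed(7)
  for (i in 1:200) {
    a <- random_model(); b <- random_model()
    expect_equal(exonic_overlap(a, b, "ignore"), oracle_overlap_bases(a, b))
    if (a$strand != "*" && b$strand != "*") {
      expect_equal(exonic_overlap(a, b, "ignore"),
                   exonic_overlap(a, b, "same") +
                     exonic_overlap(a, b, "opposite"))
    }
  }
})

test_that("feature overlap summary counts each locus once", {
  ann <- make_ann(list(
    a = list(exons = list(c(0, 100))),
    b = list(exons = list(c(200, 300))),
    c = list(exons = list(c(400, 500)))
  ))
  feats <- data.frame(chrom = "chr1", start = c(50, 60, 250),
                      end = c(80, 90, 260), strand = "*")
  expect_equal(feature_overlap_summary(ann, feats), 2 / 3)
  expect_equal(feature_overlap_summary(ann, feats[0, ]), 0)
  big <- data.frame(chrom = "chr1", start = 0, end = 1000, strand = "*")
  expect_equal(feature_overlap_summary(ann, big), 1)
  empty <- annotation_set(data.frame(transcript_id = character(),
                                     gene_id = character(),
                                     chrom = character(), start = numeric(),
                                     end = numeric()))
  expect_error(feature_overlap_summary(empty, feats), "empty")
})

test_that("annotation_set enforces its invariants", {
  expect_error(annotation_set(data.frame(transcript_id = "t", gene_id = "g",
                                         chrom = "chr1", start = 10, end = 5)),
               "end <= start")
  expect_error(make_ann(list(t = list(exons = list(c(0, 100), c(50, 150))))),
               "overlapping exons")
  expect_error(annotation_set(data.frame(transcript_id = "t", gene_id = "g",
                                         chrom = "chr1", start = 0, end = 10,
                                         strand = "x")),
               "strand")
})
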