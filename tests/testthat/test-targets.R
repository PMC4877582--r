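# cis/trans target prediction, random-pair null, neighbor-pair correlation,
# hypergeometric enrichment.

# lncRNA at 0-1kb; genes at 51 kb, exactly 100 kb, and 151 kb; one on chr2
target_fixture <- function() {
  lnc <- make_ann(list(
    L1 = list(chrom = "chr1", gene = "XL1", exons = list(c(0, 1000)))
  ))
  mrna <- make_ann(list(
    near.1 = list(chrom = "chr1", gene = "near", biotype = "protein_coding",
                  exons = list(c(51000, 52000))),
    edge.1 = list(chrom = "chr1", gene = "edge", biotype = "protein_coding",
                  exons = list(c(101000, 102000))),
    far.1 = list(chrom = "chr1", gene = "far", biotype = "protein_coding",
                 exons = list(c(151000, 152000))),
    other.1 = list(chrom = "chr2", gene = "other", biotype = "protein_coding",
                   exons = list(c(0, 1000)))
  ))
  list(lnc = lnc, mrna = mrna)
}

test_that("cis pairing uses an inclusive 100 kb span-gap window", {
  fx <- target_fixture()
  cis <- cis_targets(fx$lnc, fx$mrna, window = 1e5)
  expect_setequal(cis$mrna_id, c("near", "edge"))
  expect_equal(cis$distance[cis$mrna_id == "near"], 50000)
  expect_equal(cis$distance[cis$mrna_id == "edge"], 100000)  # boundary kept
  expect_true(all(cis$mode == "cis"))
})

test_that("trans pairing requires strong correlation and positional remoteness", {
  fx <- target_fixture()
  ids <- c("L1", "near.1", "edge.1", "far.1", "other.1")
  set.seed(13)
  prof <- rnorm(9, 0, 1)
  v <- rbind(
    L1 = 2^(5 + prof),
    near.1 = 2^(5 + prof + rnorm(9, 0, 0.01)),   # r ~ 1 but within window
    edge.1 = 2^rnorm(9, 5, 1),                   # uncorrelated
    far.1 = 2^(5 - prof + rnorm(9, 0, 0.01)),    # r ~ -1, beyond window
    other.1 = 2^(5 + prof + rnorm(9, 0, 0.01))   # r ~ 1, other chromosome
  )
  colnames(v) <- paste0("s", 1:9)
  expr <- expression_matrix(v, stats::setNames(rep(c("A", "B", "C"), each = 3),
                                               colnames(v)), unit = "FPKM")
  tr <- trans_targets(fx$lnc, fx$mrna, expr, pcc_min = 0.95, window = 1e5)
  expect_setequal(tr$mrna_id, c("far", "other"))
  expect_lt(tr$pcc[tr$mrna_id == "far"], -0.95)
  expect_equal(tr$distance[tr$mrna_id == "other"], Inf)
  # cis and trans sets are disjoint by the distance rule
  cis <- cis_targets(fx$lnc, fx$mrna, expr = expr, window = 1e5)
  expect_length(intersect(paste(cis$lncrna_id, cis$mrna_id),
                          paste(tr$lncrna_id, tr$mrna_id)), 0)
})

test_that("random pair draws are seeded, distinct and exhaustive at full count", {
  p1 <- random_pair_null(letters[1:10], 20, seed = 4)
  p2 <- random_pair_null(letters[1:10], 20, seed = 4)
  expect_identical(p1, p2)
  expect_false(identical(p1, random_pair_null(letters[1:10], 20, seed = 5)))
  all6 <- random_pair_null(letters[1:4], 6, seed = 1)
  expect_equal(nrow(unique(all6)), 6)
  expect_true(all(all6$id_1 < all6$id_2))
  expect_error(random_pair_null(letters[1:4], 7, seed = 1), "exceeds")
  expect_error(random_pair_null("a", 1, seed = 1), "at least 2")
})

test_that("random pairs from independent expression have mean PCC near zero", {
  set.seed(19)
  n_genes <- 60
  v <- matrix(2^rnorm(n_genes * 9, 5, 1), n_genes, 9,
              dimnames = list(paste0("g", 1:n_genes), paste0("s", 1:9)))
  pairs <- random_pair_null(rownames(v), 1000, seed = 2)
  lv <- log10(v + 1)
  pccs <- mapply(function(a, b) stats::cor(lv[a, ], lv[b, ]),
                 pairs$id_1, pairs$id_2)
  se <- sd(pccs) / sqrt(length(pccs))
  expect_lt(abs(mean(pccs)), 3 * se + 0.05)
})

test_that("neighbor-pair analysis recovers a planted correlation structure", {
  # 20 isolated (lncRNA, gene) couples and 20 isolated gene-gene couples,
  # each pair 10 kb apart and > 200 kb from everything else
  rho <- 0.3
  lnc_list <- list(); mrna_list <- list()
  for (i in 1:20) {
    off <- (i - 1) * 3e5
    lnc_list[[sprintf("L%02d", i)]] <-
      list(chrom = "chr1", gene = sprintf("XL%02d", i),
           exons = list(c(off, off + 1000)))
    mrna_list[[sprintf("gl%02d.1", i)]] <-
      list(chrom = "chr1", gene = sprintf("gl%02d", i),
           exons = list(c(off + 11000, off + 12000)))
  }
  for (i in 1:20) {
    off <- 1e7 + (i - 1) * 3e5
    mrna_list[[sprintf("ga%02d.1", i)]] <-
      list(chrom = "chr2", gene = sprintf("ga%02d", i),
           exons = list(c(off, off + 1000)))
    mrna_list[[sprintf("gb%02d.1", i)]] <-
      list(chrom = "chr2", gene = sprintf("gb%02d", i),
           exons = list(c(off + 11000, off + 12000)))
  }
  lnc <- make_ann(lnc_list); mrna <- make_ann(mrna_list)
  set.seed(23)
  n_s <- 9
  draw_pair <- function(rho) {
    z <- rnorm(n_s)
    cbind(sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_s),
          sqrt(rho) * z + sqrt(1 - rho) * rnorm(n_s))
  }
  rows <- list()
  for (i in 1:20) {
    xy <- draw_pair(rho)
    rows[[sprintf("L%02d", i)]] <- 2^(5 + 2 * xy[, 1])
    rows[[sprintf("gl%02d.1", i)]] <- 2^(5 + 2 * xy[, 2])
  }
  for (i in 1:20) {
    xy <- draw_pair(rho)
    rows[[sprintf("ga%02d.1", i)]] <- 2^(5 + 2 * xy[, 1])
    rows[[sprintf("gb%02d.1", i)]] <- 2^(5 + 2 * xy[, 2])
  }
  v <- do.call(rbind, rows)
  colnames(v) <- paste0("s", 1:n_s)
  expr <- expression_matrix(v, stats::setNames(rep(c("A", "B", "C"), each = 3),
                                               colnames(v)), unit = "FPKM")
  res <- neighbor_correlation_analysis(lnc, mrna, expr, window = 1e5, seed = 3)
  se_cls <- function(cl) sd(cl$pccs) / sqrt(cl$n)
  expect_lt(abs(res$classes$lnc_cis$mean_pcc - rho),
            3 * se_cls(res$classes$lnc_cis) + 0.05)
  expect_lt(abs(res$classes$mrna_cis$mean_pcc - rho),
            3 * se_cls(res$classes$mrna_cis) + 0.05)
  expect_lt(abs(res$classes$random$mean_pcc),
            3 * se_cls(res$classes$random) + 0.05)
  expect_equal(res$classes$random$n, res$classes$lnc_cis$n)
  expect_equal(nrow(res$tests), 3)
})

test_that("degenerate expression leaves empty pair classes and errors", {
  fx <- target_fixture()
  v <- matrix(5, 5, 9, dimnames = list(c("L1", "near.1", "edge.1", "far.1",
                                         "other.1"), paste0("s", 1:9)))
  expr <- expression_matrix(v, stats::setNames(rep(c("A", "B", "C"), each = 3),
                                               colnames(v)), unit = "FPKM")
  expect_error(neighbor_correlation_analysis(fx$lnc, fx$mrna, expr),
               "empty class")
})

test_that("hypergeometric enrichment matches closed-form and enumeration", {
  bg <- paste0("g", 1:10)
  fg <- paste0("g", 1:4)
  sets <- list(hit = paste0("g", c(1:4, 6)),       # K=5, k=4
               none = paste0("g", 9:10),           # k=0 -> p = 1
               all = bg)                           # term of everything -> p = 1
  res <- hypergeometric_enrichment(fg, bg, sets)
  expect_equal(res$p_raw[res$term == "hit"], 5 / 210)
  expect_equal(res$p_raw[res$term == "none"], 1)
  expect_equal(res$p_raw[res$term == "all"], 1)
  expect_equal(res$rich_factor[res$term == "hit"], 4 / 5)
  expect_true(all(res$q >= res$p_raw))
  expect_error(hypergeometric_enrichment(c("g1", "zz"), bg, sets),
               "not in background")
  # enumeration oracle on random small universes
  set.seed(41)
  for (i in 1:20) {
    N <- sample(6:12, 1); K <- sample(1:(N - 1), 1); n <- sample(1:(N - 1), 1)
    bgx <- paste0("x", 1:N)
    fgx <- sample(bgx, n)
    term <- list(t = bgx[1:K])
    r <- hypergeometric_enrichment(fgx, bgx, term)
    expect_equal(r$p_raw, enum_hyper_tail(N, K, n, r$k), tolerance = 1e-12)
  }
})

test_that("significance never grows as the term family grows", {
  set.seed(47)
  bg <- paste0("g", 1:50)
  fg <- sample(bg, 12)
  sets <- lapply(1:12, function(i) sample(bg, sample(5:15, 1)))
  names(sets) <- paste0("T", 1:12)
  small <- hypergeometric_enrichment(fg, bg, sets[1:4])
  large <- hypergeometric_enrichment(fg, bg, sets)
  for (tm in small$term[small$significant]) {
    expect_gte(small$q[small$term == tm] + 1e-12,
               small$p_raw[small$term == tm])
  }
  sig_small <- small$term[small$significant]
  sig_large <- large$term[large$significant & large$term %in% small$term]
  expect_true(all(sig_large %in% sig_small))
})

test_that("rich factor is k / K with validated domain", {
  expect_equal(rich_factor(5, 20), 0.25)
  expect_equal(rich_factor(0, 7), 0)
  expect_equal(rich_factor(7, 7), 1)
  expect_error(rich_factor(1, 0), "K")
  expect_error(rich_factor(5, 3), "k")
})

test_that("GMT files round-trip", {
  sets <- list(A = c("g1", "g2"), B = c("g2", "g3", "g4"))
  f <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, f, descriptions = c(A = "first", B = "second"))
  back <- read_gmt(f)
  expect_equal(back[["A"]], sets$A)
  expect_equal(back[["B"]], sets$B)
  expect_equal(attr(back, "descriptions")[["A"]], "first")
  writeLines("term_only\tdesc", f)
  expect_error(read_gmt(f), "malformed")
})
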