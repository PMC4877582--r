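# lncRNA target prediction (cis within a genomic window, trans by strong
# coexpression), neighbor-pair correlation analysis with a random-pair null,
# and hypergeometric gene-set enrichment.

# evaluate expr with a private, seeded RNG stream; global RNG state untouched
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Union spans of gene loci
#'
#' Gene-level positions for neighborhood tests: for each locus (gene_id) the
#' union span of its transcripts on one chromosome/strand.
#'
#' @param ann annotation_set.
#' @return data.frame `locus_id`, `chrom`, `strand`, `start`, `end`.
#' @export
locus_spans <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  tx <- transcripts(ann)
  if (nrow(tx) == 0) {
    return(data.frame(locus_id = character(), chrom = character(),
                      strand = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  first <- !duplicated(tx$gene_id)
  ids <- tx$gene_id[first]
  out <- data.frame(
    locus_id = ids,
    chrom = tx$chrom[first],
    strand = tx$strand[first],
    start = as.numeric(tapply(tx$start, tx$gene_id, min)[ids]),
    end = as.numeric(tapply(tx$end, tx$gene_id, max)[ids]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Aggregate transcript expression to locus level
#'
#' Sums FPKM over the transcripts of each locus. Used for gene-level
#' correlation in cis/trans target prediction.
#'
#' @param expr expression_matrix in FPKM.
#' @param ann annotation_set mapping transcripts to loci.
#' @return numeric matrix, loci x samples.
#' @export
locus_expression <- function(expr, ann) {
  stopifnot(inherits(expr, "expression_matrix"), inherits(ann, "annotation_set"))
  tx <- transcripts(ann)
  tx <- tx[tx$transcript_id %in% rownames(expr$values), , drop = FALSE]
  if (nrow(tx) == 0) stop("no annotated transcript present in the matrix")
  v <- expr$values[tx$transcript_id, , drop = FALSE]
  rowsum(v, group = tx$gene_id)
}

# span gap between interval (s1,e1) and vectors (s2,e2); Inf across chroms
.span_gap <- function(chrom1, s1, e1, chrom2, s2, e2) {
  gap <- pmax(0, pmax(s1, s2) - pmin(e1, e2))
  gap[chrom1 != chrom2] <- Inf
  gap
}

# correlation of log10(FPKM + 1) profiles; NA (with a count) for zero variance
.pcc_log10 <- function(x, y) {
  lx <- log10(x + 1); ly <- log10(y + 1)
  if (stats::var(lx) == 0 || stats::var(ly) == 0) return(NA_real_)
  stats::cor(lx, ly)
}

#' Predict cis targets of lncRNAs
#'
#' A protein-coding locus is a candidate cis target of a lncRNA when it lies
#' within `window` bases of the lncRNA on the same chromosome (span gap,
#' inclusive boundary: a locus exactly `window` bases away is kept). When
#' expression is supplied, the Pearson correlation of the pair's
#' `log10(FPKM + 1)` profiles is attached (lncRNA at transcript level, coding
#' locus as the FPKM sum of its transcripts); pairs with a zero-variance
#' member get `NA` with the count recorded in attribute `n_zero_variance`.
#'
#' @param lnc_ann annotation_set of lncRNA transcripts.
#' @param mrna_ann annotation_set of protein-coding transcripts.
#' @param expr optional expression_matrix in FPKM covering both.
#' @param window neighborhood size in bases (default 100 kb).
#' @return data.frame `lncrna_id`, `mrna_id` (locus), `mode` (`"cis"`),
#'   `distance`, `pcc`.
#' @export
cis_targets <- function(lnc_ann, mrna_ann, expr = NULL, window = 1e5) {
  stopifnot(inherits(lnc_ann, "annotation_set"),
            inherits(mrna_ann, "annotation_set"))
  ltx <- transcripts(lnc_ann)
  loci <- locus_spans(mrna_ann)
  rows <- list()
  for (i in seq_len(nrow(ltx))) {
    gap <- .span_gap(ltx$chrom[i], ltx$start[i], ltx$end[i],
                     loci$chrom, loci$start, loci$end)
    hit <- which(gap <= window)
    if (length(hit) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        lncrna_id = ltx$transcript_id[i], mrna_id = loci$locus_id[hit],
        mode = "cis", distance = gap[hit], pcc = NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(lncrna_id = character(), mrna_id = character(),
               mode = character(), distance = numeric(), pcc = numeric(),
               stringsAsFactors = FALSE)
  }
  n_zero <- 0L
  if (!is.null(expr) && nrow(out) > 0) {
    gene_expr <- locus_expression(expr, mrna_ann)
    for (i in seq_len(nrow(out))) {
      lid <- out$lncrna_id[i]; mid <- out$mrna_id[i]
      if (lid %in% rownames(expr$values) && mid %in% rownames(gene_expr)) {
        pcc <- .pcc_log10(expr$values[lid, ], gene_expr[mid, ])
        if (is.na(pcc)) n_zero <- n_zero + 1L
        out$pcc[i] <- pcc
      }
    }
  }
  rownames(out) <- NULL
  attr(out, "n_zero_variance") <- n_zero
  out
}

#' Predict trans targets of lncRNAs by strong coexpression
#'
#' A protein-coding locus is a candidate trans target when its expression is
#' strongly correlated with the lncRNA (`|PCC| > pcc_min`, strict, on
#' `log10(FPKM + 1)` profiles) and it is positionally remote: more than
#' `window` bases away or on a different chromosome. The distance rule makes
#' cis and trans sets disjoint for any pair.
#'
#' @inheritParams cis_targets
#' @param expr expression_matrix in FPKM (required).
#' @param pcc_min correlation magnitude threshold (default 0.95).
#' @return data.frame `lncrna_id`, `mrna_id`, `mode` (`"trans"`), `distance`
#'   (`Inf` across chromosomes), `pcc`.
#' @export
trans_targets <- function(lnc_ann, mrna_ann, expr, pcc_min = 0.95,
                          window = 1e5) {
  stopifnot(inherits(lnc_ann, "annotation_set"),
            inherits(mrna_ann, "annotation_set"),
            inherits(expr, "expression_matrix"))
  ltx <- transcripts(lnc_ann)
  ltx <- ltx[ltx$transcript_id %in% rownames(expr$values), , drop = FALSE]
  loci <- locus_spans(mrna_ann)
  gene_expr <- locus_expression(expr, mrna_ann)
  loci <- loci[loci$locus_id %in% rownames(gene_expr), , drop = FALSE]
  if (nrow(ltx) == 0 || nrow(loci) == 0) {
    return(data.frame(lncrna_id = character(), mrna_id = character(),
                      mode = character(), distance = numeric(),
                      pcc = numeric(), stringsAsFactors = FALSE))
  }
  llog <- t(log10(expr$values[ltx$transcript_id, , drop = FALSE] + 1))
  glog <- t(log10(gene_expr[loci$locus_id, , drop = FALSE] + 1))
  lvar <- apply(llog, 2, stats::var)
  gvar <- apply(glog, 2, stats::var)
  pcc <- suppressWarnings(stats::cor(llog, glog))
  pcc[lvar == 0, ] <- NA
  pcc[, gvar == 0] <- NA
  rows <- list()
  for (i in seq_len(nrow(ltx))) {
    gap <- .span_gap(ltx$chrom[i], ltx$start[i], ltx$end[i],
                     loci$chrom, loci$start, loci$end)
    hit <- which(!is.na(pcc[i, ]) & abs(pcc[i, ]) > pcc_min & gap > window)
    if (length(hit) > 0) {
      rows[[length(rows) + 1]] <- data.frame(
        lncrna_id = ltx$transcript_id[i], mrna_id = loci$locus_id[hit],
        mode = "trans", distance = gap[hit], pcc = pcc[i, hit],
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else {
    data.frame(lncrna_id = character(), mrna_id = character(),
               mode = character(), distance = numeric(), pcc = numeric(),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Sample random protein-coding gene pairs
#'
#' Draws `n_pairs` distinct unordered pairs uniformly without replacement,
#' reproducibly under `seed`. Used as the null class in the neighbor-pair
#' correlation analysis.
#'
#' @param mrna_ids character vector of at least 2 gene ids.
#' @param n_pairs number of pairs to draw (at most `choose(n, 2)`).
#' @param seed integer seed; the global RNG state is left untouched.
#' @return data.frame `id_1`, `id_2` with `id_1 < id_2` within each pair.
#' @export
random_pair_null <- function(mrna_ids, n_pairs, seed) {
  mrna_ids <- unique(as.character(mrna_ids))
  n <- length(mrna_ids)
  if (n < 2) stop("need at least 2 gene ids")
  total <- choose(n, 2)
  if (n_pairs > total) {
    stop(sprintf("n_pairs (%d) exceeds the %d distinct pairs available",
                 n_pairs, total))
  }
  ks <- .with_seed(seed, sample.int(total, n_pairs))
  # unrank: pair index k -> (i, j), i < j, pairs ordered (1,2),(1,3),...,(1,n),(2,3),...
  cum <- cumsum((n - 1):1)
  i <- findInterval(ks - 1, c(0, cum), rightmost.closed = FALSE)
  j <- i + (ks - c(0, cum)[i])
  a <- mrna_ids[pmin(i, j)]; b <- mrna_ids[pmax(i, j)]
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  data.frame(id_1 = a, id_2 = b, stringsAsFactors = FALSE)
}

#' Neighbor-pair correlation analysis
#'
#' Compares the expression correlation of three pair classes:
#' `lnc_cis` (lncRNA with each protein-coding locus within `window`),
#' `mrna_cis` (protein-coding locus pairs within `window` of each other) and
#' `random` (uniformly drawn protein-coding pairs, count matched to the
#' `lnc_cis` class). Correlations are Pearson on `log10(FPKM + 1)` profiles
#' across all samples; pairs with a zero-variance member are excluded with a
#' logged count. Class means are compared with Student's t-test.
#'
#' @inheritParams trans_targets
#' @param seed seed for the random-pair draw.
#' @return list of class `neighbor_correlation`: `classes` (named list; each
#'   with `pccs`, `mean_pcc`, `n`, `n_excluded`), and `tests` (data.frame of
#'   pairwise class comparisons with t and p).
#' @export
neighbor_correlation_analysis <- function(lnc_ann, mrna_ann, expr,
                                          window = 1e5, seed = 1) {
  cis <- cis_targets(lnc_ann, mrna_ann, expr = expr, window = window)
  lnc_pcc <- cis$pcc[!is.na(cis$pcc)]
  lnc_excl <- sum(is.na(cis$pcc))

  loci <- locus_spans(mrna_ann)
  gene_expr <- locus_expression(expr, mrna_ann)
  loci <- loci[loci$locus_id %in% rownames(gene_expr), , drop = FALSE]
  mrna_pcc <- numeric(); mrna_excl <- 0L
  if (nrow(loci) >= 2) {
    ord <- order(loci$chrom, loci$start)
    loci <- loci[ord, , drop = FALSE]
    for (i in seq_len(nrow(loci) - 1)) {
      for (j in (i + 1):nrow(loci)) {
        if (loci$chrom[j] != loci$chrom[i]) break
        gap <- max(0, loci$start[j] - loci$end[i])
        if (gap > window) break
        pcc <- .pcc_log10(gene_expr[loci$locus_id[i], ],
                          gene_expr[loci$locus_id[j], ])
        if (is.na(pcc)) mrna_excl <- mrna_excl + 1L else {
          mrna_pcc <- c(mrna_pcc, pcc)
        }
      }
    }
  }

  if (length(lnc_pcc) < 2) stop("empty class: fewer than 2 lncRNA cis pairs")
  if (length(mrna_pcc) < 2) stop("empty class: fewer than 2 mRNA cis pairs")
  rnd <- random_pair_null(loci$locus_id, min(length(lnc_pcc),
                                             choose(nrow(loci), 2)), seed)
  rnd_pcc <- numeric(); rnd_excl <- 0L
  for (i in seq_len(nrow(rnd))) {
    pcc <- .pcc_log10(gene_expr[rnd$id_1[i], ], gene_expr[rnd$id_2[i], ])
    if (is.na(pcc)) rnd_excl <- rnd_excl + 1L else rnd_pcc <- c(rnd_pcc, pcc)
  }
  if (length(rnd_pcc) < 2) stop("empty class: fewer than 2 random pairs")

  classes <- list(
    lnc_cis = list(pccs = lnc_pcc, mean_pcc = mean(lnc_pcc),
                   n = length(lnc_pcc), n_excluded = lnc_excl),
    mrna_cis = list(pccs = mrna_pcc, mean_pcc = mean(mrna_pcc),
                    n = length(mrna_pcc), n_excluded = mrna_excl),
    random = list(pccs = rnd_pcc, mean_pcc = mean(rnd_pcc),
                  n = length(rnd_pcc), n_excluded = rnd_excl)
  )
  cmp <- list(c("lnc_cis", "random"), c("mrna_cis", "random"),
              c("lnc_cis", "mrna_cis"))
  tests <- do.call(rbind, lapply(cmp, function(pair) {
    tt <- student_t_test(classes[[pair[1]]]$pccs, classes[[pair[2]]]$pccs)
    data.frame(class_a = pair[1], class_b = pair[2], t = tt$t, p = tt$p,
               stringsAsFactors = FALSE)
  }))
  structure(list(classes = classes, tests = tests),
            class = "neighbor_correlation")
}

#' @export
print.neighbor_correlation <- function(x, ...) {
  for (nm in names(x$classes)) {
    cl <- x$classes[[nm]]
    cat(sprintf("%-9s n = %4d  mean PCC = %+.3f  (%d excluded)\n",
                nm, cl$n, cl$mean_pcc, cl$n_excluded))
  }
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' For each term, with `N` background genes of which `K` belong to the term,
#' and a foreground of `n` genes of which `k` belong, the upper-tail
#' hypergeometric probability `P(X >= k)` is the enrichment p-value. Q-values
#' are BH-adjusted across all tested terms; a term is significant at
#' `q < alpha`. The rich factor is `k / K`. Terms are intersected with the
#' background first; terms with no background gene are dropped.
#'
#' @param foreground character vector of genes of interest (subset of
#'   `background`).
#' @param background character vector, the gene universe.
#' @param gene_sets named list of character vectors (term -> member genes),
#'   e.g. from [read_gmt()].
#' @param alpha significance level on the q-value (default 0.05).
#' @return data.frame, one row per tested term, sorted by `p_raw`: `term`,
#'   `k`, `K`, `n`, `N`, `p_raw`, `q`, `rich_factor`, `significant`.
#' @export
hypergeometric_enrichment <- function(foreground, background, gene_sets,
                                      alpha = 0.05) {
  foreground <- unique(as.character(foreground))
  background <- unique(as.character(background))
  stray <- setdiff(foreground, background)
  if (length(stray) > 0) {
    stop("foreground gene(s) not in background: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  N <- length(background); n <- length(foreground)
  rows <- lapply(names(gene_sets), function(term) {
    members <- intersect(unique(gene_sets[[term]]), background)
    K <- length(members)
    if (K == 0) return(NULL)
    k <- length(intersect(members, foreground))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, K = K, n = n, N = N, p_raw = p,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_raw = numeric(),
                      q = numeric(), rich_factor = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p_raw)
  out$rich_factor <- rich_factor(out$k, out$K)
  out$significant <- out$q < alpha
  out <- out[order(out$p_raw, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rich factor of an enriched term
#'
#' The number of enriched (foreground) genes in a term divided by the number
#' of background genes in that term.
#'
#' @param k foreground genes in the term, `0 <= k <= K`.
#' @param K background genes in the term, `> 0`.
#' @return `k / K`.
#' @export
rich_factor <- function(k, K) {
  if (any(K <= 0)) stop("K must be > 0")
  if (any(k < 0 | k > K)) stop("k must satisfy 0 <= k <= K")
  k / K
}

#' Read / write GMT gene-set files
#'
#' GMT format: one term per line, tab-separated: term id, description, then
#' member gene ids.
#'
#' @param path GMT file path.
#' @return `read_gmt`: named list of character vectors with a `descriptions`
#'   attribute.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) {
    stop("malformed GMT line ", which(lengths(fields) < 3)[1],
         ": need term, description and >= 1 gene")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1)
  attr(sets, "descriptions") <- stats::setNames(
    vapply(fields, `[[`, "", 2), names(sets))
  sets
}

#' @rdname read_gmt
#' @param gene_sets named list of character vectors.
#' @param descriptions optional named character vector of term descriptions.
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  lines <- vapply(names(gene_sets), function(term) {
    desc <- if (!is.null(descriptions) && term %in% names(descriptions)) {
      descriptions[[term]]
    } else "na"
    paste(c(term, desc, gene_sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
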