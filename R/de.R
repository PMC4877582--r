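# Differential expression: signed fold change, pooled-variance t-test,
# Benjamini-Hochberg adjustment, per-comparison calling, common-DE
# intersection, sample clustering by correlation distance.

#' Signed fold change between two group means
#'
#' Ratio of pseudocounted means, `(mean_a + pc) / (mean_b + pc)`, reported
#' with the usual signed convention: ratios below 1 are returned as
#' `-1 / ratio`, so a halving appears as -2 rather than 0.5 and fold-change
#' tables read symmetrically for up- and down-regulation.
#'
#' @param mean_a,mean_b non-negative group mean abundances (FPKM).
#' @param pseudocount positive stabilizing offset (default 1).
#' @return signed fold change (`1` for equal means; never in `(-1, 1)`).
#' @export
fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(mean_a < 0) || any(mean_b < 0)) stop("negative means")
  ratio <- (mean_a + pseudocount) / (mean_b + pseudocount)
  ifelse(ratio < 1, -1 / ratio, ratio)
}

#' Two-sided pooled-variance (Student's) two-sample t-test
#'
#' Classic equal-variance t-test returning the two-sided p-value. A floor of
#' `1e-8` on the pooled variance keeps the statistic finite when both groups
#' are (near-)constant; when the two groups are constant and equal the test
#' is degenerate and returns p = 1 by convention.
#'
#' @param a,b numeric vectors, each of length >= 2, finite.
#' @return list with `t`, `df`, `p`.
#' @export
student_t_test <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 observations per group")
  if (!all(is.finite(a)) || !all(is.finite(b))) stop("non-finite values")
  na <- length(a); nb <- length(b)
  df <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
  if (sp2 == 0 && mean(a) == mean(b)) {
    return(list(t = 0, df = df, p = 1))
  }
  sp2 <- max(sp2, 1e-8)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tstat, df = df, p = 2 * stats::pt(-abs(tstat), df))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: with p-values sorted ascending, the i-th adjusted
#' value is `min over j >= i of p_(j) * m / j`, capped at 1, returned in the
#' original input order. Inputs outside `[0, 1]` are rejected.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values (q-values), same order as input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric())
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Call differential expression between two sample groups
#'
#' For every transcript: Student's t-test on `log2(FPKM + pseudocount)`
#' between the two groups, signed fold change of the group FPKM means, BH
#' adjustment across all transcripts tested in the comparison, and a
#' significance call at `p_adj < alpha`. Direction is `"up"` when group `a`
#' exceeds group `b`.
#'
#' @param expr expression_matrix in FPKM.
#' @param group_a,group_b group labels present in `expr$sample_groups`, each
#'   with at least 2 samples.
#' @param alpha significance level on the adjusted p-value (default 0.05).
#' @param pseudocount offset for both the log transform and the fold change.
#' @return data.frame with one row per transcript: `transcript_id`,
#'   `group_a`, `group_b`, `mean_a`, `mean_b`, `fold_change`, `log2_fc`,
#'   `p_raw`, `p_adj`, `direction`, `significant`.
#' @export
call_de <- function(expr, group_a, group_b, alpha = 0.05, pseudocount = 1) {
  stopifnot(inherits(expr, "expression_matrix"))
  groups <- expr$sample_groups
  for (g in c(group_a, group_b)) {
    if (sum(groups == g) < 2) {
      stop("group not present with >= 2 samples: ", g)
    }
  }
  va <- expr$values[, groups == group_a, drop = FALSE]
  vb <- expr$values[, groups == group_b, drop = FALSE]
  la <- log2(va + pseudocount)
  lb <- log2(vb + pseudocount)
  na <- ncol(la); nb <- ncol(lb); df <- na + nb - 2
  ma <- rowMeans(la); mb <- rowMeans(lb)
  vara <- apply(la, 1, stats::var)
  varb <- apply(lb, 1, stats::var)
  sp2 <- ((na - 1) * vara + (nb - 1) * varb) / df
  degenerate <- sp2 == 0 & ma == mb
  sp2 <- pmax(sp2, 1e-8)
  tstat <- (ma - mb) / sqrt(sp2 * (1 / na + 1 / nb))
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  p_raw[degenerate] <- 1
  p_adj <- bh_adjust(p_raw)
  mean_a <- rowMeans(va); mean_b <- rowMeans(vb)
  fc <- fold_change(mean_a, mean_b, pseudocount)
  out <- data.frame(
    transcript_id = rownames(expr$values),
    group_a = group_a, group_b = group_b,
    mean_a = mean_a, mean_b = mean_b,
    fold_change = fc,
    log2_fc = log2((mean_a + pseudocount) / (mean_b + pseudocount)),
    p_raw = p_raw, p_adj = p_adj,
    direction = ifelse(fc >= 1, "up", "down"),
    significant = p_adj < alpha,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Intersect two sets of significant transcript ids
#'
#' @param de_1,de_2 character vectors of transcript ids (or data.frames from
#'   [call_de()], in which case the significant ids are taken).
#' @return ids present in both, in the order of `de_1`.
#' @export
intersect_common_de <- function(de_1, de_2) {
  pick <- function(x) {
    if (is.data.frame(x)) x$transcript_id[x$significant] else as.character(x)
  }
  a <- pick(de_1); b <- pick(de_2)
  a[a %in% b]
}

#' Hierarchical clustering of samples by correlation distance
#'
#' Agglomerative average-linkage clustering of sample expression profiles
#' over a transcript subset, with distance `1 - PCC` between samples
#' (profiles taken on `log2(FPKM + 1)`). Samples with zero variance over the
#' subset cannot be correlated and are excluded with a warning.
#'
#' @param expr expression_matrix.
#' @param transcript_subset transcript ids to cluster on (e.g. a DE set);
#'   default all.
#' @return `hclust` object over the retained samples (cut with
#'   [stats::cutree()]).
#' @export
hierarchical_cluster <- function(expr, transcript_subset = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  ids <- transcript_subset %||% rownames(expr$values)
  missing_ids <- setdiff(ids, rownames(expr$values))
  if (length(missing_ids) > 0) {
    stop("transcripts not in matrix: ", paste(missing_ids, collapse = ", "))
  }
  if (length(ids) < 2) stop("need >= 2 transcripts to correlate samples")
  v <- log2(expr$values[ids, , drop = FALSE] + 1)
  if (ncol(v) < 2) stop("need >= 2 samples")
  sample_var <- apply(v, 2, stats::var)
  if (any(sample_var == 0)) {
    warning("excluding zero-variance sample(s): ",
            paste(colnames(v)[sample_var == 0], collapse = ", "))
    v <- v[, sample_var > 0, drop = FALSE]
    if (ncol(v) < 2) stop("fewer than 2 samples with variance")
  }
  d <- stats::as.dist(1 - stats::cor(v))
  stats::hclust(d, method = "average")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
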