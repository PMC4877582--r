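# Compact constructors and independent oracles used across the suite.

# build an annotation_set from a list of transcripts:
#   list(t1 = list(chrom=, strand=, gene=, exons=list(c(s,e), ...)), ...)
make_ann <- function(tx) {
  rows <- lapply(names(tx), function(id) {
    t <- tx[[id]]
    ex <- do.call(rbind, t$exons)
    data.frame(transcript_id = id,
               gene_id = t$gene %||% id,
               chrom = t$chrom %||% "chr1",
               start = ex[, 1], end = ex[, 2],
               strand = t$strand %||% "+",
               biotype = t$biotype %||% "other",
               stringsAsFactors = FALSE)
  })
  annotation_set(do.call(rbind, rows))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-transcript model without an annotation_set detour
make_model <- function(chrom = "chr1", strand = "+", exons,
                       id = "t", gene = "g") {
  ex <- do.call(rbind, exons)
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  list(transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
       biotype = "other",
       exons = data.frame(start = ex[, 1], end = ex[, 2]),
       start = min(ex[, 1]), end = max(ex[, 2]),
       length = sum(ex[, 2] - ex[, 1]))
}

# expression matrix over 3 groups x n samples from a plain matrix
make_expr <- function(values, n_per_group = 3,
                      groups = c("ECRSwNP", "nonECRSwNP", "CTRL"),
                      unit = "FPKM") {
  grp <- rep(groups, each = n_per_group)
  samples <- paste(grp, sequence(rep(n_per_group, length(groups))), sep = "_")
  colnames(values) <- samples
  expression_matrix(values, stats::setNames(grp, samples), unit = unit)
}

# --- independent oracles ---------------------------------------------------

# per-base membership overlap between two exon sets
oracle_overlap_bases <- function(a, b) {
  lim <- max(a$exons$end, b$exons$end)
  in_set <- function(m) {
    v <- logical(lim)
    for (i in seq_len(nrow(m$exons))) {
      if (m$exons$end[i] > m$exons$start[i]) {
        v[(m$exons$start[i] + 1):m$exons$end[i]] <- TRUE
      }
    }
    v
  }
  sum(in_set(a) & in_set(b))
}

# per-base reimplementation of the positional classification rules
oracle_classify <- function(t, coding_ref) {
  cod_tx <- transcripts(coding_ref)
  cod_tx <- cod_tx[cod_tx$chrom == t$chrom, , drop = FALSE]
  if (nrow(cod_tx) > 0 && t$strand %in% c("+", "-")) {
    for (cid in cod_tx$transcript_id) {
      cm <- transcript_model(coding_ref, cid)
      if (cm$strand != t$strand &&
          oracle_overlap_bases(t, cm) > 0) return("antisense")
    }
  }
  for (cid in cod_tx$transcript_id) {
    cm <- transcript_model(coding_ref, cid)
    n <- nrow(cm$exons)
    if (n < 2) next
    intron_bases <- logical(max(cm$exons$end))
    for (i in seq_len(n - 1)) {
      if (cm$exons$start[i + 1] > cm$exons$end[i]) {
        intron_bases[(cm$exons$end[i] + 1):cm$exons$start[i + 1]] <- TRUE
      }
    }
    ok <- all(vapply(seq_len(nrow(t$exons)), function(j) {
      span <- (t$exons$start[j] + 1):t$exons$end[j]
      all(span <= length(intron_bases)) && all(intron_bases[span])
    }, logical(1)))
    if (ok) return("intronic")
  }
  "lincRNA"
}

# O(m^2) step-up adjustment, straight from the definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (rank in seq_len(m)) {
    i <- ord[rank]
    q[i] <- min(1, min(p[ord[rank:m]] * m / (rank:m)))
  }
  q
}

# exhaustive hypergeometric upper tail P(X >= k) by subset enumeration
enum_hyper_tail <- function(N, K, n, k) {
  subsets <- utils::combn(N, n)
  mean(colSums(subsets <= K) >= k)
}

# random small transcript topology on a <= 1 kb span
random_model <- function(chrom = "chr1", max_pos = 1000) {
  n_ex <- sample(1:3, 1)
  pts <- sort(sample(0:max_pos, 2 * n_ex))
  ex <- lapply(seq_len(n_ex), function(i) {
    s <- pts[2 * i - 1]; e <- pts[2 * i]
    if (e == s) e <- e + 1
    c(s, e)
  })
  # re-separate abutting/overlapping exons introduced by the +1 fix
  for (i in seq_along(ex)[-1]) {
    if (ex[[i]][1] < ex[[i - 1]][2]) ex[[i]] <- ex[[i - 1]][2] + c(1, 3)
  }
  make_model(chrom = chrom, strand = sample(c("+", "-"), 1), exons = ex)
}
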