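# lncRNA catalog construction: candidate filtering, known/novel split,
# positional classification (lincRNA / intronic / antisense), summary stats.

#' Filtering parameters for lncRNA candidate selection
#'
#' @param min_length minimum spliced transcript length in bases. lncRNAs are
#'   by definition noncoding transcripts longer than 200 nt, so this must be
#'   at least 200.
#' @param min_exons_novel minimum exon count required of novel candidates;
#'   transcripts matching the reference lncRNA annotation are exempt, so
#'   annotated single-exon lncRNAs survive.
#' @param min_fpkm minimum FPKM required in at least one sample.
#' @param coding_score_max maximum coding-potential score (PhyloCSF
#'   convention: lower = less coding) for a transcript with a provided score.
#' @param orf_max_codons a transcript whose longest open reading frame is
#'   shorter than this many codons is treated as noncoding when only a
#'   sequence (no score) is available.
#' @return list of class `filter_params`.
#' @export
filter_params <- function(min_length = 200, min_exons_novel = 2,
                          min_fpkm = 0.5, coding_score_max = 0,
                          orf_max_codons = 100) {
  if (min_length < 200) stop("min_length must be >= 200 (lncRNA definition)")
  vals <- c(min_length, min_exons_novel, min_fpkm, coding_score_max,
            orf_max_codons)
  if (any(!is.finite(vals))) stop("filter thresholds must be finite")
  structure(list(min_length = min_length, min_exons_novel = min_exons_novel,
                 min_fpkm = min_fpkm, coding_score_max = coding_score_max,
                 orf_max_codons = orf_max_codons),
            class = "filter_params")
}

# any same/opposite-strand exonic overlap of candidate spans against a set of
# exons; tx_rows is the candidate's exon subset, other an annotation_set
.has_exonic_overlap <- function(chrom, strand, starts, ends, other,
                                strand_mode) {
  o <- other[other$chrom == chrom, , drop = FALSE]
  if (nrow(o) == 0) return(FALSE)
  ok <- vapply(o$strand, .strand_compatible, logical(1),
               sb = strand, strand_mode = strand_mode)
  o <- o[ok, , drop = FALSE]
  if (nrow(o) == 0) return(FALSE)
  .interval_overlap_bases(starts, ends, o$start, o$end) > 0
}

#' Longest open reading frame of a transcript sequence
#'
#' Scans the three forward frames of a sense-strand transcript sequence for
#' the longest ATG-to-stop open reading frame. A crude but serviceable
#' surrogate for coding potential: transcripts whose longest ORF is shorter
#' than ~100 codons are unlikely to encode protein.
#'
#' @param seq character scalar, nucleotide sequence (ACGT, case-insensitive).
#' @return length of the longest ORF in codons (including the start codon,
#'   excluding the stop); 0 when no ORF exists.
#' @export
longest_orf_codons <- function(seq) {
  s <- toupper(seq)
  n <- nchar(s)
  if (n < 6) return(0L)
  codons_at <- function(offset) {
    starts <- seq(1 + offset, n - 2, by = 3)
    substring(s, starts, starts + 2)
  }
  best <- 0L
  for (off in 0:2) {
    if (n - off < 6) next
    cod <- codons_at(off)
    is_start <- cod == "ATG"
    is_stop <- cod %in% c("TAA", "TAG", "TGA")
    open_from <- NA_integer_
    for (i in seq_along(cod)) {
      if (is.na(open_from) && is_start[i]) open_from <- i
      if (!is.na(open_from) && is_stop[i]) {
        best <- max(best, i - open_from)
        open_from <- NA_integer_
      }
    }
  }
  as.integer(best)
}

#' Filter assembled transcripts to reliable lncRNA candidates
#'
#' Applies the identification pipeline's filters in order, keeping transcripts
#' that satisfy all of:
#' \enumerate{
#'   \item spliced length >= `min_length` (the > 200 nt lncRNA definition);
#'   \item exon count >= `min_exons_novel`, unless the transcript matches the
#'     reference lncRNA annotation (see [split_known_novel()]);
#'   \item maximum FPKM across samples >= `min_fpkm` (reliable expression);
#'   \item no same-strand exonic overlap with any protein-coding transcript;
#'   \item coding-potential filter: provided score <= `coding_score_max` when
#'     a score exists; else longest ORF < `orf_max_codons` when a sequence
#'     exists; else pass with a warning.
#' }
#' A per-stage attrition log records how many transcripts each filter removed.
#'
#' @param assembled annotation_set of assembled transcript models.
#' @param coding_ref annotation_set of protein-coding reference transcripts.
#' @param expr expression_matrix in FPKM covering every assembled transcript.
#' @param params [filter_params()].
#' @param lnc_ref optional annotation_set of reference lncRNAs, used only to
#'   exempt annotated transcripts from the exon-count filter.
#' @param scores optional named numeric vector of coding-potential scores.
#' @param sequences optional named character vector of transcript sequences
#'   for the ORF surrogate.
#' @return list with `candidates` (character vector of surviving transcript
#'   ids) and `attrition` (data.frame `stage`, `n_removed`, in pipeline
#'   order).
#' @export
filter_candidates <- function(assembled, coding_ref, expr,
                              params = filter_params(), lnc_ref = NULL,
                              scores = NULL, sequences = NULL) {
  stopifnot(inherits(assembled, "annotation_set"),
            inherits(coding_ref, "annotation_set"),
            inherits(expr, "expression_matrix"),
            inherits(params, "filter_params"))
  tx <- transcripts(assembled)
  missing_expr <- setdiff(tx$transcript_id, rownames(expr$values))
  if (length(missing_expr) > 0) {
    stop("transcript(s) missing from expression matrix: ",
         paste(missing_expr, collapse = ", "))
  }
  alive <- tx$transcript_id
  attrition <- data.frame(stage = character(), n_removed = integer(),
                          stringsAsFactors = FALSE)
  drop_stage <- function(alive, keep, stage) {
    attrition <<- rbind(attrition, data.frame(
      stage = stage, n_removed = sum(!keep), stringsAsFactors = FALSE))
    alive[keep]
  }

  # 1. length
  keep <- tx$length[match(alive, tx$transcript_id)] >= params$min_length
  alive <- drop_stage(alive, keep, "min_length")

  # 2. exon count (known transcripts exempt)
  n_ex <- tx$n_exons[match(alive, tx$transcript_id)]
  exempt <- if (!is.null(lnc_ref) && length(alive) > 0) {
    split_known_novel(assembled, lnc_ref, ids = alive) == "known"
  } else {
    rep(FALSE, length(alive))
  }
  keep <- n_ex >= params$min_exons_novel | exempt
  alive <- drop_stage(alive, keep, "min_exons")

  # 3. expression
  if (length(alive) > 0) {
    mx <- apply(expr$values[alive, , drop = FALSE], 1, max)
    keep <- mx >= params$min_fpkm
  } else keep <- logical(0)
  alive <- drop_stage(alive, keep, "min_fpkm")

  # 4. same-strand exonic overlap with protein-coding transcripts
  keep <- vapply(alive, function(id) {
    rows <- assembled[assembled$transcript_id == id, , drop = FALSE]
    !.has_exonic_overlap(rows$chrom[1], rows$strand[1], rows$start, rows$end,
                         coding_ref, "same")
  }, logical(1))
  alive <- drop_stage(alive, keep, "coding_overlap")

  # 5. coding potential
  warned <- FALSE
  keep <- vapply(alive, function(id) {
    if (!is.null(scores) && id %in% names(scores)) {
      return(scores[[id]] <= params$coding_score_max)
    }
    if (!is.null(sequences) && id %in% names(sequences)) {
      return(longest_orf_codons(sequences[[id]]) < params$orf_max_codons)
    }
    warned <<- TRUE
    TRUE
  }, logical(1))
  if (warned) {
    warning("no coding-potential score or sequence for some transcripts; ",
            "they pass the coding filter unassessed")
  }
  alive <- drop_stage(alive, keep, "coding_potential")

  list(candidates = alive, attrition = attrition)
}

# intron-chain keys for every transcript of an annotation_set
.chain_keys <- function(ann) {
  tx <- transcripts(ann)
  keys <- vapply(tx$transcript_id, function(id) {
    intron_chain(transcript_model(ann, id))
  }, character(1))
  stats::setNames(keys, tx$transcript_id)
}

#' Split lncRNA candidates into known and novel
#'
#' A candidate is "known" when it matches the reference lncRNA annotation:
#' multi-exon transcripts match by identical intron chain (terminal exon ends
#' may differ); single-exon transcripts match a single-exon reference lncRNA
#' on the same strand with exonic overlap of at least half the shorter
#' transcript. Everything else is "novel".
#'
#' @param candidates annotation_set containing the candidate transcripts.
#' @param lnc_ref annotation_set of reference lncRNAs.
#' @param ids optional subset of candidate transcript ids to label (defaults
#'   to all).
#' @return named character vector (`"known"`/`"novel"`) over `ids`.
#' @export
split_known_novel <- function(candidates, lnc_ref, ids = NULL) {
  stopifnot(inherits(candidates, "annotation_set"),
            inherits(lnc_ref, "annotation_set"))
  if (is.null(ids)) ids <- unique(candidates$transcript_id)
  if (length(ids) == 0) return(stats::setNames(character(), character()))
  ref_chains <- .chain_keys(lnc_ref)
  ref_chains <- ref_chains[!is.na(ref_chains)]
  ref_tx <- transcripts(lnc_ref)
  ref_single <- ref_tx[ref_tx$n_exons == 1, , drop = FALSE]
  out <- vapply(ids, function(id) {
    m <- transcript_model(candidates, id)
    if (nrow(m$exons) >= 2) {
      return(if (intron_chain(m) %in% ref_chains) "known" else "novel")
    }
    hits <- ref_single[ref_single$chrom == m$chrom &
                         (ref_single$strand == m$strand |
                            ref_single$strand == "*" | m$strand == "*"), ,
                       drop = FALSE]
    if (nrow(hits) == 0) return("novel")
    ov <- pmin(hits$end, m$end) - pmax(hits$start, m$start)
    shorter <- pmin(hits$length, m$length)
    if (any(ov >= 0.5 * shorter)) "known" else "novel"
  }, character(1))
  stats::setNames(out, ids)
}

# introns of one transcript model as a data.frame(start, end)
.introns_of <- function(m) {
  n <- nrow(m$exons)
  if (n < 2) return(data.frame(start = numeric(), end = numeric()))
  data.frame(start = m$exons$end[-n], end = m$exons$start[-1])
}

#' Classify a lncRNA by position relative to protein-coding genes
#'
#' Classes, in precedence order:
#' \enumerate{
#'   \item `antisense` — any exonic overlap (>= 1 bp) with a protein-coding
#'     exon on the opposite strand; exon contact is the strongest positional
#'     evidence so it wins over containment;
#'   \item `intronic` — every exon lies within introns of one protein-coding
#'     transcript (either strand);
#'   \item `lincRNA` — otherwise (intergenic; no exonic contact and not
#'     intron-contained).
#' }
#' Assumes the transcript already passed [filter_candidates()], so it has no
#' same-strand exonic overlap with coding exons.
#'
#' @param t transcript model (see [transcript_model()]).
#' @param coding_ref annotation_set of protein-coding transcripts.
#' @return one of `"lincRNA"`, `"intronic"`, `"antisense"`.
#' @export
classify_lncrna <- function(t, coding_ref) {
  t <- .as_model(t)
  stopifnot(inherits(coding_ref, "annotation_set"))
  cod <- coding_ref[coding_ref$chrom == t$chrom, , drop = FALSE]
  if (nrow(cod) > 0 && t$strand %in% c("+", "-")) {
    opp <- cod[cod$strand != t$strand & cod$strand %in% c("+", "-"), ,
               drop = FALSE]
    if (nrow(opp) > 0 &&
        .interval_overlap_bases(t$exons$start, t$exons$end,
                                opp$start, opp$end) > 0) {
      return("antisense")
    }
  }
  # intronic: all exons inside introns of a single coding transcript
  if (nrow(cod) > 0) {
    for (cid in unique(cod$transcript_id)) {
      cm <- transcript_model(coding_ref, cid)
      if (cm$start > t$start || cm$end < t$end) next
      intr <- .introns_of(cm)
      if (nrow(intr) == 0) next
      contained <- vapply(seq_len(nrow(t$exons)), function(i) {
        any(intr$start <= t$exons$start[i] & t$exons$end[i] <= intr$end)
      }, logical(1))
      if (all(contained)) return("intronic")
    }
  }
  "lincRNA"
}

#' Build the full lncRNA catalog
#'
#' Composes [filter_candidates()], [split_known_novel()] and
#' [classify_lncrna()] into the end-to-end identification pipeline.
#'
#' @inheritParams filter_candidates
#' @param lnc_ref annotation_set of reference lncRNAs (required here: it
#'   drives the known/novel split).
#' @return list with `catalog` (data.frame: `transcript_id`, `locus_id`,
#'   `novelty`, `positional_class`, `length`, `n_exons`, `coding_score`) and
#'   `attrition` (from the filter).
#' @export
build_catalog <- function(assembled, coding_ref, lnc_ref, expr,
                          params = filter_params(), scores = NULL,
                          sequences = NULL) {
  filt <- filter_candidates(assembled, coding_ref, expr, params = params,
                            lnc_ref = lnc_ref, scores = scores,
                            sequences = sequences)
  ids <- filt$candidates
  tx <- transcripts(assembled)
  tx <- tx[match(ids, tx$transcript_id), , drop = FALSE]
  novelty <- if (length(ids) > 0) {
    unname(split_known_novel(assembled, lnc_ref, ids = ids))
  } else character()
  classes <- vapply(ids, function(id) {
    classify_lncrna(transcript_model(assembled, id), coding_ref)
  }, character(1), USE.NAMES = FALSE)
  score <- if (!is.null(scores)) {
    unname(scores[ids])
  } else rep(NA_real_, length(ids))
  catalog <- data.frame(
    transcript_id = ids, locus_id = tx$gene_id, novelty = novelty,
    positional_class = classes, length = tx$length, n_exons = tx$n_exons,
    coding_score = score, stringsAsFactors = FALSE
  )
  rownames(catalog) <- NULL
  list(catalog = catalog, attrition = filt$attrition)
}

#' Summary statistics of a lncRNA catalog
#'
#' @param catalog data.frame as produced by [build_catalog()] (columns
#'   `transcript_id`, `locus_id`, `novelty`, `positional_class`, `length`,
#'   `n_exons`).
#' @param expr optional expression_matrix in FPKM; when given, the expression
#'   distribution is summarized as the per-transcript mean of
#'   `log10(FPKM + 1)` across samples.
#' @return list of class `catalog_stats`: `n_transcripts`, `n_loci`,
#'   `mean_length`, `mean_exons`, `isoforms_per_locus`
#'   (= n_transcripts / n_loci), `class_counts` (novelty x positional class
#'   table), and `expression` (named numeric vector, possibly empty).
#' @export
catalog_stats <- function(catalog, expr = NULL) {
  if (is.null(catalog) || nrow(catalog) == 0) {
    stop("catalog_stats: empty catalog")
  }
  n_tx <- nrow(catalog)
  n_loci <- length(unique(catalog$locus_id))
  expr_summary <- numeric()
  if (!is.null(expr)) {
    ids <- intersect(catalog$transcript_id, rownames(expr$values))
    if (length(ids) > 0) {
      expr_summary <- rowMeans(log10(expr$values[ids, , drop = FALSE] + 1))
    }
  }
  structure(list(
    n_transcripts = n_tx,
    n_loci = n_loci,
    mean_length = mean(catalog$length),
    mean_exons = mean(catalog$n_exons),
    isoforms_per_locus = n_tx / n_loci,
    class_counts = table(novelty = catalog$novelty,
                         positional_class = catalog$positional_class),
    expression = expr_summary
  ), class = "catalog_stats")
}

#' @export
print.catalog_stats <- function(x, ...) {
  cat(sprintf(paste0("lncRNA catalog: %d transcripts / %d loci ",
                     "(%.2f isoforms per locus)\n"),
              x$n_transcripts, x$n_loci, x$isoforms_per_locus))
  cat(sprintf("mean length %.0f bp, mean exons %.2f\n",
              x$mean_length, x$mean_exons))
  print(x$class_counts)
  invisible(x)
}
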