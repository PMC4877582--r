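# Transcript models and strand-aware interval arithmetic.
#
# Coordinate conventions: everything internal is 0-based half-open [start, end).
# GTF I/O is 1-based closed; BED I/O is 0-based half-open. Strand is one of
# "+", "-", "*" (unstranded); "*" matches either strand in overlap tests.

#' Construct an annotation set from an exon table
#'
#' An annotation set is the package's container for spliced transcript models:
#' a data frame with one row per exon and columns `transcript_id`, `gene_id`,
#' `chrom`, `start`, `end`, `strand`, `biotype`. Coordinates are 0-based
#' half-open. Exons of a transcript must lie on one chromosome and strand and
#' must not overlap one another; they are stored sorted by start.
#'
#' @param exons data.frame with columns `transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, and optionally `strand` (default `"*"`) and `biotype`
#'   (default `"other"`).
#' @return A data.frame of class `annotation_set`, exons sorted by
#'   (transcript, start).
#' @examples
#' ann <- annotation_set(data.frame(
#'   transcript_id = "t1", gene_id = "g1", chrom = "chr1",
#'   start = c(100, 300), end = c(200, 400), strand = "+"
#' ))
#' transcripts(ann)
#' @export
annotation_set <- function(exons) {
  stopifnot(is.data.frame(exons))
  required <- c("transcript_id", "gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(exons))
  if (length(missing_cols) > 0) {
    stop("exon table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)
  if (is.null(exons$strand)) exons$strand <- rep("*", nrow(exons))
  if (is.null(exons$biotype)) exons$biotype <- rep("other", nrow(exons))
  exons <- exons[, c("transcript_id", "gene_id", "chrom", "start", "end",
                     "strand", "biotype")]
  exons$transcript_id <- as.character(exons$transcript_id)
  exons$gene_id <- as.character(exons$gene_id)
  exons$chrom <- as.character(exons$chrom)
  exons$strand <- as.character(exons$strand)
  exons$biotype <- as.character(exons$biotype)
  exons$start <- as.numeric(exons$start)
  exons$end <- as.numeric(exons$end)
  if (nrow(exons) > 0) {
    if (any(!exons$strand %in% c("+", "-", "*"))) {
      stop("strand must be one of '+', '-', '*'")
    }
    if (any(exons$start < 0)) stop("negative exon start")
    bad <- exons$end <= exons$start
    if (any(bad)) {
      stop("exon end <= start for transcript(s): ",
           paste(unique(exons$transcript_id[bad]), collapse = ", "))
    }
    exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
    rownames(exons) <- NULL
    # per-transcript invariants: one chrom/strand/gene, non-overlapping exons
    for (fld in c("chrom", "strand", "gene_id")) {
      n_distinct <- tapply(exons[[fld]], exons$transcript_id,
                           function(x) length(unique(x)))
      if (any(n_distinct > 1)) {
        stop("transcript(s) with inconsistent ", fld, ": ",
             paste(names(n_distinct)[n_distinct > 1], collapse = ", "))
      }
    }
    overlapping <- tapply(seq_len(nrow(exons)), exons$transcript_id,
                          function(i) {
                            if (length(i) < 2) return(FALSE)
                            any(exons$start[i][-1] < exons$end[i][-length(i)])
                          })
    if (any(overlapping)) {
      stop("overlapping exons within transcript(s): ",
           paste(names(overlapping)[overlapping], collapse = ", "))
    }
  }
  class(exons) <- c("annotation_set", "data.frame")
  exons
}

#' @export
print.annotation_set <- function(x, ...) {
  tx <- unique(x$transcript_id)
  cat(sprintf("annotation_set: %d transcript(s), %d locus/loci, %d exon row(s)\n",
              length(tx), length(unique(x$gene_id)), nrow(x)))
  NextMethod()
}

#' Per-transcript summary of an annotation set
#'
#' @param ann annotation_set.
#' @return data.frame with one row per transcript: `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `biotype`, genomic span `start`/`end`, `n_exons`, and
#'   spliced `length` (sum of exon lengths).
#' @export
transcripts <- function(ann) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(ann) == 0) {
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), strand = character(),
                      biotype = character(), start = numeric(),
                      end = numeric(), n_exons = integer(),
                      length = numeric(), stringsAsFactors = FALSE))
  }
  first <- !duplicated(ann$transcript_id)
  ids <- ann$transcript_id[first]
  out <- data.frame(
    transcript_id = ids,
    gene_id = ann$gene_id[first],
    chrom = ann$chrom[first],
    strand = ann$strand[first],
    biotype = ann$biotype[first],
    start = as.numeric(tapply(ann$start, ann$transcript_id, min)[ids]),
    end = as.numeric(tapply(ann$end, ann$transcript_id, max)[ids]),
    n_exons = as.integer(tapply(ann$start, ann$transcript_id, length)[ids]),
    length = as.numeric(tapply(ann$end - ann$start, ann$transcript_id, sum)[ids]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Extract one transcript model
#'
#' @param ann annotation_set.
#' @param transcript_id id of the transcript to extract.
#' @return list with `transcript_id`, `gene_id`, `chrom`, `strand`, `biotype`,
#'   an `exons` data.frame (`start`, `end`, sorted), span `start`/`end`, and
#'   spliced `length`.
#' @export
transcript_model <- function(ann, transcript_id) {
  stopifnot(inherits(ann, "annotation_set"))
  rows <- ann[ann$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(rows) == 0) stop("unknown transcript_id: ", transcript_id)
  list(
    transcript_id = transcript_id,
    gene_id = rows$gene_id[1],
    chrom = rows$chrom[1],
    strand = rows$strand[1],
    biotype = rows$biotype[1],
    exons = data.frame(start = rows$start, end = rows$end),
    start = min(rows$start),
    end = max(rows$end),
    length = sum(rows$end - rows$start)
  )
}

.as_model <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$exons)) return(x)
  stop("expected a transcript model (see transcript_model())")
}

.parse_gtf_attr <- function(attr, key) {
  m <- regmatches(attr, regexpr(paste0(key, '\\s+"([^"]*)"'), attr))
  if (length(m) == 0) return(NA_character_)
  sub(paste0(key, '\\s+"([^"]*)"'), "\\1", m)
}

#' Read exon features from a GTF file
#'
#' Parses the `exon` features of a GTF file into an [annotation_set()].
#' GTF 1-based closed coordinates are converted to the internal 0-based
#' half-open convention. Each exon line must carry `transcript_id` and
#' `gene_id` attributes; a `biotype` attribute is kept when present.
#'
#' @param path path to a tab-delimited GTF file.
#' @param default_biotype biotype assigned when the attribute is absent.
#' @return annotation_set.
#' @export
read_gtf <- function(path, default_biotype = "other") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0) {
    return(annotation_set(data.frame(transcript_id = character(),
                                     gene_id = character(),
                                     chrom = character(),
                                     start = numeric(), end = numeric())))
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields < 9)) {
    stop("malformed GTF line ", idx[which(n_fields < 9)[1]],
         ": expected 9 tab-separated fields")
  }
  feat <- vapply(fields, `[[`, "", 3)
  exon <- feat == "exon"
  if (!any(exon)) {
    return(annotation_set(data.frame(transcript_id = character(),
                                     gene_id = character(),
                                     chrom = character(),
                                     start = numeric(), end = numeric())))
  }
  fields <- fields[exon]
  idx <- idx[exon]
  start1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4)))
  end1 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5)))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- which(is.na(start1) | is.na(end1))[1]
    stop("malformed GTF line ", idx[bad], ": non-numeric coordinates")
  }
  if (any(end1 < start1)) {
    bad <- which(end1 < start1)[1]
    stop("invalid GTF line ", idx[bad], ": end < start")
  }
  attrs <- vapply(fields, `[[`, "", 9)
  tid <- vapply(attrs, .parse_gtf_attr, "", key = "transcript_id",
                USE.NAMES = FALSE)
  gid <- vapply(attrs, .parse_gtf_attr, "", key = "gene_id", USE.NAMES = FALSE)
  if (anyNA(tid) || anyNA(gid)) {
    bad <- which(is.na(tid) | is.na(gid))[1]
    stop("malformed GTF line ", idx[bad],
         ": missing transcript_id or gene_id attribute")
  }
  bt <- vapply(attrs, .parse_gtf_attr, "", key = "biotype", USE.NAMES = FALSE)
  bt[is.na(bt)] <- default_biotype
  annotation_set(data.frame(
    transcript_id = tid, gene_id = gid,
    chrom = vapply(fields, `[[`, "", 1),
    start = start1 - 1, end = end1,
    strand = vapply(fields, `[[`, "", 7),
    biotype = bt, stringsAsFactors = FALSE
  ))
}

#' Write an annotation set to GTF
#'
#' Emits one `exon` feature per exon in 1-based closed coordinates with
#' `transcript_id`, `gene_id` and `biotype` attributes, ordered by
#' (chromosome, start, transcript_id) so output is deterministic.
#' `read_gtf(write_gtf(x))` reproduces the exon set of `x`.
#'
#' @param ann annotation_set.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  if (nrow(ann) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  ord <- order(ann$chrom, ann$start, ann$transcript_id)
  x <- ann[ord, , drop = FALSE]
  lines <- sprintf(
    '%s\tlnckit\texon\t%d\t%d\t.\t%s\t.\ttranscript_id "%s"; gene_id "%s"; biotype "%s";',
    x$chrom, as.integer(x$start) + 1L, as.integer(x$end), x$strand,
    x$transcript_id, x$gene_id, x$biotype
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED3+ file of genomic intervals
#'
#' BED coordinates are already 0-based half-open and are returned unchanged.
#' A sixth column, when present, is used as the strand; otherwise intervals
#' are unstranded (`"*"`).
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   preserving file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t|[ ]+")
  if (any(lengths(fields) < 3)) {
    stop("malformed BED line ", which(lengths(fields) < 3)[1],
         ": fewer than 3 fields")
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         ": non-numeric coordinates")
  }
  strand <- vapply(fields, function(f) {
    if (length(f) >= 6 && f[[6]] %in% c("+", "-")) f[[6]] else "*"
  }, "")
  data.frame(chrom = vapply(fields, `[[`, "", 1), start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Genomic distance between two transcript models
#'
#' The gap in bases between the genomic spans (first exon start to last exon
#' end) of two transcripts: 0 when the spans overlap or abut, `Inf` when the
#' transcripts lie on different chromosomes (the "unreachable" sentinel).
#' Span-based distance makes overlap equivalent to distance 0 and is the
#' conservative reading of "genomic distance" for neighborhood windows.
#'
#' @param a,b transcript models (see [transcript_model()]).
#' @return non-negative number of bases, or `Inf` if on different chromosomes.
#' @export
genomic_distance <- function(a, b) {
  a <- .as_model(a); b <- .as_model(b)
  if (a$chrom != b$chrom) return(Inf)
  max(0, max(a$start, b$start) - min(a$end, b$end))
}

.strand_compatible <- function(sa, sb, strand_mode) {
  if (strand_mode == "ignore") return(TRUE)
  if (sa == "*" || sb == "*") return(TRUE)
  if (strand_mode == "same") return(sa == sb)
  sa != sb  # opposite
}

# total overlap in bases between two sets of non-overlapping intervals
.interval_overlap_bases <- function(s1, e1, s2, e2) {
  if (length(s1) == 0 || length(s2) == 0) return(0)
  ov <- outer(e1, e2, pmin) - outer(s1, s2, pmax)
  sum(ov[ov > 0])
}

#' Exonic overlap between two transcript models
#'
#' Total number of bases shared by the exon sets of two transcripts, under a
#' strand-compatibility rule: `"same"` counts overlap only when the strands
#' agree, `"opposite"` only when they differ, `"ignore"` always. An
#' unstranded transcript (`"*"`) is compatible with either strand. Returns 0
#' when the chromosomes differ or the strand mode excludes the pair.
#'
#' @param a,b transcript models.
#' @param strand_mode one of `"same"`, `"opposite"`, `"ignore"`.
#' @return overlap length in bases.
#' @export
exonic_overlap <- function(a, b, strand_mode = c("same", "opposite", "ignore")) {
  strand_mode <- match.arg(strand_mode)
  a <- .as_model(a); b <- .as_model(b)
  if (a$chrom != b$chrom) return(0)
  if (!.strand_compatible(a$strand, b$strand, strand_mode)) return(0)
  .interval_overlap_bases(a$exons$start, a$exons$end,
                          b$exons$start, b$exons$end)
}

#' Fraction of loci whose genomic span intersects at least one feature
#'
#' Summarizes overlap of transcript loci with a set of regions (for example
#' DNase I hypersensitive sites or histone-mark peaks from a BED file). A
#' locus counts once no matter how many features it touches. Unstranded
#' features match either strand.
#'
#' @param ann annotation_set (each transcript's span is a locus).
#' @param features data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   e.g. from [read_bed()].
#' @return fraction in `[0, 1]`.
#' @export
feature_overlap_summary <- function(ann, features) {
  stopifnot(inherits(ann, "annotation_set"))
  tx <- transcripts(ann)
  if (nrow(tx) == 0) stop("feature_overlap_summary: empty locus list")
  if (is.null(features) || nrow(features) == 0) return(0)
  hit <- vapply(seq_len(nrow(tx)), function(i) {
    f <- features[features$chrom == tx$chrom[i], , drop = FALSE]
    if (nrow(f) == 0) return(FALSE)
    any(pmin(f$end, tx$end[i]) > pmax(f$start, tx$start[i]))
  }, logical(1))
  mean(hit)
}

#' Intron chain of a transcript model
#'
#' The ordered intron coordinates (0-based half-open gaps between consecutive
#' exons), used to test transcript identity between catalogs: two multi-exon
#' transcripts are the same model iff their chromosomes, strands and intron
#' chains agree, regardless of terminal-exon extent.
#'
#' @param a transcript model.
#' @return character key encoding chrom, strand and the intron coordinates;
#'   `NA` for single-exon transcripts.
#' @export
intron_chain <- function(a) {
  a <- .as_model(a)
  n <- nrow(a$exons)
  if (n < 2) return(NA_character_)
  paste0(a$chrom, a$strand, ":",
         paste(a$exons$end[-n], a$exons$start[-1], sep = "-", collapse = ","))
}
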