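# Abundance matrices: FPKM computation, log transform, correlation, TSV I/O.

#' Construct an expression matrix with sample groups
#'
#' @param values numeric matrix, transcripts x samples, non-negative; rownames
#'   are transcript ids, colnames sample ids.
#' @param sample_groups named character vector mapping sample id to group
#'   label; must cover every column.
#' @param unit `"fragments"` (raw fragment counts) or `"FPKM"`.
#' @return list of class `expression_matrix` with elements `values`,
#'   `sample_groups`, `unit`.
#' @export
expression_matrix <- function(values, sample_groups,
                              unit = c("fragments", "FPKM")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must have transcript rownames and sample colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate transcript ids")
  if (any(values < 0)) stop("negative abundance values")
  missing_grp <- setdiff(colnames(values), names(sample_groups))
  if (length(missing_grp) > 0) {
    stop("samples without a group: ", paste(missing_grp, collapse = ", "))
  }
  structure(
    list(values = values,
         sample_groups = sample_groups[colnames(values)],
         unit = unit),
    class = "expression_matrix"
  )
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix [%s]: %d transcripts x %d samples (%s)\n",
              x$unit, nrow(x$values), ncol(x$values),
              paste(sprintf("%s=%d", names(table(x$sample_groups)),
                            table(x$sample_groups)), collapse = ", ")))
  invisible(x)
}

#' Convert fragment counts to FPKM
#'
#' FPKM (fragments per kilobase of exon per million mapped fragments)
#' normalizes each count to the transcript's spliced length and the sample's
#' total mapped fragments:
#' `FPKM[t, s] = fragments[t, s] * 1e9 / (length[t] * totals[s])`.
#'
#' @param fragments expression_matrix with `unit = "fragments"`.
#' @param lengths named numeric vector of spliced transcript lengths (bases),
#'   covering every row.
#' @param totals named numeric vector of total mapped fragments per sample,
#'   covering every column.
#' @return expression_matrix with `unit = "FPKM"`.
#' @export
compute_fpkm <- function(fragments, lengths, totals) {
  stopifnot(inherits(fragments, "expression_matrix"))
  if (fragments$unit != "fragments") stop("input is not in fragment counts")
  v <- fragments$values
  no_len <- setdiff(rownames(v), names(lengths))
  if (length(no_len) > 0) {
    stop("transcripts without a length: ", paste(no_len, collapse = ", "))
  }
  no_tot <- setdiff(colnames(v), names(totals))
  if (length(no_tot) > 0) {
    stop("samples without a fragment total: ", paste(no_tot, collapse = ", "))
  }
  len <- lengths[rownames(v)]
  tot <- totals[colnames(v)]
  if (any(len <= 0)) stop("non-positive transcript length")
  if (any(tot <= 0)) stop("non-positive fragment total")
  fpkm <- sweep(v * 1e9, 1, len, "/")
  fpkm <- sweep(fpkm, 2, tot, "/")
  expression_matrix(fpkm, fragments$sample_groups, unit = "FPKM")
}

#' Log-transform an abundance matrix
#'
#' @param m expression_matrix or numeric matrix.
#' @param pseudocount positive offset added before taking the log (default 1).
#' @param base logarithm base (default 2).
#' @return numeric matrix of `log(value + pseudocount, base)`.
#' @export
log_transform <- function(m, pseudocount = 1, base = 2) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  v <- if (inherits(m, "expression_matrix")) m$values else as.matrix(m)
  log(v + pseudocount, base = base)
}

#' Pearson product-moment correlation
#'
#' A strict wrapper around the sample correlation: vectors must have equal
#' length of at least 3 and nonzero variance; a zero-variance input raises an
#' error rather than returning `NA` silently, so degenerate transcripts have
#' to be handled (and counted) explicitly upstream.
#'
#' @param x,y numeric vectors.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (anyNA(x) || anyNA(y)) stop("missing values in input")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero-variance input")
  }
  stats::cor(x, y)
}

#' Read / write expression tables
#'
#' TSV layout: first column `transcript_id`, remaining columns one per sample
#' with sample ids in the header. Groups files are two-column TSVs
#' (`sample_id`, `group`).
#'
#' @param path TSV path.
#' @param groups named character vector (sample -> group), e.g. from
#'   [read_groups()].
#' @param unit abundance unit of the stored values.
#' @return `read_expression`: an expression_matrix.
#' @export
read_expression <- function(path, groups, unit = c("fragments", "FPKM")) {
  unit <- match.arg(unit)
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  expression_matrix(m, groups, unit = unit)
}

#' @rdname read_expression
#' @param m expression_matrix to write.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "expression_matrix"))
  tab <- data.frame(transcript_id = rownames(m$values), m$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @export
read_groups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(as.character(tab[[2]]), tab[[1]])
}

#' @rdname read_expression
#' @export
write_groups <- function(groups, path) {
  utils::write.table(
    data.frame(sample_id = names(groups), group = unname(groups)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}
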