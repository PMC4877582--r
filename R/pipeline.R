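# End-to-end orchestration: catalog -> stats -> three DE comparisons ->
# common-DE intersection -> clustering -> cis/trans targets -> neighbor
# correlation -> enrichment, with deterministic table outputs and a manifest.

#' Pipeline run configuration
#'
#' @param assembled_gtf,coding_gtf,lnc_ref_gtf input annotation paths.
#' @param counts_tsv transcripts x samples fragment-count table.
#' @param lengths_tsv two-column TSV `transcript_id`, `length`.
#' @param totals_tsv two-column TSV `sample_id`, `total` mapped fragments.
#' @param groups_tsv two-column TSV `sample_id`, `group`.
#' @param gmt_path gene-set definitions (GMT).
#' @param scores_tsv optional two-column TSV `transcript_id`, coding score.
#' @param out_dir output directory for stage tables.
#' @param groups length-3 character: the two disease-like group labels and
#'   the control label, in that order.
#' @param params [filter_params()] for the catalog stage.
#' @param alpha adjusted-p significance cutoff (default 0.05).
#' @param cis_window cis neighborhood in bases (default 100 kb).
#' @param trans_pcc_min trans coexpression threshold (default 0.95, strict).
#' @param seed seed for the random-pair null.
#' @return validated config list of class `run_config`.
#' @export
run_config <- function(assembled_gtf, coding_gtf, lnc_ref_gtf, counts_tsv,
                       lengths_tsv, totals_tsv, groups_tsv, gmt_path,
                       out_dir, scores_tsv = NULL,
                       groups = c("ECRSwNP", "nonECRSwNP", "CTRL"),
                       params = filter_params(), alpha = 0.05,
                       cis_window = 1e5, trans_pcc_min = 0.95, seed = 1) {
  paths <- list(assembled_gtf = assembled_gtf, coding_gtf = coding_gtf,
                lnc_ref_gtf = lnc_ref_gtf, counts_tsv = counts_tsv,
                lengths_tsv = lengths_tsv, totals_tsv = totals_tsv,
                groups_tsv = groups_tsv, gmt_path = gmt_path)
  if (!is.null(scores_tsv)) paths$scores_tsv <- scores_tsv
  missing <- names(paths)[!vapply(paths, file.exists, logical(1))]
  if (length(missing) > 0) {
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", missing, unlist(paths[missing])),
               collapse = ", "))
  }
  if (length(groups) != 3) stop("groups must name two diseases and a control")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (cis_window <= 0) stop("cis_window must be positive")
  if (trans_pcc_min <= 0 || trans_pcc_min >= 1) {
    stop("trans_pcc_min must lie in (0, 1)")
  }
  structure(c(paths, list(out_dir = out_dir, groups = groups, params = params,
                          alpha = alpha, cis_window = cis_window,
                          trans_pcc_min = trans_pcc_min,
                          seed = as.integer(seed))),
            class = "run_config")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  path
}

# minimal Newick serialization of an hclust tree (leaf names, no lengths)
.hclust_newick <- function(hc) {
  node <- function(i) {
    if (i < 0) return(hc$labels[-i])
    m <- hc$merge[i, ]
    paste0("(", node(m[1]), ",", node(m[2]), ")")
  }
  paste0(node(nrow(hc$merge)), ";")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: input loading and FPKM computation; lncRNA catalog
#' construction (filter, known/novel split, classification) with attrition
#' log; catalog statistics; three pairwise DE comparisons (disease 1 vs
#' control, disease 2 vs control, disease 1 vs disease 2); common-DE mRNA
#' intersection; sample clustering on the DE transcripts of each comparison
#' and on the common-DE set; cis and trans target prediction for the
#' catalog lncRNAs; neighbor-pair correlation analysis; hypergeometric
#' enrichment of the disease-1 DE mRNA loci and of the common-DE loci.
#' Every stage writes a TSV under `out_dir`; a manifest records row counts
#' and md5 checksums, and the overall `hash` is the md5 over the per-file
#' checksums, so reruns with identical inputs and config are bit-identical.
#' A stage failure aborts the run with the stage name in the error.
#'
#' @param cfg [run_config()].
#' @return list of class `run_manifest`: `files` (data.frame `file`,
#'   `n_rows`, `md5`), `counts` (named stage summary counts), `hash`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  outputs <- character()
  emit <- function(x, file) {
    path <- .write_tsv(x, file.path(cfg$out_dir, file))
    outputs <<- c(outputs, path)
    x
  }

  inputs <- stage("load_inputs", {
    groups_map <- read_groups(cfg$groups_tsv)
    lengths_tab <- utils::read.delim(cfg$lengths_tsv, stringsAsFactors = FALSE)
    totals_tab <- utils::read.delim(cfg$totals_tsv, stringsAsFactors = FALSE)
    scores <- NULL
    if (!is.null(cfg$scores_tsv)) {
      st <- utils::read.delim(cfg$scores_tsv, stringsAsFactors = FALSE)
      scores <- stats::setNames(as.numeric(st[[2]]), st[[1]])
    }
    list(assembled = read_gtf(cfg$assembled_gtf),
         coding_ref = read_gtf(cfg$coding_gtf),
         lnc_ref = read_gtf(cfg$lnc_ref_gtf),
         counts = read_expression(cfg$counts_tsv, groups_map,
                                  unit = "fragments"),
         lengths = stats::setNames(as.numeric(lengths_tab[[2]]),
                                   lengths_tab[[1]]),
         totals = stats::setNames(as.numeric(totals_tab[[2]]),
                                  totals_tab[[1]]),
         gene_sets = read_gmt(cfg$gmt_path),
         scores = scores)
  })

  fpkm <- stage("fpkm", compute_fpkm(inputs$counts, inputs$lengths,
                                     inputs$totals))

  cat_res <- stage("catalog", build_catalog(
    inputs$assembled, inputs$coding_ref, inputs$lnc_ref, fpkm,
    params = cfg$params, scores = inputs$scores))
  emit(cat_res$catalog, "catalog.tsv")
  emit(cat_res$attrition, "attrition.tsv")
  stats_res <- stage("catalog_stats", catalog_stats(cat_res$catalog, fpkm))

  g <- cfg$groups
  comparisons <- list(c(g[1], g[3]), c(g[2], g[3]), c(g[1], g[2]))
  de <- list()
  for (cmp in comparisons) {
    nm <- paste0(cmp[1], "_vs_", cmp[2])
    de[[nm]] <- stage(paste0("de_", nm),
                      call_de(fpkm, cmp[1], cmp[2], alpha = cfg$alpha))
    emit(de[[nm]], paste0("de_", nm, ".tsv"))
  }

  mrna_ids <- unique(inputs$coding_ref$transcript_id)
  sig_mrna <- lapply(de, function(d) {
    d$transcript_id[d$significant & d$transcript_id %in% mrna_ids]
  })
  common <- stage("common_de",
                  intersect_common_de(sig_mrna[[1]], sig_mrna[[2]]))
  emit(data.frame(transcript_id = common, stringsAsFactors = FALSE),
       "common_de_mrna.tsv")

  cluster_sets <- c(stats::setNames(
    lapply(de, function(d) d$transcript_id[d$significant]), names(de)),
    list(de_union = unique(unlist(lapply(de, function(d) {
           d$transcript_id[d$significant]
         }))),
         common_de = common))
  assignments <- list()
  for (nm in names(cluster_sets)) {
    ids <- cluster_sets[[nm]]
    if (length(ids) < 2) next
    hc <- stage(paste0("cluster_", nm), hierarchical_cluster(fpkm, ids))
    writeLines(.hclust_newick(hc), file.path(cfg$out_dir,
                                             paste0("cluster_", nm, ".nwk")))
    outputs <- c(outputs, file.path(cfg$out_dir, paste0("cluster_", nm, ".nwk")))
    for (k in 2:3) {
      cut <- stats::cutree(hc, k = k)
      assignments[[paste(nm, k)]] <- data.frame(
        tree = nm, k = k, sample_id = names(cut), cluster = unname(cut),
        stringsAsFactors = FALSE)
    }
  }
  if (length(assignments) > 0) {
    emit(do.call(rbind, assignments), "cluster_assignments.tsv")
  }

  lnc_ann <- annotation_set(as.data.frame(
    inputs$assembled[inputs$assembled$transcript_id %in%
                       cat_res$catalog$transcript_id, , drop = FALSE]))
  cis <- stage("cis_targets", cis_targets(lnc_ann, inputs$coding_ref,
                                          expr = fpkm,
                                          window = cfg$cis_window))
  emit(cis, "cis_targets.tsv")
  trans <- stage("trans_targets", trans_targets(
    lnc_ann, inputs$coding_ref, fpkm, pcc_min = cfg$trans_pcc_min,
    window = cfg$cis_window))
  emit(trans, "trans_targets.tsv")

  ncor <- stage("neighbor_correlation", neighbor_correlation_analysis(
    lnc_ann, inputs$coding_ref, fpkm, window = cfg$cis_window,
    seed = cfg$seed))
  emit(data.frame(
    class = names(ncor$classes),
    n = vapply(ncor$classes, `[[`, 0, "n"),
    mean_pcc = vapply(ncor$classes, `[[`, 0, "mean_pcc"),
    n_excluded = vapply(ncor$classes, `[[`, 0L, "n_excluded"),
    stringsAsFactors = FALSE), "neighbor_classes.tsv")
  emit(ncor$tests, "neighbor_tests.tsv")

  coding_tx <- transcripts(inputs$coding_ref)
  locus_of <- stats::setNames(coding_tx$gene_id, coding_tx$transcript_id)
  background <- unique(unname(locus_of[
    coding_tx$transcript_id %in% rownames(fpkm$values)]))
  enrich_sets <- list(de_1 = unique(unname(locus_of[sig_mrna[[1]]])),
                      common = unique(unname(locus_of[common])))
  for (nm in names(enrich_sets)) {
    res <- stage(paste0("enrichment_", nm), hypergeometric_enrichment(
      enrich_sets[[nm]], background, inputs$gene_sets, alpha = cfg$alpha))
    emit(res, paste0("enrichment_", nm, ".tsv"))
  }

  files <- data.frame(
    file = basename(outputs),
    n_rows = vapply(outputs, function(f) length(readLines(f)) - 1L,
                    integer(1), USE.NAMES = FALSE),
    md5 = unname(tools::md5sum(outputs)),
    stringsAsFactors = FALSE
  )
  files <- files[order(files$file), , drop = FALSE]
  rownames(files) <- NULL
  counts <- c(
    n_catalog = nrow(cat_res$catalog),
    n_catalog_loci = stats_res$n_loci,
    stats::setNames(vapply(de, function(d) sum(d$significant), 0L),
                    paste0("n_de_", names(de))),
    n_common_de_mrna = length(common),
    n_cis_pairs = nrow(cis),
    n_trans_pairs = nrow(trans)
  )
  manifest <- structure(
    list(files = files, counts = counts,
         hash = unname(tools::md5sum(
           .write_tsv(files["md5"], file.path(cfg$out_dir, ".md5list"))))),
    class = "run_manifest")
  unlink(file.path(cfg$out_dir, ".md5list"))
  .write_tsv(files, file.path(cfg$out_dir, "manifest.tsv"))
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("pipeline run:", nrow(x$files), "output tables, hash", x$hash, "\n")
  print(x$counts)
  invisible(x)
}
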