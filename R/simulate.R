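# Seeded simulator for the whole workflow: a toy genome with interleaved
# protein-coding and noncoding loci, grouped expression with planted
# differential expression and planted lncRNA-mRNA correlation pairs, and
# gene sets with known enriched terms. Every generated feature is recorded
# in a ground-truth table so analyses can be scored against the truth.

#' Simulation configuration
#'
#' Defaults emulate a three-group RNA-seq study design (two disease groups
#' and a control, three samples each) at toy-genome scale: a few dozen
#' multi-exon protein-coding loci per chromosome separated by intergenic
#' gaps mostly under 100 kb, lncRNAs planted to realize each positional
#' class and novelty status, and a set of deliberately defective transcripts
#' that each trip one filter of the catalog pipeline.
#'
#' @param seed integer; fixes all randomness of annotation, expression and
#'   gene-set generation (distinct derived streams per stage).
#' @param n_chromosomes number of chromosomes.
#' @param n_coding_loci total protein-coding loci, spread over chromosomes.
#' @param second_isoform_prob probability that a coding locus gets a second,
#'   exon-skipping isoform (drives isoforms-per-locus above 1).
#' @param n_lnc named integer vector of planted lncRNA counts per
#'   novelty x positional class: `novel_lincRNA`, `novel_intronic`,
#'   `novel_antisense`, `known_lincRNA`, `known_intronic`, `known_antisense`.
#' @param n_ref_only reference-only decoy lncRNAs (present in the lncRNA
#'   reference annotation but never assembled).
#' @param n_noise named integer vector of defective transcripts per failure
#'   mode: `short` (< 200 nt), `single_exon`, `low_expression`,
#'   `coding_overlap` (same-strand exonic overlap with a coding gene),
#'   `high_coding_score`.
#' @param groups group labels, first two are the disease-like groups, last
#'   the control.
#' @param n_samples_per_group samples per group (default 3).
#' @param de_fraction fraction of eligible transcripts differentially
#'   expressed specifically in each disease group (vs control).
#' @param de_shared_fraction fraction differentially expressed, same
#'   direction, in both disease groups (the common-DE set).
#' @param effect_log2 log2 expression shift of a DE transcript (default 4,
#'   i.e. 16-fold — 8 standard deviations of the within-group noise; disease
#'   vs control comparisons of this kind headline changes of 16-fold and
#'   beyond, and a 3-vs-3 design only has power for large shifts).
#' @param mean_log2_fpkm named baseline means of log2 FPKM for `mrna` and
#'   `lncrna`; the lncRNA baseline is lower, as in real transcriptomes.
#' @param sd_baseline between-transcript SD of the baseline (log2).
#' @param sd_noise within-group, per-sample noise SD (log2).
#' @param neighbor_rho target Pearson correlation planted between each
#'   lncRNA and its nearest protein-coding neighbor within the window
#'   (weak positive by default, emulating cis-regulatory coupling).
#' @param planted_pair_rho target correlation of the single strongly coupled
#'   lncRNA-mRNA cis pair (the "headline" pair every run plants).
#' @param pair_profile_sd across-sample SD (log2) of coupled profiles.
#' @param fragment_total expected total mapped fragments per sample
#'   (jittered +/- 20% per sample).
#' @param cis_window neighborhood window in bases used when planting pairs.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              n_chromosomes = 3,
                              n_coding_loci = 48,
                              second_isoform_prob = 0.5,
                              n_lnc = c(novel_lincRNA = 24,
                                        novel_intronic = 4,
                                        novel_antisense = 3,
                                        known_lincRNA = 5,
                                        known_intronic = 1,
                                        known_antisense = 2),
                              n_ref_only = 5,
                              n_noise = c(short = 3, single_exon = 3,
                                          low_expression = 3,
                                          coding_overlap = 3,
                                          high_coding_score = 3),
                              groups = c("ECRSwNP", "nonECRSwNP", "CTRL"),
                              n_samples_per_group = 3,
                              de_fraction = 0.10,
                              de_shared_fraction = 0.05,
                              effect_log2 = 4,
                              mean_log2_fpkm = c(mrna = 5, lncrna = 2.5),
                              sd_baseline = 1.5,
                              sd_noise = 0.5,
                              neighbor_rho = 0.1,
                              planted_pair_rho = 0.9,
                              pair_profile_sd = 1.5,
                              fragment_total = 1e7,
                              cis_window = 1e5) {
  lnc_names <- c("novel_lincRNA", "novel_intronic", "novel_antisense",
                 "known_lincRNA", "known_intronic", "known_antisense")
  noise_names <- c("short", "single_exon", "low_expression",
                   "coding_overlap", "high_coding_score")
  full <- function(x, nms) {
    out <- stats::setNames(rep(0L, length(nms)), nms)
    out[names(x)] <- x
    out
  }
  n_lnc <- full(n_lnc, lnc_names)
  n_noise <- full(n_noise, noise_names)
  if (any(n_lnc < 0) || any(n_noise < 0) || n_coding_loci < 0) {
    stop("counts must be non-negative")
  }
  if (length(groups) != 3) stop("exactly three groups are expected")
  if (n_samples_per_group < 2) stop("need >= 2 samples per group")
  if (abs(planted_pair_rho) > 1 || abs(neighbor_rho) > 1) {
    stop("correlations must lie in [-1, 1]")
  }
  structure(list(
    seed = as.integer(seed), n_chromosomes = n_chromosomes,
    n_coding_loci = n_coding_loci, second_isoform_prob = second_isoform_prob,
    n_lnc = n_lnc, n_ref_only = n_ref_only, n_noise = n_noise,
    groups = groups, n_samples_per_group = n_samples_per_group,
    de_fraction = de_fraction, de_shared_fraction = de_shared_fraction,
    effect_log2 = effect_log2, mean_log2_fpkm = mean_log2_fpkm,
    sd_baseline = sd_baseline, sd_noise = sd_noise,
    neighbor_rho = neighbor_rho, planted_pair_rho = planted_pair_rho,
    pair_profile_sd = pair_profile_sd, fragment_total = fragment_total,
    cis_window = cis_window
  ), class = "simulation_config")
}

# --- annotation ------------------------------------------------------------

# one coding gene starting at `pos`: exon table rows for 1 or 2 isoforms
.sim_coding_gene <- function(chrom, pos, gene_id, tx_prefix, second_isoform) {
  strand <- sample(c("+", "-"), 1)
  n_ex <- sample(4:8, 1)
  exon_len <- round(stats::runif(n_ex, 100, 300))
  intron_len <- round(stats::runif(max(n_ex - 1, 0), 800, 4000))
  if (n_ex >= 3) intron_len[2] <- round(stats::runif(1, 4000, 8000))
  starts <- pos + c(0, cumsum(exon_len[-n_ex] + intron_len))
  ends <- starts + exon_len
  mk <- function(idx, tid) {
    data.frame(transcript_id = tid, gene_id = gene_id, chrom = chrom,
               start = starts[idx], end = ends[idx], strand = strand,
               biotype = "protein_coding", stringsAsFactors = FALSE)
  }
  rows <- mk(seq_len(n_ex), paste0(tx_prefix, ".1"))
  if (second_isoform && n_ex >= 4) {
    rows <- rbind(rows, mk(setdiff(seq_len(n_ex), 2), paste0(tx_prefix, ".2")))
  }
  list(rows = rows, end = max(ends), strand = strand,
       exon_starts = starts, exon_ends = ends)
}

# spliced lncRNA exons centered in [gstart, gend]; n_exons 1..3
.sim_spliced_exons <- function(gstart, gend, n_exons) {
  exon_len <- round(stats::runif(n_exons, 250, 600))
  intron_len <- if (n_exons > 1) round(stats::runif(n_exons - 1, 500, 1500)) else numeric()
  span <- sum(exon_len) + sum(intron_len)
  mid <- (gstart + gend) / 2
  s0 <- round(mid - span / 2)
  starts <- s0 + c(0, cumsum(exon_len[-n_exons] + intron_len))
  data.frame(start = starts, end = starts + exon_len)
}

#' Simulate the toy genome annotation
#'
#' Lays out protein-coding loci with intergenic gaps along each chromosome,
#' then plants lncRNAs to realize each configured class constructively:
#' lincRNAs centered in intergenic gaps, intronic lncRNAs inside a long
#' intron of a host gene, antisense lncRNAs overlapping a host exon on the
#' opposite strand. "Known" lncRNAs are copied into the reference lncRNA
#' annotation (identical intron chain with jittered terminal exons for
#' multi-exon models; a >= 50%-overlapping shifted exon for single-exon
#' models). Defective transcripts are planted to trip each catalog filter.
#' After generation the planted classes and novelty are verified with
#' [classify_lncrna()] and [split_known_novel()]; an inconsistency is an
#' error, so infeasible geometry cannot pass silently.
#'
#' @param cfg [simulation_config()].
#' @return list with annotation_sets `assembled`, `coding_ref`, `lnc_ref`
#'   and a `truth` data.frame (`transcript_id`, `locus_id`, `type`,
#'   `true_class`, `true_novelty`, `noise_mode`).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(cfg$seed, {
    coding_rows <- list()
    gaps <- list()          # intergenic slots usable for planting
    hosts <- list()         # coding transcripts usable as intronic/antisense hosts
    per_chrom <- table(factor(rep(seq_len(cfg$n_chromosomes),
                                  length.out = cfg$n_coding_loci),
                              levels = seq_len(cfg$n_chromosomes)))
    gid <- 0
    for (ci in seq_len(cfg$n_chromosomes)) {
      chrom <- paste0("chr", ci)
      pos <- 1e4
      prev_end <- 0
      n_here <- per_chrom[ci]
      for (li in seq_len(n_here)) {
        gap <- if (stats::runif(1) < 0.8) stats::runif(1, 5e3, 8e4)
               else stats::runif(1, 1.5e5, 3e5)
        gstart <- prev_end + 500
        gend <- prev_end + gap - 500
        if (gend - gstart > 5e3) {
          gaps[[length(gaps) + 1]] <- data.frame(chrom = chrom, start = gstart,
                                                 end = gend)
        }
        pos <- prev_end + gap
        gid <- gid + 1
        g <- .sim_coding_gene(chrom, round(pos),
                              sprintf("G%03d", gid), sprintf("TC%03d", gid),
                              stats::runif(1) < cfg$second_isoform_prob)
        coding_rows[[gid]] <- g$rows
        hosts[[gid]] <- list(transcript_id = g$rows$transcript_id[1],
                             chrom = chrom, strand = g$strand,
                             exon_starts = g$exon_starts,
                             exon_ends = g$exon_ends)
        prev_end <- g$end
      }
      gaps[[length(gaps) + 1]] <- data.frame(
        chrom = chrom, start = prev_end + 500,
        end = prev_end + 500 + stats::runif(1, 3e4, 8e4))
    }
    coding <- do.call(rbind, coding_rows)

    n_gaps_needed <- cfg$n_lnc[["novel_lincRNA"]] + cfg$n_lnc[["known_lincRNA"]] +
      cfg$n_ref_only + cfg$n_noise[["short"]] + cfg$n_noise[["single_exon"]] +
      cfg$n_noise[["low_expression"]] + cfg$n_noise[["high_coding_score"]]
    if (length(gaps) < n_gaps_needed) {
      stop(sprintf(paste0("infeasible geometry: %d intergenic slots needed ",
                          "but only %d generated; increase n_coding_loci ",
                          "or reduce planted counts"),
                   n_gaps_needed, length(gaps)))
    }
    n_hosts_needed <- cfg$n_lnc[["novel_intronic"]] + cfg$n_lnc[["known_intronic"]] +
      cfg$n_lnc[["novel_antisense"]] + cfg$n_lnc[["known_antisense"]] +
      cfg$n_noise[["coding_overlap"]]
    eligible_hosts <- Filter(function(h) length(h$exon_starts) >= 3, hosts)
    if (length(eligible_hosts) < n_hosts_needed) {
      stop("infeasible geometry: not enough multi-intron host genes")
    }
    gap_order <- sample(length(gaps))
    host_order <- sample(length(eligible_hosts))
    gap_i <- 0; host_i <- 0
    next_gap <- function() { gap_i <<- gap_i + 1; gaps[[gap_order[gap_i]]] }
    next_host <- function() { host_i <<- host_i + 1; eligible_hosts[[host_order[host_i]]] }

    lnc_rows <- list()
    ref_rows <- list()
    truth_rows <- list()
    lnc_id <- 0; ref_id <- 0
    add_truth <- function(tid, gidv, type, cls, nov, noise_mode = NA_character_) {
      truth_rows[[length(truth_rows) + 1]] <<- data.frame(
        transcript_id = tid, locus_id = gidv, type = type,
        true_class = cls, true_novelty = nov, noise_mode = noise_mode,
        stringsAsFactors = FALSE)
    }
    new_lnc_ids <- function() {
      lnc_id <<- lnc_id + 1
      c(sprintf("TCONS_%05d", lnc_id), sprintf("XLOC_%06d", lnc_id))
    }
    add_ref_copy <- function(exons, chrom, strand, single_exon_shift = FALSE) {
      ref_id <<- ref_id + 1
      ex <- exons
      if (single_exon_shift) {
        len <- ex$end - ex$start
        ex$start <- ex$start + round(0.25 * len)
        ex$end <- ex$end + round(0.25 * len)
      } else if (nrow(ex) >= 2) {
        ex$start[1] <- max(0, ex$start[1] - 30)
        ex$end[nrow(ex)] <- ex$end[nrow(ex)] + 30
      }
      ref_rows[[length(ref_rows) + 1]] <<- data.frame(
        transcript_id = sprintf("LNCREF_%03d", ref_id),
        gene_id = sprintf("LNCG_%03d", ref_id), chrom = chrom,
        start = ex$start, end = ex$end, strand = strand,
        biotype = "lncRNA_known", stringsAsFactors = FALSE)
    }

    plant_linc <- function(novelty, single_exon) {
      g <- next_gap()
      n_ex <- if (single_exon) 1 else sample(2:3, 1)
      ex <- .sim_spliced_exons(g$start, g$end, n_ex)
      ids <- new_lnc_ids()
      strand <- sample(c("+", "-"), 1)
      lnc_rows[[length(lnc_rows) + 1]] <<- data.frame(
        transcript_id = ids[1], gene_id = ids[2], chrom = g$chrom,
        start = ex$start, end = ex$end, strand = strand,
        biotype = "lncRNA_candidate", stringsAsFactors = FALSE)
      if (novelty == "known") {
        add_ref_copy(ex, g$chrom, strand, single_exon_shift = single_exon)
      }
      add_truth(ids[1], ids[2], "lncRNA", "lincRNA", novelty)
    }
    plant_intronic <- function(novelty) {
      h <- next_host()
      introns_s <- h$exon_ends[-length(h$exon_ends)]
      introns_e <- h$exon_starts[-1]
      k <- which.max(introns_e - introns_s)
      single <- novelty == "known"
      if (single) {
        ex <- data.frame(start = introns_s[k] + 150, end = introns_s[k] + 450)
      } else {
        s1 <- introns_s[k] + 150
        ex <- data.frame(start = c(s1, s1 + 450), end = c(s1 + 250, s1 + 700))
      }
      stopifnot(all(ex$end <= introns_e[k]))
      ids <- new_lnc_ids()
      strand <- sample(c("+", "-"), 1)
      lnc_rows[[length(lnc_rows) + 1]] <<- data.frame(
        transcript_id = ids[1], gene_id = ids[2], chrom = h$chrom,
        start = ex$start, end = ex$end, strand = strand,
        biotype = "lncRNA_candidate", stringsAsFactors = FALSE)
      if (novelty == "known") {
        add_ref_copy(ex, h$chrom, strand, single_exon_shift = single)
      }
      add_truth(ids[1], ids[2], "lncRNA", "intronic", novelty)
    }
    plant_antisense <- function(novelty) {
      h <- next_host()
      a_strand <- if (h$strand == "+") "-" else "+"
      # exon 2 of the host is always flanked by introns >= 800 bp
      hs <- h$exon_starts[2]
      ex <- data.frame(start = c(hs - 550, hs - 100),
                       end = c(hs - 400, hs + 100))
      ids <- new_lnc_ids()
      lnc_rows[[length(lnc_rows) + 1]] <<- data.frame(
        transcript_id = ids[1], gene_id = ids[2], chrom = h$chrom,
        start = ex$start, end = ex$end, strand = a_strand,
        biotype = "lncRNA_candidate", stringsAsFactors = FALSE)
      if (novelty == "known") add_ref_copy(ex, h$chrom, a_strand)
      add_truth(ids[1], ids[2], "lncRNA", "antisense", novelty)
    }
    plant_noise <- function(mode) {
      ids <- new_lnc_ids()
      if (mode %in% c("short", "single_exon", "low_expression",
                      "high_coding_score")) {
        g <- next_gap()
        ex <- switch(mode,
          short = {
            mid <- round((g$start + g$end) / 2)
            data.frame(start = mid, end = mid + 150)
          },
          single_exon = {
            mid <- round((g$start + g$end) / 2)
            data.frame(start = mid, end = mid + 420)
          },
          .sim_spliced_exons(g$start, g$end, 2)
        )
        chrom <- g$chrom; strand <- sample(c("+", "-"), 1)
      } else {  # coding_overlap: same-strand overlap with a host exon
        h <- next_host()
        hs <- h$exon_starts[2]
        ex <- data.frame(start = c(hs - 550, hs - 100),
                         end = c(hs - 400, hs + 100))
        chrom <- h$chrom; strand <- h$strand
      }
      lnc_rows[[length(lnc_rows) + 1]] <<- data.frame(
        transcript_id = ids[1], gene_id = ids[2], chrom = chrom,
        start = ex$start, end = ex$end, strand = strand,
        biotype = "other", stringsAsFactors = FALSE)
      add_truth(ids[1], ids[2], "noise", NA_character_, NA_character_,
                noise_mode = mode)
    }

    for (i in seq_len(cfg$n_lnc[["novel_lincRNA"]])) plant_linc("novel", FALSE)
    kl <- cfg$n_lnc[["known_lincRNA"]]
    if (kl > 0) {
      n_single <- min(kl, max(1, floor(kl * 0.4)))
      for (i in seq_len(kl - n_single)) plant_linc("known", FALSE)
      for (i in seq_len(n_single)) plant_linc("known", TRUE)
    }
    for (i in seq_len(cfg$n_lnc[["novel_intronic"]])) plant_intronic("novel")
    for (i in seq_len(cfg$n_lnc[["known_intronic"]])) plant_intronic("known")
    for (i in seq_len(cfg$n_lnc[["novel_antisense"]])) plant_antisense("novel")
    for (i in seq_len(cfg$n_lnc[["known_antisense"]])) plant_antisense("known")
    for (mode in names(cfg$n_noise)) {
      for (i in seq_len(cfg$n_noise[[mode]])) plant_noise(mode)
    }
    for (i in seq_len(cfg$n_ref_only)) {
      g <- next_gap()
      ex <- .sim_spliced_exons(g$start, g$end, sample(1:2, 1))
      ref_id <- ref_id + 1
      ref_rows[[length(ref_rows) + 1]] <- data.frame(
        transcript_id = sprintf("LNCREF_%03d", ref_id),
        gene_id = sprintf("LNCG_%03d", ref_id), chrom = g$chrom,
        start = ex$start, end = ex$end, strand = sample(c("+", "-"), 1),
        biotype = "lncRNA_known", stringsAsFactors = FALSE)
    }

    empty_ann <- annotation_set(data.frame(
      transcript_id = character(), gene_id = character(), chrom = character(),
      start = numeric(), end = numeric()))
    coding_ref <- if (is.null(coding)) empty_ann else annotation_set(coding)
    lnc_part <- if (length(lnc_rows) > 0) do.call(rbind, lnc_rows) else NULL
    assembled <- annotation_set(rbind(coding, lnc_part))
    lnc_ref <- if (length(ref_rows) > 0) {
      annotation_set(do.call(rbind, ref_rows))
    } else empty_ann
    truth_coding <- data.frame(
      transcript_id = transcripts(coding_ref)$transcript_id,
      locus_id = transcripts(coding_ref)$gene_id,
      type = "mRNA", true_class = NA_character_,
      true_novelty = NA_character_, noise_mode = NA_character_,
      stringsAsFactors = FALSE)
    truth <- rbind(truth_coding,
                   if (length(truth_rows) > 0) do.call(rbind, truth_rows))
    rownames(truth) <- NULL

    # constructive verification: planted geometry must classify as intended
    planted <- truth[truth$type == "lncRNA", , drop = FALSE]
    if (nrow(planted) > 0) {
      got_class <- vapply(planted$transcript_id, function(id) {
        classify_lncrna(transcript_model(assembled, id), coding_ref)
      }, character(1), USE.NAMES = FALSE)
      got_nov <- unname(split_known_novel(assembled, lnc_ref,
                                          ids = planted$transcript_id))
      bad <- got_class != planted$true_class | got_nov != planted$true_novelty
      if (any(bad)) {
        stop("simulated geometry is inconsistent with its planted labels: ",
             paste(planted$transcript_id[bad], collapse = ", "))
      }
    }
    list(assembled = assembled, coding_ref = coding_ref, lnc_ref = lnc_ref,
         truth = truth)
  })
}

# --- expression ------------------------------------------------------------

#' Simulate grouped expression with planted effects
#'
#' Per-transcript baselines are drawn log-normally (lncRNA baseline lower
#' than mRNA), differential expression is planted as a log2 shift in the
#' designated disease group(s), coupled lncRNA-mRNA pairs share a latent
#' across-sample profile realizing the target Pearson correlation, and
#' expected FPKM is converted to fragment counts through the inverse FPKM
#' formula with Poisson sampling. Coupled transcripts are kept out of the DE
#' sets so planted correlations are not confounded by group shifts.
#'
#' @param cfg [simulation_config()].
#' @param annotation result of [simulate_annotation()] (same `cfg`).
#' @return list: `fragments` (expression_matrix of counts), `lengths`,
#'   `totals`, `fpkm_true` (noise-free FPKM matrix), `de_truth` (data.frame
#'   `transcript_id`, direction per disease comparison: -1/0/1), and
#'   `pair_truth` (data.frame `lncrna_id`, `mrna_locus`, `rho`).
#' @export
simulate_expression <- function(cfg, annotation) {
  stopifnot(inherits(cfg, "simulation_config"))
  .with_seed(cfg$seed + 1000003L, {
    tx <- transcripts(annotation$assembled)
    truth <- annotation$truth[match(tx$transcript_id,
                                    annotation$truth$transcript_id), ]
    n_tx <- nrow(tx)
    grp <- rep(cfg$groups, each = cfg$n_samples_per_group)
    samples <- paste(grp, sequence(rep(cfg$n_samples_per_group, 3)), sep = "_")
    n_s <- length(samples)
    disease <- cfg$groups[1:2]; ctrl <- cfg$groups[3]

    is_lnc <- truth$type == "lncRNA"
    base <- stats::rnorm(n_tx,
                         ifelse(is_lnc, cfg$mean_log2_fpkm[["lncrna"]],
                                cfg$mean_log2_fpkm[["mrna"]]),
                         cfg$sd_baseline)
    # planted transcripts must be reliably expressed so the catalog filter
    # tests expression, not baseline luck; noise low_expression sinks instead
    base[is_lnc] <- pmax(base[is_lnc], 1)
    base[truth$type == "mRNA"] <- pmax(base[truth$type == "mRNA"], 1)
    base[!is.na(truth$noise_mode) & truth$noise_mode == "low_expression"] <- -5

    # --- coupled pairs -----------------------------------------------------
    pair_truth <- data.frame(lncrna_id = character(), mrna_locus = character(),
                             rho = numeric(), stringsAsFactors = FALSE)
    coupled <- rep(FALSE, n_tx)
    strong_pair <- rep(FALSE, n_tx)   # members of the headline pair: no DE
    latent <- matrix(0, n_tx, n_s)    # replacement across-sample profiles
    spans <- tx
    lnc_idx <- which(is_lnc & truth$true_class == "lincRNA")
    loci <- locus_spans(annotation$coding_ref)
    locus_of <- transcripts(annotation$coding_ref)
    used_locus <- character()
    couple <- function(l_i, locus, rho, sdev) {
      z <- stats::rnorm(n_s)
      members <- c(tx$transcript_id[l_i],
                   locus_of$transcript_id[locus_of$gene_id == locus])
      for (m in members) {
        mi <- match(m, tx$transcript_id)
        prof <- sqrt(abs(rho)) * z + sqrt(1 - abs(rho)) * stats::rnorm(n_s)
        # the lncRNA always loads positively; partners flip when rho < 0
        if (mi == l_i || rho >= 0) latent[mi, ] <<- sdev * prof
        else latent[mi, ] <<- -sdev * prof
      }
      coupled[match(members, tx$transcript_id)] <<- TRUE
      used_locus <<- c(used_locus, locus)
      pair_truth <<- rbind(pair_truth, data.frame(
        lncrna_id = tx$transcript_id[l_i], mrna_locus = locus, rho = rho,
        stringsAsFactors = FALSE))
    }
    nearest_free_locus <- function(i) {
      gap <- .span_gap(spans$chrom[i], spans$start[i], spans$end[i],
                       loci$chrom, loci$start, loci$end)
      ok <- which(gap <= cfg$cis_window & !(loci$locus_id %in% used_locus))
      if (length(ok) == 0) return(NA_character_)
      loci$locus_id[ok[which.min(gap[ok])]]
    }
    if (length(lnc_idx) > 0 && abs(cfg$planted_pair_rho) > 0) {
      for (i in lnc_idx) {
        locus <- nearest_free_locus(i)
        if (!is.na(locus)) {
          partners <- match(locus_of$transcript_id[locus_of$gene_id == locus],
                            tx$transcript_id)
          base[c(i, partners)] <- 6
          couple(i, locus, cfg$planted_pair_rho, cfg$pair_profile_sd)
          strong_pair[c(i, partners)] <- TRUE
          break
        }
      }
    }
    # weak neighbor coupling at noise scale: correlation is scale-free, and
    # keeping the across-sample spread at sd_noise preserves DE power for
    # coupled transcripts that also receive a group shift
    if (cfg$neighbor_rho != 0) {
      for (i in setdiff(which(is_lnc), which(coupled))) {
        locus <- nearest_free_locus(i)
        if (!is.na(locus)) couple(i, locus, cfg$neighbor_rho, cfg$sd_noise)
      }
    }

    # --- differential expression ------------------------------------------
    # only the headline pair is shielded from DE, so its planted correlation
    # is not confounded by group shifts
    eligible <- which(!strong_pair & truth$type %in% c("mRNA", "lncRNA"))
    n_shared <- floor(cfg$de_shared_fraction * length(eligible))
    n_spec <- floor(cfg$de_fraction * length(eligible))
    pool <- sample(eligible)
    shared <- pool[seq_len(n_shared)]
    pool <- setdiff(pool, shared)
    spec1 <- pool[seq_len(min(n_spec, length(pool)))]
    pool <- setdiff(pool, spec1)
    spec2 <- pool[seq_len(min(n_spec, length(pool)))]
    dir1 <- dir2 <- rep(0L, n_tx)
    shared_dir <- sample(c(-1L, 1L), length(shared), replace = TRUE)
    dir1[shared] <- shared_dir; dir2[shared] <- shared_dir
    dir1[spec1] <- sample(c(-1L, 1L), length(spec1), replace = TRUE)
    dir2[spec2] <- sample(c(-1L, 1L), length(spec2), replace = TRUE)

    shift <- matrix(0, n_tx, n_s)
    shift[, grp == disease[1]] <- dir1 * cfg$effect_log2
    shift[, grp == disease[2]] <- dir2 * cfg$effect_log2

    eps <- matrix(stats::rnorm(n_tx * n_s, 0, cfg$sd_noise), n_tx, n_s)
    profile <- ifelse(matrix(coupled, n_tx, n_s), latent, eps)
    log2_fpkm <- base + shift + profile
    fpkm_true <- 2^log2_fpkm
    dimnames(fpkm_true) <- list(tx$transcript_id, samples)

    lengths <- stats::setNames(tx$length, tx$transcript_id)
    totals <- stats::setNames(
      round(cfg$fragment_total * stats::runif(n_s, 0.8, 1.2)), samples)
    lambda <- sweep(fpkm_true, 1, lengths, "*")
    lambda <- sweep(lambda, 2, totals, "*") / 1e9
    counts <- matrix(stats::rpois(length(lambda), lambda), n_tx, n_s,
                     dimnames = dimnames(fpkm_true))
    groups_map <- stats::setNames(grp, samples)
    de_truth <- data.frame(transcript_id = tx$transcript_id,
                           de_dir_1 = dir1, de_dir_2 = dir2,
                           stringsAsFactors = FALSE)
    names(de_truth)[2:3] <- paste0("de_dir_", disease)
    list(fragments = expression_matrix(counts, groups_map, unit = "fragments"),
         lengths = lengths, totals = totals, fpkm_true = fpkm_true,
         de_truth = de_truth, pair_truth = pair_truth)
  })
}

# --- gene sets -------------------------------------------------------------

#' Simulate gene sets with known enriched terms
#'
#' Terms are random draws from the background gene universe; a designated
#' number of terms over-sample true positive genes (e.g. the truly DE
#' loci), so enrichment analysis has known positives.
#'
#' @param background character vector, the gene universe (locus ids).
#' @param positives character vector of "interesting" genes terms may
#'   over-sample (subset of background).
#' @param n_terms number of terms (default 25).
#' @param n_enriched how many terms over-sample positives (default 3).
#' @param positive_fraction fraction of an enriched term drawn from
#'   `positives` (default 0.7).
#' @param term_size_range inclusive range of term sizes.
#' @param seed integer seed.
#' @return named list of gene sets with attribute `enriched_terms` naming
#'   the planted positives.
#' @export
simulate_gene_sets <- function(background, positives, n_terms = 25,
                               n_enriched = 3, positive_fraction = 0.7,
                               term_size_range = c(8, 25), seed = 1) {
  background <- unique(as.character(background))
  positives <- intersect(unique(as.character(positives)), background)
  if (max(term_size_range) > length(background)) {
    stop("term sizes exceed background size")
  }
  .with_seed(seed + 2000003L, {
    sets <- list()
    for (i in seq_len(n_terms)) {
      size <- sample(term_size_range[1]:term_size_range[2], 1)
      nm <- sprintf("TERM_%03d", i)
      if (i <= n_enriched && length(positives) > 0) {
        n_pos <- min(round(positive_fraction * size), length(positives))
        sets[[nm]] <- unique(c(sample(positives, n_pos),
                               sample(background, size - n_pos)))
      } else {
        sets[[nm]] <- sample(background, size)
      }
    }
    attr(sets, "enriched_terms") <- names(sets)[seq_len(min(n_enriched,
                                                            n_terms))]
    sets
  })
}

#' Run the whole simulator
#'
#' @param cfg [simulation_config()].
#' @return list bundling the annotation, expression and gene-set outputs:
#'   `assembled`, `coding_ref`, `lnc_ref`, `truth`, `fragments`, `lengths`,
#'   `totals`, `fpkm_true`, `de_truth`, `pair_truth`, `gene_sets`, `scores`.
#' @export
simulate_all <- function(cfg = simulation_config()) {
  ann <- simulate_annotation(cfg)
  ex <- simulate_expression(cfg, ann)
  # coding-potential scores: planted lncRNAs score clearly noncoding, mRNAs
  # and the high_coding_score decoys clearly coding
  truth <- ann$truth
  scores <- .with_seed(cfg$seed + 3000003L, {
    s <- stats::setNames(rep(NA_real_, nrow(truth)), truth$transcript_id)
    s[truth$type == "lncRNA"] <- stats::runif(sum(truth$type == "lncRNA"),
                                              -20, -1)
    s[truth$type == "mRNA"] <- stats::runif(sum(truth$type == "mRNA"), 50, 500)
    noisy <- !is.na(truth$noise_mode)
    s[truth$noise_mode %in% "high_coding_score"] <- stats::runif(
      sum(truth$noise_mode %in% "high_coding_score"), 50, 200)
    s[noisy & !truth$noise_mode %in% "high_coding_score"] <- stats::runif(
      sum(noisy & !truth$noise_mode %in% "high_coding_score"), -20, -1)
    s
  })
  de_loci <- unique(truth$locus_id[match(
    ex$de_truth$transcript_id[ex$de_truth[[2]] != 0], truth$transcript_id)])
  mrna_loci <- unique(truth$locus_id[truth$type == "mRNA"])
  sets <- simulate_gene_sets(mrna_loci, intersect(de_loci, mrna_loci),
                             seed = cfg$seed)
  c(ann, ex, list(gene_sets = sets, scores = scores, config = cfg))
}

#' Write a simulation bundle to disk in the pipeline's input formats
#'
#' Emits `assembled.gtf`, `coding_ref.gtf`, `lnc_ref.gtf`, `counts.tsv`,
#' `lengths.tsv`, `totals.tsv`, `groups.tsv`, `scores.tsv`,
#' `gene_sets.gmt` and `ground_truth.tsv` under `dir`.
#'
#' @param sim result of [simulate_all()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_gtf(sim$assembled, p("assembled.gtf"))
  write_gtf(sim$coding_ref, p("coding_ref.gtf"))
  write_gtf(sim$lnc_ref, p("lnc_ref.gtf"))
  write_expression(sim$fragments, p("counts.tsv"))
  utils::write.table(
    data.frame(transcript_id = names(sim$lengths), length = sim$lengths),
    p("lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(sim$totals), total = sim$totals),
    p("totals.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_groups(sim$fragments$sample_groups, p("groups.tsv"))
  sc <- sim$scores[!is.na(sim$scores)]
  utils::write.table(
    data.frame(transcript_id = names(sc), score = sc),
    p("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$gene_sets, p("gene_sets.gmt"))
  utils::write.table(sim$truth, p("ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(dir)
}
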