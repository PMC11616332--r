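# End-to-end orchestration: FASTQ -> filtered/merged reads -> alignment ->
# per-read outcome records -> sample summary, plus table writers. Unique
# sequences are aligned and classified once and the records expanded back,
# which makes error-free runs (few unique templates) very fast.

# batch path: align + normalise + classify unique sequences
.classify_seqs <- function(seqs, locus, guides, match = 1, mismatch = -2,
                           gap_open = -6, gap_extend = -0.5,
                           min_identity = 0.6, free_ref_ends = FALSE) {
  useq <- unique(seqs)
  idx <- match(seqs, useq)
  raw <- cpp_align_batch(useq, locus$amplicon, match, mismatch,
                         gap_open, gap_extend, free_ref_ends)
  n <- length(useq)
  amp <- locus$amplicon
  rejected <- logical(n)
  cols <- list(category = character(n), cag_units = integer(n),
               net_delta = integer(n), frameshift = logical(n),
               flank_changed = logical(n), whole_tract_excised = logical(n),
               mh_seq = character(n), mh_len = integer(n),
               mh_tract_internal = logical(n), staggered_ins = logical(n),
               templated_ins = logical(n),
               templated_donor_start = rep(NA_integer_, n),
               templated_donor_end = rep(NA_integer_, n),
               identity = numeric(n))
  for (i in seq_len(n)) {
    a <- raw[[i]]
    if (is.null(a) || a$identity < min_identity) {
      rejected[i] <- TRUE
      next
    }
    ip <- a$ins_pos
    is_ <- a$ins_seq
    ds <- a$del_start
    de <- a$del_end
    for (k in seq_along(ds)) {
      se <- .leftshift_del(amp, ds[k], de[k])
      ds[k] <- se[1L]
      de[k] <- se[2L]
    }
    for (k in seq_along(ip)) {
      pq <- .leftshift_ins(amp, ip[k], is_[k])
      ip[k] <- pq$pos
      is_[k] <- pq$seq
    }
    core <- .classify_core(useq[i], ip, is_, ds, de, locus, guides)
    for (nm in names(core)) cols[[nm]][i] <- core[[nm]]
    cols$identity[i] <- a$identity
  }
  rec_u <- as.data.frame(cols, stringsAsFactors = FALSE)
  list(records_unique = rec_u, rejected_unique = rejected, map = idx)
}

#' Classify an editing sample end to end
#'
#' Runs the full read-processing and classification pipeline: quality
#' filter (mean Phred >= \code{min_mean_q}), pair merging (paired input),
#' global alignment to the amplicon with identity-based rejection, indel
#' left-normalisation, per-read outcome classification and sample
#' summarisation. Unmerged and rejected reads are excluded from the
#' denominators but counted in the QC block.
#'
#' @param fastq path to merged-read FASTQ, or a \code{read_set}, or the
#'   result of \code{\link{simulate_reads}}.
#' @param locus a \code{\link{repeat_locus}}.
#' @param guides list of \code{cas9_guide}s used for signature annotation.
#' @param fastq2 optional mate FASTQ for paired input.
#' @param control optional unedited-control input (same forms as
#'   \code{fastq}) used for stutter correction.
#' @param min_mean_q,min_overlap,max_overlap_mismatch,min_identity stage
#'   parameters (see the stage functions).
#' @param out_dir optional output directory: writes per-read records TSV,
#'   summary JSON, CAG length histogram TSV, cluster TSV and a QC JSON.
#' @return list with \code{records} (per-read data.frame),
#'   \code{summary} (an \code{outcome_summary}), \code{qc} and
#'   \code{clusters}.
#' @export
pipeline_classify <- function(fastq, locus, guides = list(), fastq2 = NULL,
                              control = NULL, min_mean_q = 5,
                              min_overlap = 20, max_overlap_mismatch = 0.1,
                              min_identity = 0.6, out_dir = NULL) {
  qc <- list(params = list(min_mean_q = min_mean_q,
                           min_overlap = min_overlap,
                           max_overlap_mismatch = max_overlap_mismatch,
                           min_identity = min_identity))
  if (is.list(fastq) && !is.null(fastq$layout)) {
    sim <- fastq
    if (sim$layout == "merged") {
      r1 <- sim$reads
      r2 <- NULL
    } else {
      r1 <- sim$r1
      r2 <- sim$r2
    }
  } else {
    r1 <- if (inherits(fastq, "read_set")) fastq else read_fastq(fastq)
    r2 <- if (is.null(fastq2)) NULL
          else if (inherits(fastq2, "read_set")) fastq2 else read_fastq(fastq2)
  }
  if (length(r1$seq) == 0L) stop("empty FASTQ")
  qc$n_input <- length(r1$seq)

  if (is.null(r2)) {
    kept <- quality_filter(r1, min_mean_q)
    qc$n_quality_discarded <- attr(kept, "n_discarded")
    merged <- kept
    qc$n_unmerged <- 0L
  } else {
    mq1 <- vapply(r1$qual, mean, numeric(1L))
    mq2 <- vapply(r2$qual, mean, numeric(1L))
    ok <- mq1 >= min_mean_q & mq2 >= min_mean_q
    qc$n_quality_discarded <- sum(!ok)
    mg <- merge_pairs(.subset_reads(r1, ok), .subset_reads(r2, ok),
                      min_overlap, max_overlap_mismatch)
    merged <- mg$merged
    qc$n_unmerged <- mg$n_unmerged
  }
  if (length(merged$seq) == 0L) stop("no reads left after filtering/merging")
  qc$n_merged <- length(merged$seq)

  cl <- .classify_seqs(merged$seq, locus, guides,
                       min_identity = min_identity)
  rej <- cl$rejected_unique[cl$map]
  qc$n_rejected <- sum(rej)
  qc$n_classified <- sum(!rej)
  if (qc$n_classified == 0L) stop("no reads aligned to the amplicon")
  records <- cl$records_unique[cl$map[!rej], , drop = FALSE]
  records <- cbind(data.frame(read_id = merged$id[!rej],
                              stringsAsFactors = FALSE), records)
  rownames(records) <- NULL

  clusters <- cluster_reads(merged$seq[!rej])

  control_records <- NULL
  if (!is.null(control)) {
    ctl <- pipeline_classify(control, locus, guides,
                             min_mean_q = min_mean_q,
                             min_overlap = min_overlap,
                             max_overlap_mismatch = max_overlap_mismatch,
                             min_identity = min_identity)
    control_records <- ctl$records
  }
  summary <- summarize_outcomes(records, locus, control_records, clusters)

  out <- list(records = records, summary = summary, qc = qc,
              clusters = clusters)
  if (!is.null(out_dir)) write_outcome_bundle(out, out_dir)
  out
}

#' Write the classification output bundle
#'
#' Per-read records TSV, summary JSON, CAG-length histogram TSV (cag_units,
#' frameshift, fraction), cluster TSV and QC JSON.
#'
#' @param result a \code{\link{pipeline_classify}} result.
#' @param out_dir output directory (created if needed).
#' @export
write_outcome_bundle <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$records, file.path(out_dir, "records.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  s <- result$summary
  js <- list(n_reads = s$n_reads,
             category_fractions = as.list(s$category_fractions),
             flank_fraction = s$flank_fraction,
             whole_tract_fraction = s$whole_tract_fraction,
             staggered_ins_fraction = s$staggered_ins_fraction,
             top_variants = s$top_variants)
  if (!is.null(s$stutter_corrected))
    js$stutter_corrected_fractions <-
      as.list(s$stutter_corrected$category_fractions)
  jsonlite::write_json(js, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write.table(s$length_histogram, file.path(out_dir, "length_histogram.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(result$clusters, file.path(out_dir, "clusters.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$qc, file.path(out_dir, "qc.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Simulate a sample and write its FASTQ + truth bundle
#'
#' Thin wrapper over \code{\link{simulate_reads}} for scripted use.
#'
#' @inheritParams simulate_reads
#' @export
pipeline_simulate <- function(locus, guides, spec, cfg, out_dir) {
  simulate_reads(locus, guides, spec, cfg, out_dir = out_dir)
}

#' Resection analysis from a Cq CSV
#'
#' @param csv path to a CSV with columns site, distance_bp, timepoint_h,
#'   condition, replicate, cq (see \code{\link{resection_table}}).
#' @param baseline see \code{\link{resection_table}}.
#' @param out optional output TSV path.
#' @export
pipeline_resection <- function(csv, baseline = 10, out = NULL) {
  df <- read.csv(csv)
  tab <- resection_table(df, baseline)
  if (!is.null(out))
    write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

#' ChIP/DRIP enrichment analysis from a qPCR CSV
#'
#' @param csv path to a CSV (see \code{\link{enrichment_table}}).
#' @param out optional output TSV path.
#' @export
pipeline_enrichment <- function(csv, out = NULL) {
  tab <- enrichment_table(read.csv(csv))
  if (!is.null(out))
    write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  tab
}

#' LFQ differential abundance from TSV + group JSON
#'
#' @param tsv,groups_json see \code{\link{read_lfq}}.
#' @param out optional output TSV path (volcano-ready table).
#' @param ... passed to \code{\link{lfq_workflow}}.
#' @export
pipeline_lfq <- function(tsv, groups_json, out = NULL, ...) {
  x <- read_lfq(tsv, groups_json)
  res <- lfq_workflow(x$intensities, x$groups, ...)
  if (!is.null(out))
    write.table(res, out, sep = "\t", quote = FALSE, row.names = FALSE)
  res
}
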