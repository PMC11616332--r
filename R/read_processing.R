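# FASTQ -> one aligned sequence per template: quality filter, pair merging,
# fitting alignment against the amplicon, indel normalisation, clustering.

#' Read a FASTQ file into a read set
#'
#' @param path FASTQ file (plain or gzip).
#' @return list with \code{id} (character), \code{seq} (character) and
#'   \code{qual} (list of integer Phred vectors), class \code{read_set}.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      # benign constructor notice about dropped metadata columns
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  qual <- as(Biostrings::quality(x), "IntegerList")
  structure(list(id = names(x), seq = unname(as.character(x)),
                 qual = unname(as.list(qual))),
            class = "read_set")
}

#' Write a read set to FASTQ
#' @param reads a \code{read_set}.
#' @param path output path (".gz" suffix compresses).
#' @export
write_fastq <- function(reads, path) {
  q <- Biostrings::PhredQuality(methods::as(reads$qual, "IntegerList"))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(setNames(reads$seq, reads$id)), q)
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

.subset_reads <- function(reads, keep) {
  structure(list(id = reads$id[keep], seq = reads$seq[keep],
                 qual = reads$qual[keep]),
            class = "read_set")
}

#' Mean-quality read filter
#'
#' Keeps reads whose mean Phred score is at least \code{min_mean_q}
#' (boundary inclusive). The count of discarded reads is attached as the
#' \code{"n_discarded"} attribute.
#'
#' @param reads a \code{read_set}.
#' @param min_mean_q minimum mean Phred quality (default 5).
#' @export
quality_filter <- function(reads, min_mean_q = 5) {
  stopifnot(min_mean_q >= 0)
  mq <- vapply(reads$qual, mean, numeric(1L))
  keep <- mq >= min_mean_q
  out <- .subset_reads(reads, keep)
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Merge read pairs by best ungapped overlap
#'
#' The reverse complement of each R2 is slid over its R1; the offset
#' maximising matching bases wins. Disagreeing overlap bases resolve to the
#' higher-quality base (tie: R1); merged quality is the per-base maximum.
#' Pairs whose best overlap is shorter than \code{min_overlap} or whose
#' overlap mismatch rate exceeds \code{max_overlap_mismatch} are reported
#' unmerged, not errors.
#'
#' @param r1,r2 \code{read_set}s of equal length (r2 = reverse-strand mate).
#' @param min_overlap minimum acceptable overlap (nt).
#' @param max_overlap_mismatch maximum mismatch fraction in the overlap.
#' @return list with \code{merged} (a \code{read_set}) and
#'   \code{n_unmerged}.
#' @export
merge_pairs <- function(r1, r2, min_overlap = 20,
                        max_overlap_mismatch = 0.1) {
  stopifnot(length(r1$seq) == length(r2$seq))
  r2rc <- .revcomp(r2$seq)
  q2rc <- lapply(r2$qual, rev)
  res <- cpp_merge_pairs(r1$seq, r2rc, r1$qual, q2rc,
                         as.integer(min_overlap), max_overlap_mismatch)
  ok <- res$merged == 1L
  merged <- structure(list(id = r1$id[ok], seq = res$seq[ok],
                           qual = res$qual[ok]),
                      class = "read_set")
  list(merged = merged, n_unmerged = sum(!ok))
}

#' Merge one read pair
#'
#' Single-pair convenience wrapper around \code{\link{merge_pairs}};
#' returns the merged record or the string \code{"UNMERGED"}.
#'
#' @param r1,r2 lists with \code{seq} and \code{qual} for one read each.
#' @inheritParams merge_pairs
#' @export
merge_pair <- function(r1, r2, min_overlap = 20,
                       max_overlap_mismatch = 0.1) {
  rs1 <- structure(list(id = "r", seq = r1$seq, qual = list(r1$qual)),
                   class = "read_set")
  rs2 <- structure(list(id = "r", seq = r2$seq, qual = list(r2$qual)),
                   class = "read_set")
  out <- merge_pairs(rs1, rs2, min_overlap, max_overlap_mismatch)
  if (out$n_unmerged == 1L) return("UNMERGED")
  list(seq = out$merged$seq[[1L]], qual = out$merged$qual[[1L]])
}

#' Align reads to the amplicon
#'
#' Affine-gap alignment in which the read is aligned end to end and
#' unaligned reference flanks are free. Reads whose identity falls below
#' \code{min_identity} are rejected; identity is the fraction of read
#' bases that match the reference (deleted reference segments involve no
#' read base), so a legitimate whole-tract excision scores ~1 while random
#' DNA lands near 0.25-0.4 and is rejected. Among
#' equal-score paths the traceback prefers mismatch over insertion over
#' deletion; indels are then left-normalised by
#' \code{\link{normalize_indels}}.
#'
#' @param seqs character vector of read sequences (A/C/G/T/N).
#' @param locus a \code{\link{repeat_locus}}.
#' @param match,mismatch,gap_open,gap_extend scoring parameters; a gap of
#'   length L costs \code{gap_open + L * gap_extend}.
#' @param min_identity rejection threshold on identity.
#' @param free_ref_ends if TRUE, unaligned reference flanks are free
#'   (fitting alignment, for reads covering only part of the product);
#'   default FALSE, i.e. fully global, which is correct for merged reads
#'   spanning the complete PCR product and keeps a long terminal deletion
#'   from being mis-scored as a cheap read-end insertion.
#' @param normalize left-normalise indels (default TRUE).
#' @return list of alignments; rejected reads yield \code{NULL}. Each
#'   alignment is a list with \code{seq}, \code{score}, \code{identity},
#'   \code{ref_span}, \code{ins} (data.frame pos/seq) and \code{del}
#'   (data.frame start/end), coordinates 0-based.
#' @export
align_to_amplicon <- function(seqs, locus, match = 1, mismatch = -2,
                              gap_open = -6, gap_extend = -0.5,
                              min_identity = 0.6, free_ref_ends = FALSE,
                              normalize = TRUE) {
  stopifnot(inherits(locus, "repeat_locus"))
  if (length(seqs) == 0L) return(list())
  if (any(!nzchar(seqs))) stop("invalid sequence: empty read")
  if (any(grepl("[^ACGTN]", seqs))) stop("invalid sequence")
  raw <- cpp_align_batch(seqs, locus$amplicon, match, mismatch,
                         gap_open, gap_extend, free_ref_ends)
  lapply(seq_along(raw), function(i) {
    a <- raw[[i]]
    if (is.null(a) || a$identity < min_identity) return(NULL)
    aln <- list(seq = seqs[[i]], score = a$score, identity = a$identity,
                n_match = a$n_match, n_col = a$n_col,
                ref_span = c(a$ref_start, a$ref_end),
                ins = data.frame(pos = a$ins_pos, seq = a$ins_seq,
                                 stringsAsFactors = FALSE),
                del = data.frame(start = a$del_start, end = a$del_end))
    if (normalize) normalize_indels(aln, locus) else aln
  })
}

# Left-shift one deletion to its leftmost equivalent placement.
.leftshift_del <- function(amp, s, e) {
  while (s > 0L && substr(amp, s, s) == substr(amp, e, e)) {
    s <- s - 1L
    e <- e - 1L
  }
  c(s, e)
}

# Left-shift one insertion (position + inserted word, rotating the word).
.leftshift_ins <- function(amp, p, q) {
  L <- nchar(q)
  while (p > 0L && substr(amp, p, p) == substr(q, L, L)) {
    q <- paste0(substr(q, L, L), substr(q, 1L, L - 1L))
    p <- p - 1L
  }
  list(pos = p, seq = q)
}

#' Left-normalise the indels of an alignment
#'
#' Shifts every insertion and deletion to its leftmost equivalent placement
#' (the placement yielding the same edited sequence), as in variant
#' normalisation. Idempotent.
#'
#' @param aln an alignment from \code{\link{align_to_amplicon}}.
#' @param locus the \code{\link{repeat_locus}} aligned against.
#' @export
normalize_indels <- function(aln, locus) {
  if (is.null(aln)) return(NULL)
  amp <- locus$amplicon
  if (nrow(aln$del)) {
    for (i in seq_len(nrow(aln$del))) {
      se <- .leftshift_del(amp, aln$del$start[i], aln$del$end[i])
      aln$del$start[i] <- se[1L]
      aln$del$end[i] <- se[2L]
    }
  }
  if (nrow(aln$ins)) {
    for (i in seq_len(nrow(aln$ins))) {
      pq <- .leftshift_ins(amp, aln$ins$pos[i], aln$ins$seq[i])
      aln$ins$pos[i] <- pq$pos
      aln$ins$seq[i] <- pq$seq
    }
  }
  aln
}

#' Greedy same-length clustering at 95% identity
#'
#' Reads are collapsed to unique sequences, ordered by abundance, and each
#' joins the first existing cluster whose representative has identical
#' length and at least \code{identity} ungapped identity; otherwise it
#' founds a new cluster.
#'
#' @param seqs character vector of read sequences.
#' @param identity minimum identity to join a cluster (default 0.95).
#' @return data.frame with \code{representative}, \code{size} and
#'   \code{n_unique}, ordered by size.
#' @export
cluster_reads <- function(seqs, identity = 0.95) {
  if (length(seqs) == 0L)
    return(data.frame(representative = character(0), size = integer(0),
                      n_unique = integer(0)))
  tab <- sort(table(seqs), decreasing = TRUE)
  uniq <- names(tab)
  counts <- as.integer(tab)
  lens <- nchar(uniq)
  rep_idx <- integer(0)
  size <- integer(0)
  n_unique <- integer(0)
  assign <- integer(length(uniq))
  for (i in seq_along(uniq)) {
    cand <- rep_idx[lens[rep_idx] == lens[i]]
    hit <- 0L
    if (length(cand)) {
      d <- cpp_hamming_one_many(uniq[i], uniq[cand])
      ok <- which(d <= (1 - identity) * lens[i])
      if (length(ok)) hit <- cand[ok[1L]]
    }
    if (hit > 0L) {
      k <- match(hit, rep_idx)
      size[k] <- size[k] + counts[i]
      n_unique[k] <- n_unique[k] + 1L
    } else {
      rep_idx <- c(rep_idx, i)
      size <- c(size, counts[i])
      n_unique <- c(n_unique, 1L)
    }
  }
  out <- data.frame(representative = uniq[rep_idx], size = size,
                    n_unique = n_unique, stringsAsFactors = FALSE)
  out[order(-out$size), , drop = FALSE]
}
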