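# Per-read CAG-tract calling, six-category outcome classification, repair
# signature annotation, and sample-level summaries.
#
# Categories: UNEDITED (no indels), INS_CAG / DEL_CAG (in-frame tract
# gain/loss), INS / DEL / INDEL (frameshift), plus the internal label
# OTHER_INFRAME for the rare in-frame read whose indels leave the tract
# length unchanged (a pure-flank in-frame indel). OTHER_INFRAME is reported
# alongside the six headline categories but never folded into them
# silently.

CATEGORY_LEVELS <- c("UNEDITED", "INS_CAG", "DEL_CAG", "INS", "DEL",
                     "INDEL", "OTHER_INFRAME")

#' Longest exact tandem repeat run
#'
#' Finds the longest uninterrupted run of exact motif copies (any phase) in
#' a sequence; ties break leftmost. Interruptions (e.g. a CAA triplet in a
#' CAG tract) terminate a run.
#'
#' @param seq DNA string.
#' @param motif repeat unit (default "CAG").
#' @return list with \code{units} and the 0-based half-open \code{interval}
#'   on \code{seq} (\code{c(0, 0)} when no run exists).
#' @examples
#' count_repeats(paste0("TT", strrep("CAG", 5), "AA"))$units  # 5
#' @export
count_repeats <- function(seq, motif = "CAG") {
  stopifnot(nzchar(motif))
  m <- gregexpr(paste0("(?:", motif, ")+"), seq)[[1L]]
  if (m[1L] < 0L) return(list(units = 0L, interval = c(0L, 0L)))
  lens <- attr(m, "match.length")
  i <- which.max(lens)
  start0 <- m[i] - 1L
  list(units = lens[i] %/% nchar(motif),
       interval = c(start0, start0 + lens[i]))
}

# Vectorised units-only variant used on whole read sets.
.count_units_vec <- function(seqs, motif = "CAG") {
  hits <- gregexpr(paste0("(?:", motif, ")+"), seqs)
  vapply(hits, function(m) {
    if (m[1L] < 0L) 0L else max(attr(m, "match.length")) %/% nchar(motif)
  }, integer(1L))
}

# Equivalent-placement range of a deletion [s, e): number of left (l) and
# right (r) single-base shifts that yield the same edited sequence.
.del_shift_range <- function(amp, s, e) {
  n <- nchar(amp)
  l <- 0L
  while (s - l - 1L >= 0L &&
         substr(amp, s - l, s - l) == substr(amp, e - l, e - l)) l <- l + 1L
  r <- 0L
  while (e + r < n &&
         substr(amp, e + r + 1L, e + r + 1L) ==
         substr(amp, s + r + 1L, s + r + 1L)) r <- r + 1L
  c(left = l, right = r)
}

# Equivalent-placement range of an insertion at p of word q.
.ins_shift_range <- function(amp, p, q) {
  n <- nchar(amp)
  L <- nchar(q)
  w <- q
  pp <- p
  l <- 0L
  while (pp > 0L && substr(amp, pp, pp) == substr(w, L, L)) {
    w <- paste0(substr(w, L, L), substr(w, 1L, L - 1L))
    pp <- pp - 1L
    l <- l + 1L
  }
  w <- q
  pp <- p
  r <- 0L
  while (pp < n && substr(amp, pp + 1L, pp + 1L) == substr(w, 1L, 1L)) {
    w <- paste0(substr(w, 2L, L), substr(w, 1L, 1L))
    pp <- pp + 1L
    r <- r + 1L
  }
  c(left = l, right = r)
}

# TRUE if a deletion admits an equivalent placement fully inside the tract.
.del_tract_only <- function(amp, s, e, start, end) {
  sh <- .del_shift_range(amp, s, e)
  max(e - end, -sh[["right"]]) <= min(s - start, sh[["left"]])
}

# TRUE if an insertion admits an equivalent position within the tract
# (boundary positions count as tract-internal).
.ins_tract_only <- function(amp, p, q, start, end) {
  sh <- .ins_shift_range(amp, p, q)
  (p - sh[["left"]]) <= end && (p + sh[["right"]]) >= start
}

#' Microhomology at a deletion junction
#'
#' The largest k (up to \code{max_len}) for which the k bases flanking both
#' junction ends repeat: \code{amp[s-k:s] == amp[e-k:e]} (left side) or
#' \code{amp[s:s+k] == amp[e:e+k]} (right side); the maximum over both
#' sides is reported, with the repeated word.
#'
#' @param del_start,del_end 0-based half-open deletion interval.
#' @param amplicon reference sequence.
#' @param max_len cap on reported length (default 10).
#' @return list with \code{seq} and \code{len} (0 and "" when the junction
#'   is unique).
#' @export
detect_microhomology <- function(del_start, del_end, amplicon,
                                 max_len = 10) {
  sh <- .del_shift_range(amplicon, del_start, del_end)
  l <- min(sh[["left"]], max_len)
  r <- min(sh[["right"]], max_len)
  if (max(l, r) == 0L) return(list(seq = "", len = 0L))
  if (l >= r) {
    list(seq = substr(amplicon, del_start - l + 1L, del_start), len = l)
  } else {
    list(seq = substr(amplicon, del_start + 1L, del_start + r), len = r)
  }
}

#' Templated (locally duplicated) insertion detection
#'
#' Searches for an exact copy of the inserted sequence (or its longest
#' prefix/suffix of at least \code{min_len} nt) within \code{window} nt of
#' the insertion point on the forward strand — the signature of polymerase
#' theta gap filling from the nearby flank.
#'
#' @param ins_pos 0-based insertion point.
#' @param ins_seq inserted bases.
#' @param amplicon reference sequence.
#' @param window search window around the insertion point (nt).
#' @param min_len minimum matched length (default 4).
#' @return list with 0-based half-open \code{donor} interval and the
#'   matched \code{seq}, or \code{NULL} when no donor is found or the
#'   insertion is shorter than \code{min_len}.
#' @export
detect_templated_insertion <- function(ins_pos, ins_seq, amplicon,
                                       window = 25, min_len = 4) {
  L <- nchar(ins_seq)
  if (L < min_len) return(NULL)
  lo <- max(0L, ins_pos - window)
  hi <- min(nchar(amplicon), ins_pos + window)
  neighborhood <- substr(amplicon, lo + 1L, hi)
  # full insert first, then shrink from either end
  for (k in L:min_len) {
    for (word in unique(c(substr(ins_seq, 1L, k),
                          substr(ins_seq, L - k + 1L, L)))) {
      hits <- gregexpr(word, neighborhood, fixed = TRUE)[[1L]]
      if (hits[1L] > 0L) {
        # nearest hit to the insertion point
        starts <- lo + hits - 1L
        d <- abs(starts + k / 2 - ins_pos)
        s0 <- starts[which.min(d)]
        return(list(donor = c(s0, s0 + k), seq = word))
      }
    }
  }
  NULL
}

#' Staggered-cut single-base insertion detection
#'
#' TRUE iff the insertion is a single base, lies within 1 nt of the guide's
#' blunt cut, and duplicates the staggered-cut donor base (the 4th
#' nucleotide upstream of the PAM on the non-target strand).
#'
#' @param ins_pos 0-based insertion point (after normalisation).
#' @param ins_seq inserted bases.
#' @param guide a \code{cas9_guide}.
#' @param amplicon reference sequence.
#' @export
detect_staggered_ins <- function(ins_pos, ins_seq, guide, amplicon) {
  nchar(ins_seq) == 1L &&
    abs(ins_pos - guide$blunt_cut) <= 1L &&
    ins_seq == substr(amplicon, guide$staggered_donor + 1L,
                      guide$staggered_donor + 1L)
}

# Classification core on plain event vectors; returns a flat list of
# scalars (shared by classify_read and the batch pipeline path).
#
# The repeat count is called from the alignment: the annotated tract
# length plus the net indel change intersecting the tract (insertions
# counted when they admit a tract-internal equivalent placement). This is
# robust to isolated sequencing substitutions, which interrupt an exact
# motif run but do not change the tract length — the same tolerance a
# score-based tandem-repeat finder has. On error-free reads it coincides
# with the exact-run search of count_repeats.
.classify_core <- function(seq, ins_pos, ins_seq, del_start, del_end,
                           locus, guides = NULL) {
  amp <- locus$amplicon
  rs <- locus$repeat_start
  re <- locus$repeat_end
  mlen <- nchar(locus$motif)
  net <- sum(nchar(ins_seq)) - sum(del_end - del_start)
  fs <- net %% 3L != 0L
  tract_delta <- 0L
  for (i in seq_along(del_start)) {
    ov <- min(del_end[i], re) - max(del_start[i], rs)
    if (ov > 0L) tract_delta <- tract_delta - ov
  }
  for (i in seq_along(ins_pos)) {
    if (.ins_tract_only(amp, ins_pos[i], ins_seq[i], rs, re))
      tract_delta <- tract_delta + nchar(ins_seq[i])
  }
  cag <- max(0L, (re - rs + tract_delta) %/% mlen)
  has_ins <- length(ins_pos) > 0L
  has_del <- length(del_start) > 0L
  category <- if (!has_ins && !has_del) "UNEDITED"
  else if (fs) {
    if (has_ins && has_del) "INDEL" else if (has_ins) "INS" else "DEL"
  } else if (cag > locus$expected_units) "INS_CAG"
  else if (cag < locus$expected_units) "DEL_CAG"
  else "OTHER_INFRAME"

  tract_only <- TRUE
  if (has_del)
    for (i in seq_along(del_start)) {
      if (!.del_tract_only(amp, del_start[i], del_end[i], rs, re)) {
        tract_only <- FALSE
        break
      }
    }
  if (tract_only && has_ins)
    for (i in seq_along(ins_pos)) {
      if (!.ins_tract_only(amp, ins_pos[i], ins_seq[i], rs, re)) {
        tract_only <- FALSE
        break
      }
    }
  flank_changed <- (has_ins || has_del) && !tract_only
  whole_tract <- has_del && any(del_start <= rs & del_end >= re)

  mh_seq <- ""
  mh_len <- 0L
  mh_tract_internal <- FALSE
  if (has_del) {
    for (i in seq_along(del_start)) {
      mh <- detect_microhomology(del_start[i], del_end[i], amp)
      if (mh$len > mh_len) {
        mh_len <- mh$len
        mh_seq <- mh$seq
        mh_tract_internal <- del_start[i] >= rs && del_end[i] <= re
      }
    }
  }

  stag <- FALSE
  if (has_ins && length(guides)) {
    for (g in guides) {
      for (i in seq_along(ins_pos)) {
        if (detect_staggered_ins(ins_pos[i], ins_seq[i], g, amp)) stag <- TRUE
      }
    }
  }
  tmpl <- FALSE
  tmpl_donor <- c(NA_integer_, NA_integer_)
  if (has_ins) {
    for (i in seq_along(ins_pos)) {
      hit <- detect_templated_insertion(ins_pos[i], ins_seq[i], amp)
      if (!is.null(hit)) {
        tmpl <- TRUE
        tmpl_donor <- hit$donor
        break
      }
    }
  }
  list(category = category, cag_units = cag, net_delta = net,
       frameshift = fs, flank_changed = flank_changed,
       whole_tract_excised = whole_tract, mh_seq = mh_seq,
       mh_len = mh_len, mh_tract_internal = mh_tract_internal,
       staggered_ins = stag, templated_ins = tmpl,
       templated_donor_start = tmpl_donor[1L],
       templated_donor_end = tmpl_donor[2L])
}

#' Classify one aligned read
#'
#' Assigns the editing-outcome category from the normalised alignment:
#' frameshift follows the net indel length (mod 3), the repeat count comes
#' from \code{\link{count_repeats}} on the read itself, and flank change
#' uses the indel's full equivalent-placement range (an indel that can be
#' placed entirely inside the tract counts as tract-only, so left-alignment
#' does not overcall flank changes at the tract's left edge).
#'
#' @param aln normalised alignment (from \code{\link{align_to_amplicon}}).
#' @param locus a \code{\link{repeat_locus}}.
#' @param guides optional list of \code{cas9_guide}s for staggered-cut
#'   annotation.
#' @param read_id read identifier carried into the record.
#' @return one-row data.frame (an outcome record).
#' @export
classify_read <- function(aln, locus, guides = NULL, read_id = NA_character_) {
  if (is.null(aln)) stop("rejected alignment is not classifiable")
  core <- .classify_core(aln$seq, aln$ins$pos, aln$ins$seq,
                         aln$del$start, aln$del$end, locus, guides)
  cbind(data.frame(read_id = read_id, stringsAsFactors = FALSE),
        as.data.frame(core, stringsAsFactors = FALSE))
}

#' Empirical stutter distribution from an unedited control
#'
#' PCR slippage over a long repeat yields exact whole-unit length changes
#' even without editing. This estimates the distribution of unit change
#' among in-frame, tract-only reads of an unedited control sample.
#'
#' @param control_records outcome records (data.frame) of the control.
#' @param expected_units tract length of the unedited allele.
#' @return named numeric vector of probabilities over the unit change
#'   (names are signed integers), with attribute \code{p0}.
#' @export
estimate_stutter <- function(control_records, expected_units) {
  if (is.null(control_records) || nrow(control_records) == 0L)
    stop("empty control")
  ok <- !control_records$frameshift & !control_records$flank_changed
  if (!any(ok)) stop("no usable control reads")
  delta <- control_records$cag_units[ok] - expected_units
  tab <- table(delta)
  p <- as.numeric(tab) / sum(tab)
  names(p) <- names(tab)
  attr(p, "p0") <- if ("0" %in% names(p)) p[["0"]] else 0
  p
}

.fractions <- function(x, levels) {
  f <- table(factor(x, levels = levels)) / length(x)
  as.numeric(f) |> setNames(levels)
}

#' Summarise outcome records for one sample
#'
#' Category fractions over all reads, flank-change fraction over edited
#' reads, the CAG length histogram stratified by frameshift, top variant
#' signatures, and (when a control is supplied) stutter-corrected category
#' fractions by non-negative subtraction deconvolution applied to the
#' in-frame tract-only block only.
#'
#' @param records outcome records (data.frame, one row per read).
#' @param locus a \code{\link{repeat_locus}}.
#' @param control_records optional records from an unedited control.
#' @param clusters optional cluster table (for top variants by cluster
#'   representative); falls back to per-read signatures.
#' @param top_n number of top variants reported.
#' @return an \code{outcome_summary} list.
#' @export
summarize_outcomes <- function(records, locus, control_records = NULL,
                               clusters = NULL, top_n = 3L) {
  stopifnot(nrow(records) >= 1L)
  n <- nrow(records)
  cat_frac <- .fractions(records$category, CATEGORY_LEVELS)
  edited <- records$category != "UNEDITED"
  flank_fraction <- if (any(edited)) mean(records$flank_changed[edited])
                    else NA_real_
  hist <- aggregate(list(fraction = rep.int(1L, n)),
                    by = list(cag_units = records$cag_units,
                              frameshift = records$frameshift),
                    FUN = function(z) length(z))
  hist$fraction <- hist$fraction / n
  hist <- hist[order(hist$cag_units, hist$frameshift), , drop = FALSE]

  sig <- sprintf("net%+d;cag=%d;fs=%d", records$net_delta,
                 records$cag_units, as.integer(records$frameshift))
  st <- sort(table(sig), decreasing = TRUE)
  top <- data.frame(signature = names(st), fraction = as.numeric(st) / n,
                    stringsAsFactors = FALSE)[seq_len(min(top_n, length(st))), ]

  out <- list(n_reads = n, category_fractions = cat_frac,
              flank_fraction = flank_fraction,
              length_histogram = hist, top_variants = top,
              whole_tract_fraction = mean(records$whole_tract_excised),
              staggered_ins_fraction = mean(records$staggered_ins),
              clusters = clusters, stutter_corrected = NULL)

  if (!is.null(control_records)) {
    stut <- estimate_stutter(control_records, locus$expected_units)
    inframe <- !records$frameshift & !records$flank_changed
    if (any(inframe)) {
      delta <- records$cag_units[inframe] - locus$expected_units
      obs <- table(delta) / n          # fractions of ALL reads
      obs_p <- as.numeric(obs)
      names(obs_p) <- names(obs)
      p0_ctrl <- attr(stut, "p0")
      unedited_frac <- if (p0_ctrl > 0 && "0" %in% names(obs_p))
        obs_p[["0"]] / p0_ctrl else 0
      all_d <- union(names(obs_p), names(stut))
      getp <- function(v, k) if (k %in% names(v)) v[[k]] else 0
      corr <- vapply(all_d, function(k)
        max(0, getp(obs_p, k) - unedited_frac * getp(stut, k)), numeric(1L))
      names(corr) <- all_d
      d_num <- as.integer(all_d)
      cf <- cat_frac
      cf[["UNEDITED"]] <- sum(corr[d_num == 0L])
      cf[["DEL_CAG"]] <- cat_frac[["DEL_CAG"]] -
        sum(obs_p[as.integer(names(obs_p)) < 0L]) + sum(corr[d_num < 0L])
      cf[["INS_CAG"]] <- cat_frac[["INS_CAG"]] -
        sum(obs_p[as.integer(names(obs_p)) > 0L]) + sum(corr[d_num > 0L])
      cf <- pmax(cf, 0)
      if (sum(cf) > 0) cf <- cf / sum(cf)
      out$stutter_corrected <- list(category_fractions = cf,
                                    stutter = stut,
                                    unedited_fraction = unedited_frac,
                                    corrected_delta = corr)
    }
  }
  class(out) <- "outcome_summary"
  out
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary> %d reads\n", x$n_reads))
  f <- x$category_fractions
  f <- f[f > 0 | names(f) %in% c("UNEDITED")]
  for (k in names(f))
    cat(sprintf("  %-13s %6.2f%%\n", k, 100 * f[[k]]))
  cat(sprintf("  flank changed (of edited): %.2f%%\n",
              100 * x$flank_fraction))
  cat(sprintf("  whole-tract excision: %.2f%%  staggered insertion: %.2f%%\n",
              100 * x$whole_tract_fraction,
              100 * x$staggered_ins_fraction))
  invisible(x)
}
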