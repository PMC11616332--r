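# Synthetic-data generators: edited amplicon reads with ground truth, plus
# Cq tables, CE peak tables and LFQ matrices for the companion assays.
#
# Simulated outcome classes (the editing products observed at a CAG-repeat
# locus): UNEDITED, STUTTER (PCR slippage by whole units), INFRAME_DEL_CAG,
# INS_CAG, WHOLE_TRACT_MH_DEL (microhomology-flanked excision of the whole
# tract plus 0-10 flank nt), STAGGERED_INS (single-base duplication of the
# staggered-cut donor base), TEMPLATED_INS (local duplication from the
# upstream flank), FLANK_DEL, DUAL_CUT_EXCISION, COMPLEX.

SIM_CLASSES <- c("UNEDITED", "STUTTER", "INFRAME_DEL_CAG", "INS_CAG",
                 "WHOLE_TRACT_MH_DEL", "STAGGERED_INS", "TEMPLATED_INS",
                 "FLANK_DEL", "DUAL_CUT_EXCISION", "COMPLEX")

# run code under a fixed seed without disturbing the caller's RNG stream
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Outcome mixture specification
#'
#' @param ... named class probabilities (e.g. \code{UNEDITED = 0.05}) or
#'   named lists \code{list(prob =, params = list(...))}.
#' @return \code{outcome_spec} object: list of components with class,
#'   prob and params. Probabilities must sum to 1 (tolerance 1e-9).
#' @examples
#' outcome_spec(UNEDITED = 0.5, WHOLE_TRACT_MH_DEL = 0.5)
#' @export
outcome_spec <- function(...) {
  args <- list(...)
  if (length(args) == 0L) stop("empty outcome spec")
  comps <- lapply(names(args), function(nm) {
    if (!nm %in% SIM_CLASSES)
      stop("unknown outcome class: ", nm)
    a <- args[[nm]]
    if (is.numeric(a)) list(class = nm, prob = as.numeric(a), params = list())
    else list(class = nm, prob = as.numeric(a$prob),
              params = a$params %||% list())
  })
  probs <- vapply(comps, `[[`, numeric(1L), "prob")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("component probabilities must be in [0,1] and sum to 1")
  structure(comps, class = "outcome_spec")
}

#' Read-simulation configuration
#'
#' Defaults mirror the emulated assay: 250 bp paired-end reads and one
#' million reads per sample, constant Phred 30 qualities.
#'
#' @param n_reads number of templates (read pairs when paired).
#' @param seed RNG seed.
#' @param sub_error_rate per-base substitution error probability (< 0.1).
#' @param layout \code{"paired"} or \code{"merged"}.
#' @param read_len read length (<= 300 nt).
#' @param quality list: \code{type = "constant"} with \code{q}, or
#'   \code{type = "decay"} with \code{q0} and \code{slope} (Phred lost per
#'   cycle).
#' @export
sim_config <- function(n_reads = 1e6, seed = 1, sub_error_rate = 0,
                       layout = c("paired", "merged"), read_len = 250,
                       quality = list(type = "constant", q = 30L)) {
  layout <- match.arg(layout)
  stopifnot(n_reads >= 1, sub_error_rate >= 0, sub_error_rate < 0.1,
            read_len <= 300, read_len >= 30)
  structure(list(n_reads = as.integer(n_reads), seed = as.integer(seed),
                 sub_error_rate = sub_error_rate, layout = layout,
                 read_len = as.integer(read_len), quality = quality),
            class = "sim_config")
}

#' Sample a stuttered repeat count
#'
#' PCR slippage model: with probability \code{1 - slip_prob} the unit count
#' is unchanged; otherwise the magnitude of the change is geometric
#' (support >= 1) and the sign is a contraction with probability
#' \code{contraction_bias}. The result is clamped at zero. The rates are
#' tunable placeholders: the modelled experiments report exact whole-unit
#' stutter in unedited samples but no rate.
#'
#' @param units starting unit count (>= 0).
#' @param slip_prob probability of any slip (in [0, 0.5)).
#' @param n number of draws.
#' @param p_geo geometric success parameter for the slip magnitude.
#' @param contraction_bias probability a slip is a contraction.
#' @return integer vector of stuttered unit counts.
#' @export
sample_stutter <- function(units, slip_prob, n = 1L, p_geo = 0.5,
                           contraction_bias = 0.9) {
  stopifnot(units >= 0, slip_prob >= 0, slip_prob < 0.5)
  if (units == 0L) return(rep(0L, n))   # nothing to slip on
  slip <- rbinom(n, 1L, slip_prob) == 1L
  mag <- rgeom(n, p_geo) + 1L
  sgn <- ifelse(rbinom(n, 1L, contraction_bias) == 1L, -1L, 1L)
  delta <- ifelse(slip, sgn * mag, 0L)
  pmax(0L, units + delta)
}

# Whole-tract microhomology deletion candidates: [s, e) spanning the tract
# plus at most flank_max nt on either side, with a junction repeat of at
# least min_mh nt whose 2-mer belongs to mh_words.
.mh_candidates <- function(locus, mh_words = c("CC", "GG"), min_mh = 2L,
                           flank_max = 10L) {
  amp <- locus$amplicon
  rs <- locus$repeat_start
  re <- locus$repeat_end
  out <- NULL
  for (s in seq(max(min_mh, rs - flank_max), rs)) {
    for (e in seq(re, min(nchar(amp), re + flank_max))) {
      sh <- .del_shift_range(amp, s, e)
      if (sh[["left"]] >= min_mh) {
        word2 <- substr(amp, s - 1L, s)
        if (word2 %in% mh_words)
          out <- rbind(out, data.frame(s = s, e = e,
                                       mh_len = sh[["left"]],
                                       word = word2))
      }
    }
  }
  out
}

# one event set: plain lists (hot path; data.frames are too slow per read)
.no_events <- function() list(del_start = integer(0), del_end = integer(0),
                              ins_pos = integer(0), ins_seq = character(0))

# sample one value from a vector (length-1 safe)
.sample1 <- function(v) if (length(v) == 1L) v else sample(v, 1L)

.apply_events <- function(amp, ev) {
  nd <- length(ev$del_start)
  ni <- length(ev$ins_pos)
  if (nd + ni == 0L) return(amp)
  at <- c(ev$del_start, ev$ins_pos)
  kind <- rep(c("del", "ins"), c(nd, ni))
  idx <- c(seq_len(nd), seq_len(ni))
  ord <- order(at)
  out <- character(0)
  cur <- 0L
  for (k in ord) {
    if (kind[k] == "del") {
      out <- c(out, substr(amp, cur + 1L, ev$del_start[idx[k]]))
      cur <- ev$del_end[idx[k]]
    } else {
      out <- c(out, substr(amp, cur + 1L, ev$ins_pos[idx[k]]),
               ev$ins_seq[idx[k]])
      cur <- ev$ins_pos[idx[k]]
    }
  }
  paste0(paste(out, collapse = ""), substr(amp, cur + 1L, nchar(amp)))
}

# Ground-truth labelling from the generator's own event list (mirrors the
# category invariants; the classifier must recover these labels).
.truth_label <- function(locus, template, ev) {
  net <- sum(nchar(ev$ins_seq)) - sum(ev$del_end - ev$del_start)
  has_ins <- length(ev$ins_pos) > 0L
  has_del <- length(ev$del_start) > 0L
  fs <- net %% 3L != 0L
  cag <- .count_units_vec(template, locus$motif)
  cat <- if (!has_ins && !has_del) "UNEDITED"
  else if (fs) {
    if (has_ins && has_del) "INDEL" else if (has_ins) "INS" else "DEL"
  } else if (cag > locus$expected_units) "INS_CAG"
  else if (cag < locus$expected_units) "DEL_CAG"
  else "OTHER_INFRAME"
  amp <- locus$amplicon
  rs <- locus$repeat_start
  re <- locus$repeat_end
  tract_only <- TRUE
  if (has_del)
    tract_only <- all(vapply(seq_along(ev$del_start), function(i)
      .del_tract_only(amp, ev$del_start[i], ev$del_end[i], rs, re),
      logical(1L)))
  if (tract_only && has_ins)
    tract_only <- all(vapply(seq_along(ev$ins_pos), function(i)
      .ins_tract_only(amp, ev$ins_pos[i], ev$ins_seq[i], rs, re),
      logical(1L)))
  list(cag_units = cag, net_delta = net, expected_category = cat,
       whole_tract = has_del &&
         any(ev$del_start <= rs & ev$del_end >= re),
       flank_changed = (has_ins || has_del) && !tract_only)
}

.rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# event generators per class; each returns one event set
.gen_event <- function(class, locus, guides, params) {
  amp <- locus$amplicon
  rs <- locus$repeat_start
  re <- locus$repeat_end
  units <- locus$expected_units
  mlen <- nchar(locus$motif)
  need_guide <- function() {
    if (!length(guides)) stop("guide required for class ", class)
    guides[[params$guide %||% 1L]]
  }
  ev <- .no_events()
  if (class == "UNEDITED") {
    ev
  } else if (class == "STUTTER") {
    u2 <- sample_stutter(units, params$slip_prob %||% 0.02, 1L,
                         params$p_geo %||% 0.5,
                         params$contraction_bias %||% 0.9)
    d <- u2 - units
    if (d < 0L) { ev$del_start <- rs; ev$del_end <- rs - d * mlen }
    if (d > 0L) { ev$ins_pos <- rs; ev$ins_seq <- strrep(locus$motif, d) }
    ev
  } else if (class == "INFRAME_DEL_CAG") {
    k <- .sample1(seq(params$min_units %||% 1L,
                      params$max_units %||% (units - 1L)))
    ev$del_start <- rs
    ev$del_end <- rs + k * mlen
    ev
  } else if (class == "INS_CAG") {
    k <- .sample1(seq(params$min_units %||% 1L, params$max_units %||% 5L))
    ev$ins_pos <- rs
    ev$ins_seq <- strrep(locus$motif, k)
    ev
  } else if (class == "WHOLE_TRACT_MH_DEL") {
    cand <- params$.candidates
    if (is.null(cand) || nrow(cand) == 0L)
      stop("no microhomology candidates on this locus")
    i <- .sample1(seq_len(nrow(cand)))
    ev$del_start <- cand$s[i]
    ev$del_end <- cand$e[i]
    ev
  } else if (class == "STAGGERED_INS") {
    g <- need_guide()
    ev$ins_pos <- g$blunt_cut
    ev$ins_seq <- substr(amp, g$staggered_donor + 1L, g$staggered_donor + 1L)
    ev
  } else if (class == "TEMPLATED_INS") {
    g <- need_guide()
    len <- .sample1(seq(params$min_len %||% 4L, params$max_len %||% 12L))
    win <- params$window %||% 25L
    d0 <- .sample1(seq(max(0L, g$blunt_cut - win), g$blunt_cut - len))
    ev$ins_pos <- g$blunt_cut
    ev$ins_seq <- substr(amp, d0 + 1L, d0 + len)
    ev
  } else if (class == "FLANK_DEL") {
    g <- need_guide()
    d <- .sample1(seq(params$min_len %||% 1L, params$max_len %||% 20L))
    if (g$blunt_cut <= rs) { lo <- 0L; hi <- rs } else { lo <- re; hi <- nchar(amp) }
    smin <- max(lo, g$blunt_cut - d)
    smax <- min(g$blunt_cut, hi - d)
    s <- if (smax > smin) .sample1(seq(smin, smax)) else min(smin, smax)
    ev$del_start <- s
    ev$del_end <- s + d
    ev
  } else if (class == "DUAL_CUT_EXCISION") {
    if (length(guides) < 2L) stop("guide required: two guides needed")
    idx <- params$guides %||% c(1L, 2L)
    cuts <- sort(c(guides[[idx[1L]]]$blunt_cut, guides[[idx[2L]]]$blunt_cut))
    ev$del_start <- cuts[1L]
    ev$del_end <- cuts[2L]
    ev
  } else if (class == "COMPLEX") {
    g <- need_guide()
    d <- .sample1(seq(params$del_min %||% 4L, params$del_max %||% 10L))
    r <- .sample1(seq(params$ins_min %||% 4L, params$ins_max %||% 8L))
    if ((r - d) %% 3L == 0L) r <- r + 1L
    gap <- params$gap %||% 12L
    ev$del_start <- g$blunt_cut
    ev$del_end <- min(nchar(amp), g$blunt_cut + d)
    ev$ins_pos <- max(0L, g$blunt_cut - gap)
    ev$ins_seq <- .rand_dna(r)
    ev
  } else stop("unknown class ", class)
}

.apply_sub_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    L <- nchar(s)
    k <- rbinom(1L, L, rate)
    if (k == 0L) return(s)
    pos <- sample.int(L, k)
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    for (p in pos) {
      ch[p] <- sample(setdiff(bases, ch[p]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

.make_quals <- function(lens, quality) {
  if (identical(quality$type, "decay")) {
    q0 <- quality$q0 %||% 37L
    slope <- quality$slope %||% 0.03
    lapply(lens, function(L) pmax(2L, as.integer(round(q0 - slope * seq_len(L)))))
  } else {
    q <- as.integer(quality$q %||% 30L)
    lapply(lens, function(L) rep.int(q, L))
  }
}

#' Simulate edited amplicon reads with ground truth
#'
#' Draws outcome classes from the mixture, constructs the edited template
#' for each read, optionally adds substitution errors, and emits merged
#' reads or overlapping read pairs. Deterministic given the seed. Read
#' names carry the truth label (class, resulting CAG count, net indel);
#' the full truth table is returned and optionally written as TSV.
#'
#' @param locus a \code{\link{repeat_locus}}.
#' @param guides list of \code{cas9_guide}s (classes tied to a cut site
#'   fail with "guide required" when missing).
#' @param spec an \code{\link{outcome_spec}}.
#' @param cfg a \code{\link{sim_config}}.
#' @param out_dir optional directory: writes \code{R1.fastq}/\code{R2.fastq}
#'   (paired) or \code{merged.fastq}, plus \code{truth.tsv}.
#' @return list with \code{reads} (a \code{read_set}, merged layout) or
#'   \code{r1}/\code{r2} (paired), and \code{truth} (data.frame: read_id,
#'   class, cag_units, net_delta, expected_category, whole_tract,
#'   staggered, flank_changed).
#' @export
simulate_reads <- function(locus, guides, spec, cfg, out_dir = NULL) {
  stopifnot(inherits(spec, "outcome_spec"), inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    n <- cfg$n_reads
    probs <- vapply(spec, `[[`, numeric(1L), "prob")
    classes <- vapply(spec, `[[`, character(1L), "class")
    draw <- sample(seq_along(classes), n, replace = TRUE, prob = probs)

    # precompute whole-tract MH candidates once
    spec <- lapply(spec, function(comp) {
      if (comp$class == "WHOLE_TRACT_MH_DEL") {
        comp$params$.candidates <- .mh_candidates(
          locus,
          comp$params$mh_words %||% c("CC", "GG"),
          comp$params$min_mh %||% 2L,
          comp$params$flank_max %||% 10L)
      }
      comp
    })

    templates <- character(n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      comp <- spec[[draw[i]]]
      ev <- .gen_event(comp$class, locus, guides, comp$params)
      tpl <- .apply_events(locus$amplicon, ev)
      lab <- .truth_label(locus, tpl, ev)
      templates[i] <- tpl
      truth[[i]] <- c(list(class = comp$class), lab)
    }
    truth <- do.call(rbind, lapply(truth, function(x)
      data.frame(class = x$class, cag_units = x$cag_units,
                 net_delta = x$net_delta,
                 expected_category = x$expected_category,
                 whole_tract = x$whole_tract,
                 flank_changed = x$flank_changed,
                 stringsAsFactors = FALSE)))
    truth$staggered <- truth$class == "STAGGERED_INS"
    ids <- sprintf("r%07d;class=%s;cag=%d;net=%+d", seq_len(n),
                   truth$class, truth$cag_units, truth$net_delta)
    truth <- cbind(read_id = ids, truth, stringsAsFactors = FALSE)

    out <- list(truth = truth, layout = cfg$layout)
    if (cfg$layout == "merged") {
      seqs <- .apply_sub_errors(templates, cfg$sub_error_rate)
      out$reads <- structure(list(id = ids, seq = seqs,
                                  qual = .make_quals(nchar(seqs),
                                                     cfg$quality)),
                             class = "read_set")
    } else {
      L <- nchar(templates)
      r1 <- substr(templates, 1L, pmin(L, cfg$read_len))
      r2 <- .revcomp(substr(templates, pmax(1L, L - cfg$read_len + 1L), L))
      r1 <- .apply_sub_errors(r1, cfg$sub_error_rate)
      r2 <- .apply_sub_errors(r2, cfg$sub_error_rate)
      out$r1 <- structure(list(id = ids, seq = r1,
                               qual = .make_quals(nchar(r1), cfg$quality)),
                          class = "read_set")
      out$r2 <- structure(list(id = ids, seq = r2,
                               qual = .make_quals(nchar(r2), cfg$quality)),
                          class = "read_set")
    }
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      if (cfg$layout == "merged") {
        out$files <- file.path(out_dir, "merged.fastq")
        write_fastq(out$reads, out$files)
      } else {
        out$files <- file.path(out_dir, c("R1.fastq", "R2.fastq"))
        write_fastq(out$r1, out$files[1L])
        write_fastq(out$r2, out$files[2L])
      }
      truth_path <- file.path(out_dir, "truth.tsv")
      write.table(truth, truth_path, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      out$truth_file <- truth_path
    }
    out
  })
}

#' Simulate a resection-assay Cq table
#'
#' Analytic inverse of \code{\link{resection_percent}}: for a true ssDNA
#' percentage the digested-fraction Cq exceeds the mock Cq by
#' \code{log2(100/ssdna - 0.5) + 1}, plus optional replicate noise.
#'
#' @param truth data.frame with columns \code{site}, \code{timepoint_h},
#'   \code{ssdna_pct} (0 < ssdna_pct <= 100) and optionally
#'   \code{distance_bp}.
#' @param cq_mock_base baseline mock Cq.
#' @param noise_sd replicate noise SD on the Cq scale.
#' @param seed RNG seed.
#' @param n_bio,n_tech biological / technical replicates per cell.
#' @return long-format data.frame: site, distance_bp, timepoint_h,
#'   condition (digested/mock), replicate, cq.
#' @export
simulate_resection_cq <- function(truth, cq_mock_base = 24, noise_sd = 0,
                                  seed = 1, n_bio = 3L, n_tech = 3L) {
  stopifnot(all(truth$ssdna_pct > 0), all(truth$ssdna_pct <= 100))
  .with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      dcq <- log2(100 / truth$ssdna_pct[i] - 0.5) + 1
      for (b in seq_len(n_bio)) {
        mock_b <- cq_mock_base + if (noise_sd > 0) rnorm(1L, 0, noise_sd) else 0
        for (cond in c("mock", "digested")) {
          cq <- mock_b + if (cond == "digested") dcq else 0
          cq <- cq + if (noise_sd > 0) rnorm(n_tech, 0, noise_sd) else
            rep(0, n_tech)
          rows[[length(rows) + 1L]] <- data.frame(
            site = truth$site[i],
            distance_bp = truth$distance_bp[i] %||% NA,
            timepoint_h = truth$timepoint_h[i],
            condition = cond, replicate = b, cq = cq,
            stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Simulate a label-free proteomics intensity matrix
#'
#' Two groups of \code{n_per_group} replicates; \code{n_shifted} proteins
#' receive a \code{log2_effect} shift in group B (alternating sign).
#' Intensities are log-normal with per-protein means and a common replicate
#' SD; under MNAR missingness the dropout probability decreases with
#' intensity.
#'
#' @param n_proteins,n_shifted counts.
#' @param log2_effect true shift in log2 units.
#' @param n_per_group replicates per group (default 5).
#' @param missing_mechanism \code{"none"} or \code{"MNAR"}.
#' @param seed RNG seed.
#' @param base_mean,base_sd log10 distribution of protein means.
#' @param rep_sd replicate SD in log10 units.
#' @param target_missing overall missing fraction aimed for under MNAR.
#' @return list: \code{intensities} (linear-scale matrix, NA = missing),
#'   \code{groups} (named vector sample -> group), \code{truth}
#'   (data.frame protein, shifted, direction) and \code{logmat_complete}
#'   (the log10 matrix before missingness was applied).
#' @export
simulate_lfq <- function(n_proteins, n_shifted, log2_effect,
                         n_per_group = 5L,
                         missing_mechanism = c("none", "MNAR"), seed = 1,
                         base_mean = 6.5, base_sd = 0.8, rep_sd = 0.1,
                         target_missing = 0.15) {
  missing_mechanism <- match.arg(missing_mechanism)
  stopifnot(n_shifted <= n_proteins)
  .with_seed(seed, {
    if (log2_effect == 0) n_shifted <- 0L
    prot <- sprintf("P%05d", seq_len(n_proteins))
    samples <- c(sprintf("A%d", seq_len(n_per_group)),
                 sprintf("B%d", seq_len(n_per_group)))
    groups <- setNames(rep(c("A", "B"), each = n_per_group), samples)
    mu <- rnorm(n_proteins, base_mean, base_sd)
    shifted <- seq_len(n_proteins) <= n_shifted
    direction <- ifelse(seq_len(n_proteins) %% 2L == 0L, -1, 1)
    direction[!shifted] <- 0
    eff10 <- log2_effect * log10(2)
    logmat <- matrix(rnorm(n_proteins * 2L * n_per_group, 0, rep_sd),
                     n_proteins)
    logmat <- logmat + mu
    bcol <- (n_per_group + 1L):(2L * n_per_group)
    logmat[, bcol] <- logmat[, bcol] + direction * eff10
    complete <- logmat
    if (missing_mechanism == "MNAR") {
      thresh <- quantile(logmat, target_missing)
      pmiss <- stats::plogis((thresh - logmat) / (0.5 * sd(logmat)))
      logmat[matrix(runif(length(logmat)), nrow(logmat)) < pmiss] <- NA
    }
    intensities <- 10^logmat
    dimnames(intensities) <- list(prot, samples)
    dimnames(complete) <- dimnames(intensities)
    list(intensities = intensities, groups = groups,
         truth = data.frame(protein = prot, shifted = shifted,
                            direction = direction,
                            stringsAsFactors = FALSE),
         logmat_complete = complete)
  })
}

#' Simulate a capillary-electrophoresis peak table
#'
#' Peak areas proportional to the true product fractions, heights
#' proportional to areas; optional sub-threshold noise peaks below 5% of
#' the top height.
#'
#' @param fractions data.frame with \code{size_bp} and \code{fraction}
#'   (fractions sum to 1).
#' @param total_area total signal area.
#' @param jitter multiplicative area noise SD.
#' @param n_noise_peaks number of sub-threshold noise peaks to add.
#' @param seed RNG seed.
#' @return data.frame: size_bp, height, area_bp.
#' @export
simulate_ce_peaks <- function(fractions, total_area = 1e4, jitter = 0,
                              n_noise_peaks = 0L, seed = 1) {
  stopifnot(abs(sum(fractions$fraction) - 1) < 1e-9)
  .with_seed(seed, {
    area <- fractions$fraction * total_area
    if (jitter > 0) area <- area * pmax(0.01, 1 + rnorm(length(area), 0, jitter))
    height <- area / 10
    out <- data.frame(size_bp = fractions$size_bp, height = height,
                      area_bp = area)
    if (n_noise_peaks > 0L) {
      hmax <- max(out$height)
      noise <- data.frame(
        size_bp = runif(n_noise_peaks, 50, max(fractions$size_bp) + 50),
        height = runif(n_noise_peaks, 0.001, 0.045) * hmax)
      noise$area_bp <- noise$height * 10
      out <- rbind(out, noise)
    }
    out[order(out$size_bp), , drop = FALSE]
  })
}
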