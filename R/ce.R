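# Capillary-electrophoresis contraction quantification: background peaks
# below 5% of the tallest peak are excluded, then the area fraction outside
# the full-length product gives the percent of shortened products.

#' Filter CE peaks by the 5% height rule
#'
#' Keeps peaks whose height is at least \code{min_frac} of the tallest
#' peak's height in the sample (boundary inclusive).
#'
#' @param peaks data.frame with \code{size_bp}, \code{height},
#'   \code{area_bp}.
#' @param min_frac height threshold relative to the tallest peak
#'   (default 0.05).
#' @export
filter_peaks <- function(peaks, min_frac = 0.05) {
  if (is.null(peaks) || nrow(peaks) == 0L) stop("empty peak table")
  stopifnot(all(peaks$height >= 0), all(peaks$area_bp >= 0))
  peaks[peaks$height >= min_frac * max(peaks$height), , drop = FALSE]
}

#' Percent of shortened products from a filtered peak table
#'
#' Peaks within \code{tol_bp} of \code{full_length_bp} count as full
#' length; the percent shortened is the remaining area fraction. Peaks
#' larger than full length + tolerance are counted as not shortened and
#' reported separately as possible expansions.
#'
#' @param peaks filtered peak table (see \code{\link{filter_peaks}}).
#' @param full_length_bp size of the unedited product (default 242).
#' @param tol_bp size-match tolerance (default 2, CE sizing error).
#' @return numeric percent shortened, with attributes
#'   \code{expansion_pct} (area percent above full length) and
#'   \code{full_length_pct}.
#' @export
percent_shortened <- function(peaks, full_length_bp = 242, tol_bp = 2) {
  total <- sum(peaks$area_bp)
  if (total <= 0) stop("total peak area is zero")
  is_full <- abs(peaks$size_bp - full_length_bp) <= tol_bp
  is_exp <- peaks$size_bp > full_length_bp + tol_bp
  shortened <- 100 * sum(peaks$area_bp[!is_full & !is_exp]) / total
  structure(shortened,
            expansion_pct = 100 * sum(peaks$area_bp[is_exp]) / total,
            full_length_pct = 100 * sum(peaks$area_bp[is_full]) / total)
}

#' CE contraction analysis for one sample
#'
#' @param peaks peak table or path to a CSV with columns size_bp, height,
#'   area_bp.
#' @inheritParams percent_shortened
#' @return list: percent_shortened, full_length_pct, expansion_pct,
#'   n_peaks_kept, n_peaks_removed.
#' @export
ce_contraction <- function(peaks, full_length_bp = 242, tol_bp = 2) {
  if (is.character(peaks)) peaks <- read.csv(peaks)
  kept <- filter_peaks(peaks)
  p <- percent_shortened(kept, full_length_bp, tol_bp)
  list(percent_shortened = as.numeric(p),
       full_length_pct = attr(p, "full_length_pct"),
       expansion_pct = attr(p, "expansion_pct"),
       n_peaks_kept = nrow(kept),
       n_peaks_removed = nrow(peaks) - nrow(kept))
}

#' Compare CE contraction between conditions
#'
#' Mean +/- SD of percent shortened per condition over replicate samples.
#'
#' @param samples data.frame with \code{condition}, \code{replicate} and
#'   either \code{file} (CSV path per sample) or \code{percent_shortened}.
#' @inheritParams percent_shortened
#' @return data.frame: condition, n, mean_pct_shortened, sd_pct_shortened.
#' @export
ce_compare <- function(samples, full_length_bp = 242, tol_bp = 2) {
  if (is.null(samples$percent_shortened)) {
    samples$percent_shortened <- vapply(samples$file, function(f)
      ce_contraction(f, full_length_bp, tol_bp)$percent_shortened,
      numeric(1L))
  }
  out <- aggregate(percent_shortened ~ condition, data = samples,
                   FUN = function(x) c(n = length(x), mean = mean(x),
                                       sd = if (length(x) > 1L) sd(x) else 0))
  cbind(out["condition"],
        setNames(as.data.frame(out$percent_shortened),
                 c("n", "mean_pct_shortened", "sd_pct_shortened")))
}
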