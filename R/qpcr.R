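# Restriction-protection qPCR resection levels and ChIP/DRIP-qPCR
# percent-input / fold-enrichment calculators.
#
# Resection assay logic: a resected (single-stranded) restriction site is
# protected from digestion, so it still amplifies in the digested fraction;
# the Cq gap between digested and mock fractions encodes the ssDNA
# percentage. Technical replicates are averaged on the Cq scale before
# exponentiation; biological replicates are summarised after transformation.

#' ssDNA percentage from digested vs mock Cq values
#'
#' \code{ssDNA\% = 100 / (2^(dCq - 1) + 0.5)} with
#' \code{dCq = cq_digested - cq_mock}. The value is 100 at dCq = 0 and
#' strictly decreasing in dCq; negative dCq (digested amplifying earlier
#' than mock) is clamped to 100 with a warning.
#'
#' @param cq_digested,cq_mock mean Cq of the digested / mock fraction.
#' @return percentage in (0, 100].
#' @examples
#' resection_percent(25, 25)   # 100
#' resection_percent(26, 25)   # 66.67
#' @export
resection_percent <- function(cq_digested, cq_mock) {
  stopifnot(is.finite(cq_digested), is.finite(cq_mock))
  dcq <- cq_digested - cq_mock
  if (any(dcq < 0)) {
    warning("negative delta-Cq clamped to 100% ssDNA")
    dcq <- pmax(dcq, 0)
  }
  100 / (2^(dcq - 1) + 0.5)
}

#' Resection table: per site x timepoint summary
#'
#' Averages technical replicates on the Cq scale, converts each biological
#' replicate's digested/mock pair with \code{\link{resection_percent}}, and
#' reports mean +/- SD per site and timepoint. A cell is flagged
#' \code{above_baseline} when its mean exceeds the site-specific unedited
#' level, or the default 10 percent cutoff when no unedited sample is
#' supplied (the resection level of unedited samples is the cutoff).
#'
#' @param measurements long-format data.frame: \code{site},
#'   \code{timepoint_h}, \code{condition} ("digested"/"mock"),
#'   \code{replicate} (biological), \code{cq}; optional \code{distance_bp}.
#' @param baseline named numeric vector of per-site unedited levels
#'   (percent), or a single default cutoff (default 10).
#' @return data.frame: site, timepoint_h, n, mean_pct, sd_pct,
#'   above_baseline.
#' @export
resection_table <- function(measurements, baseline = 10) {
  req <- c("site", "timepoint_h", "condition", "replicate", "cq")
  if (!all(req %in% names(measurements)))
    stop("missing columns: ", paste(setdiff(req, names(measurements)),
                                    collapse = ", "))
  agg <- aggregate(cq ~ site + timepoint_h + condition + replicate,
                   data = measurements, FUN = mean)
  dig <- agg[agg$condition == "digested", ]
  mock <- agg[agg$condition == "mock", ]
  key <- function(d) paste(d$site, d$timepoint_h, d$replicate, sep = "\r")
  m <- match(key(dig), key(mock))
  if (anyNA(m) || nrow(dig) == 0L || !all(key(mock) %in% key(dig)))
    stop("unpaired measurement: each digested well needs a mock partner")
  dig$pct <- resection_percent(dig$cq, mock$cq[m])
  out <- aggregate(pct ~ site + timepoint_h, data = dig,
                   FUN = function(x) c(n = length(x), mean = mean(x),
                                       sd = if (length(x) > 1L) sd(x) else 0))
  out <- cbind(out[c("site", "timepoint_h")], as.data.frame(out$pct))
  names(out) <- c("site", "timepoint_h", "n", "mean_pct", "sd_pct")
  cut <- if (length(baseline) > 1L || !is.null(names(baseline))) {
    b <- baseline[as.character(out$site)]
    ifelse(is.na(b), 10, b)
  } else rep(baseline, nrow(out))
  out$above_baseline <- out$mean_pct > cut
  out[order(out$site, out$timepoint_h), , drop = FALSE]
}

#' Percent input recovery for ChIP/DRIP-qPCR
#'
#' \code{recovery\% = 100 * 2^((cq_input - log2(dilution)) - cq_ip)}; the
#' dilution term adjusts the input Cq for a diluted input aliquot (e.g. a
#' 100-fold diluted input).
#'
#' @param cq_input,cq_ip mean Cq of input and immunoprecipitate.
#' @param dilution input dilution factor (>= 1, default 1).
#' @return percentage.
#' @export
percent_input_recovery <- function(cq_input, cq_ip, dilution = 1) {
  stopifnot(all(dilution >= 1))
  100 * 2^((cq_input - log2(dilution)) - cq_ip)
}

#' Fold enrichment over a reference region
#'
#' Ratio of input recoveries between a target region and the reference;
#' a twofold or greater increase counts as significant (inclusive).
#'
#' @param recovery_target,recovery_reference input recoveries (percent).
#' @param threshold significance threshold on the fold (default 2).
#' @return list with \code{fold} and \code{significant}.
#' @export
fold_enrichment <- function(recovery_target, recovery_reference,
                            threshold = 2) {
  if (any(recovery_reference <= 0)) stop("reference recovery must be > 0")
  fold <- recovery_target / recovery_reference
  list(fold = fold, significant = fold >= threshold)
}

#' Enrichment table from a long-format qPCR CSV
#'
#' Computes input recovery per region and replicate and fold enrichment
#' over the reference region.
#'
#' @param df data.frame with columns \code{region}, \code{role} ("target"
#'   or "reference"), \code{condition} ("input"/"IP"), \code{replicate},
#'   \code{cq}, optional \code{dilution}.
#' @return data.frame: region, replicate, recovery_pct, fold, significant.
#' @export
enrichment_table <- function(df) {
  req <- c("region", "role", "condition", "replicate", "cq")
  if (!all(req %in% names(df)))
    stop("missing columns: ", paste(setdiff(req, names(df)), collapse = ", "))
  if (is.null(df$dilution)) df$dilution <- 1
  agg <- aggregate(cq ~ region + role + condition + replicate, data = df,
                   FUN = mean)
  dil <- aggregate(dilution ~ region + replicate, data = df, FUN = function(x) x[1L])
  inp <- agg[agg$condition == "input", ]
  ip <- agg[agg$condition == "IP", ]
  key <- function(d) paste(d$region, d$replicate, sep = "\r")
  m <- match(key(ip), key(inp))
  if (anyNA(m)) stop("unpaired measurement: each IP needs an input")
  md <- match(key(ip), key(dil))
  ip$recovery_pct <- percent_input_recovery(inp$cq[m], ip$cq,
                                            dil$dilution[md])
  ref <- ip[ip$role == "reference", ]
  tgt <- ip[ip$role == "target", ]
  mr <- match(tgt$replicate, ref$replicate)
  if (anyNA(mr)) stop("missing reference region for some replicate")
  fe <- fold_enrichment(tgt$recovery_pct, ref$recovery_pct[mr])
  data.frame(region = tgt$region, replicate = tgt$replicate,
             recovery_pct = tgt$recovery_pct, fold = fe$fold,
             significant = fe$significant, stringsAsFactors = FALSE)
}
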