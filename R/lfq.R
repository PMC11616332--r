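# Label-free proteomics differential abundance: valid-value filter,
# log10 transform, downshifted-normal imputation, two-sample t-tests with
# BH (or permutation) FDR, and the q < 0.05 & |fold change| >= 1.5
# significance call.

#' Filter proteins by valid-value count
#'
#' Default reading ("both"): a protein is dropped only when it has fewer
#' than \code{min_valid} non-missing values in BOTH groups (so a protein
#' fully present in one group and absent in the other is kept — an
#' on/off protein). \code{mode = "either"} is the stricter alternative
#' requiring \code{min_valid} values in each group.
#'
#' @param intensities numeric matrix (proteins x samples), NA = missing.
#' @param groups named character vector mapping sample -> group (exactly 2
#'   groups).
#' @param min_valid minimum valid values (default 3).
#' @param mode \code{"both"} (default) or \code{"either"}.
#' @export
filter_valid <- function(intensities, groups, min_valid = 3,
                         mode = c("both", "either")) {
  mode <- match.arg(mode)
  groups <- groups[colnames(intensities)]
  lv <- unique(groups)
  if (length(lv) != 2L) stop("exactly two groups required")
  n1 <- rowSums(!is.na(intensities[, groups == lv[1L], drop = FALSE]))
  n2 <- rowSums(!is.na(intensities[, groups == lv[2L], drop = FALSE]))
  keep <- if (mode == "both") n1 >= min_valid | n2 >= min_valid
          else n1 >= min_valid & n2 >= min_valid
  intensities[keep, , drop = FALSE]
}

#' Impute missing values from a downshifted normal distribution
#'
#' Per sample (column), missing entries are drawn from
#' \code{Normal(mean_s - downshift * sd_s, (width * sd_s)^2)} where
#' \code{mean_s}/\code{sd_s} are the column's observed log-intensity
#' moments — the standard model for intensities missing because they fall
#' below the detection limit. Set \code{per_sample = FALSE} to use the
#' whole-matrix moments instead.
#'
#' @param logmat log-transformed matrix (proteins x samples).
#' @param width,downshift distribution parameters in SD units
#'   (defaults 0.3 and 1.8).
#' @param seed RNG seed (imputation is deterministic given the seed).
#' @param per_sample column-wise moments (default) or global.
#' @export
impute_lfq <- function(logmat, width = 0.3, downshift = 1.8, seed = 1,
                       per_sample = TRUE) {
  .with_seed(seed, {
    if (per_sample) {
      for (j in seq_len(ncol(logmat))) {
        x <- logmat[, j]
        obs <- !is.na(x)
        if (sum(obs) < 2L) stop("sample with fewer than 2 observed values")
        m <- mean(x[obs])
        s <- sd(x[obs])
        k <- sum(!obs)
        if (k > 0L)
          logmat[!obs, j] <- rnorm(k, m - downshift * s, width * s)
      }
    } else {
      obs <- !is.na(logmat)
      if (sum(obs) < 2L) stop("matrix with fewer than 2 observed values")
      m <- mean(logmat[obs])
      s <- sd(logmat[obs])
      k <- sum(!obs)
      if (k > 0L)
        logmat[!obs] <- rnorm(k, m - downshift * s, width * s)
    }
    logmat
  })
}

# vectorised two-sample t-tests over matrix rows
.row_ttests <- function(x1, x2, var_equal = TRUE) {
  n1 <- ncol(x1)
  n2 <- ncol(x2)
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var)
  v2 <- apply(x2, 1L, stats::var)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  t <- (m2 - m1) / se
  p <- 2 * pt(-abs(t), df)
  list(difference = m2 - m1, t = t, p = p, df = df)
}

#' Differential abundance between two groups
#'
#' Two-sample t-tests (equal variance by default, the classic
#' Perseus-style setting; Welch via \code{var_equal = FALSE}) on a
#' filtered, log10-transformed, imputed matrix. \code{difference} is the
#' mean log10 difference (second group minus first, group labels ordered
#' alphabetically, so swapping the labels negates every difference);
#' \code{fold_change} is the signed linear ratio
#' \code{sign(difference) * 10^|difference|}. Significance requires
#' \code{q < alpha} and \code{|fold_change| >= fc_threshold}.
#'
#' @param logmat complete log10 matrix (proteins x samples).
#' @param groups named character vector sample -> group (2 groups).
#' @param var_equal pooled-variance t-test (default TRUE).
#' @param fdr \code{"BH"} (Benjamini-Hochberg, default) or
#'   \code{"permutation"} (group-label permutation FDR).
#' @param alpha q-value cutoff (default 0.05).
#' @param fc_threshold linear fold-change cutoff (default 1.5).
#' @param n_perm,seed permutation count and seed for
#'   \code{fdr = "permutation"}.
#' @return data.frame: protein, difference, fold_change, t, p, q,
#'   significant, n_valid1, n_valid2.
#' @export
lfq_differential <- function(logmat, groups, var_equal = TRUE,
                             fdr = c("BH", "permutation"), alpha = 0.05,
                             fc_threshold = 1.5, n_perm = 250L, seed = 1) {
  fdr <- match.arg(fdr)
  groups <- groups[colnames(logmat)]
  lv <- sort(unique(groups))
  if (length(lv) != 2L) stop("exactly two groups required")
  if (any(is.na(logmat))) stop("matrix must be imputed/complete")
  i1 <- which(groups == lv[1L])
  i2 <- which(groups == lv[2L])
  if (length(i1) < 2L || length(i2) < 2L)
    stop("each group needs at least 2 samples")
  tt <- .row_ttests(logmat[, i1, drop = FALSE], logmat[, i2, drop = FALSE],
                    var_equal)
  q <- if (fdr == "BH") {
    p.adjust(tt$p, "BH")
  } else {
    .with_seed(seed, {
      obs <- abs(tt$t)
      ord <- order(obs, decreasing = TRUE)
      exceed <- numeric(length(obs))
      idx <- seq_len(ncol(logmat))
      for (b in seq_len(n_perm)) {
        perm <- sample(idx)
        pt1 <- perm[seq_along(i1)]
        pt2 <- perm[-seq_along(i1)]
        tb <- abs(.row_ttests(logmat[, pt1, drop = FALSE],
                              logmat[, pt2, drop = FALSE], var_equal)$t)
        exceed <- exceed + vapply(obs, function(o) sum(tb >= o), numeric(1L))
      }
      fp <- exceed / n_perm
      qv <- fp / vapply(obs, function(o) sum(obs >= o), numeric(1L))
      pmin(1, qv)
    })
  }
  fc <- sign(tt$difference) * 10^abs(tt$difference)
  fc[tt$difference == 0] <- 1
  data.frame(protein = rownames(logmat), difference = tt$difference,
             fold_change = fc, t = tt$t, p = tt$p, q = q,
             significant = q < alpha & abs(fc) >= fc_threshold,
             stringsAsFactors = FALSE)
}

#' Full LFQ differential-abundance workflow
#'
#' Valid-value filter, log10 transform, downshifted-normal imputation and
#' two-sample testing in one call.
#'
#' @param intensities linear-scale matrix (proteins x samples), NA =
#'   missing.
#' @inheritParams filter_valid
#' @inheritParams impute_lfq
#' @inheritParams lfq_differential
#' @return see \code{\link{lfq_differential}}; the imputed log matrix is
#'   attached as attribute \code{"logmat"}.
#' @export
lfq_workflow <- function(intensities, groups, min_valid = 3,
                         mode = "both", width = 0.3, downshift = 1.8,
                         seed = 1, var_equal = TRUE, fdr = "BH",
                         alpha = 0.05, fc_threshold = 1.5) {
  m <- filter_valid(intensities, groups, min_valid, mode)
  logm <- log10(m)
  logm <- impute_lfq(logm, width, downshift, seed)
  res <- lfq_differential(logm, groups, var_equal, fdr, alpha, fc_threshold)
  gm <- groups[colnames(m)]
  lv <- sort(unique(gm))
  res$n_valid1 <- rowSums(!is.na(m[, gm == lv[1L], drop = FALSE]))
  res$n_valid2 <- rowSums(!is.na(m[, gm == lv[2L], drop = FALSE]))
  attr(res, "logmat") <- logm
  res
}

#' Read an LFQ matrix and group map
#'
#' @param tsv TSV whose first column is the protein id and remaining
#'   columns are sample intensities (0 or empty = missing).
#' @param groups_json JSON object mapping sample name -> group label.
#' @return list with \code{intensities} and \code{groups}.
#' @export
read_lfq <- function(tsv, groups_json) {
  df <- read.delim(tsv, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1L]]
  mat[mat == 0] <- NA
  groups <- unlist(jsonlite::read_json(groups_json, simplifyVector = TRUE))
  list(intensities = mat, groups = groups)
}
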