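groups10 <- setNames(rep(c("A", "B"), each = 5),
                     c(paste0("A", 1:5), paste0("B", 1:5)))

test_that("valid-value filter implements the both-groups reading", {
  m <- matrix(1000, 3, 10, dimnames = list(c("full", "onoff", "sparse"),
                                           names(groups10)))
  m["onoff", 6:10] <- NA                 # 5 + 0 valid
  m["sparse", c(3:5, 8:10)] <- NA        # 2 + 2 valid
  kept <- filter_valid(m, groups10)
  expect_setequal(rownames(kept), c("full", "onoff"))
  kept2 <- filter_valid(m, groups10, mode = "either")
  expect_equal(rownames(kept2), "full")
})

test_that("imputation draws from the downshifted normal per sample", {
  lm <- matrix(rnorm(40, 6, 0.5), 4, 10, dimnames = list(NULL,
                                                         names(groups10)))
  expect_equal(impute_lfq(lm, seed = 1), lm)   # no missing: unchanged
  lm2 <- lm
  lm2[, 1] <- NA
  expect_error(impute_lfq(lm2, seed = 1), "fewer than 2 observed")
  # Monte-Carlo against the stated law
  n_obs <- 500
  n_miss <- 10000
  col <- c(rnorm(n_obs, 6, 0.4), rep(NA, n_miss))
  lm3 <- cbind(s1 = col, s2 = rnorm(n_obs + n_miss, 6, 0.4))
  imp <- impute_lfq(lm3, seed = 7)
  m_s <- mean(col, na.rm = TRUE)
  sd_s <- sd(col, na.rm = TRUE)
  got <- imp[(n_obs + 1):(n_obs + n_miss), "s1"]
  expect_lt(abs(mean(got) - (m_s - 1.8 * sd_s)),
            3 * 0.3 * sd_s / sqrt(n_miss))
  expect_lt(abs(sd(got) - 0.3 * sd_s), 0.01)
  # deterministic given the seed
  expect_identical(imp, impute_lfq(lm3, seed = 7))
})

test_that("differential testing matches stats::t.test and its invariants", {
  set.seed(5)
  lm <- matrix(rnorm(300, 6, 0.3), 30, 10,
               dimnames = list(sprintf("P%02d", 1:30), names(groups10)))
  res <- lfq_differential(lm, groups10)
  for (i in c(1, 7, 19)) {
    tt <- t.test(lm[i, 6:10], lm[i, 1:5], var.equal = TRUE)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    expect_equal(res$difference[i], unname(diff(rev(tt$estimate))),
                 tolerance = 1e-12)
  }
  # Welch flavour against its reference too
  resw <- lfq_differential(lm, groups10, var_equal = FALSE)
  tt <- t.test(lm[3, 6:10], lm[3, 1:5])
  expect_equal(resw$p[3], tt$p.value, tolerance = 1e-12)
  # row order invariance and group-swap antisymmetry
  perm <- sample(nrow(lm))
  res_p <- lfq_differential(lm[perm, ], groups10)
  expect_equal(res_p$p[match(res$protein, res_p$protein)], res$p)
  swapped <- setNames(ifelse(groups10 == "A", "B", "A"), names(groups10))
  res_s <- lfq_differential(lm, swapped)
  expect_equal(res_s$difference, -res$difference)
})

test_that("identical groups are never significant", {
  lm <- matrix(rep(rnorm(10, 6, 0.2), each = 5), 5, 10, byrow = TRUE)
  lm <- lm[, rep(1:5, 2)]
  colnames(lm) <- names(groups10)
  rownames(lm) <- sprintf("P%d", 1:5)
  res <- lfq_differential(lm, groups10)
  expect_equal(res$difference, rep(0, 5))
  expect_equal(res$fold_change, rep(1, 5))
  expect_false(any(res$significant))
})

test_that("constant shifted groups give the closed-form extreme", {
  lm <- matrix(c(rep(1, 5), rep(2, 5)), 1, 10,
               dimnames = list("P1", names(groups10)))
  res <- lfq_differential(lm, groups10)
  expect_equal(res$difference, 1)
  expect_equal(res$fold_change, 10)     # log10 scale, signed linear ratio
  expect_equal(res$p, 0)                # zero within-group variance
})

test_that("type-I error is calibrated and true effects are recovered", {
  null <- simulate_lfq(2000, 0, 0, seed = 21)
  res0 <- lfq_workflow(null$intensities, null$groups)
  frac <- mean(res0$p < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))
  expect_false(any(res0$significant[res0$q >= 0.05]))

  eff <- simulate_lfq(2000, 100, 1.5, seed = 22)
  res1 <- lfq_workflow(eff$intensities, eff$groups)
  hits <- res1$protein[res1$significant]
  truth <- eff$truth$protein[eff$truth$shifted]
  recall <- mean(truth %in% hits)
  fdr <- if (length(hits)) mean(!hits %in% truth) else 0
  expect_gte(recall, 0.9)
  expect_lte(fdr, 0.05 + 3 * sqrt(0.05 * 0.95 / max(1, length(hits))))
})

test_that("permutation FDR broadly agrees with BH on a strong effect", {
  eff <- simulate_lfq(300, 30, 2, seed = 23)
  bh <- lfq_workflow(eff$intensities, eff$groups)
  pm <- lfq_workflow(eff$intensities, eff$groups, fdr = "permutation")
  truth <- eff$truth$protein[eff$truth$shifted]
  expect_gte(mean(truth %in% pm$protein[pm$significant]), 0.85)
  agree <- mean(bh$significant == pm$significant)
  expect_gte(agree, 0.9)
})

test_that("TSV + JSON input round-trips through the file interface", {
  td <- withr::local_tempdir()
  sim <- simulate_lfq(50, 5, 1.5, seed = 8, missing_mechanism = "MNAR")
  df <- data.frame(protein = rownames(sim$intensities), sim$intensities,
                   check.names = FALSE)
  tsv <- file.path(td, "lfq.tsv")
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "0")
  gj <- file.path(td, "groups.json")
  jsonlite::write_json(as.list(sim$groups), gj, auto_unbox = TRUE)
  res <- pipeline_lfq(tsv, gj, out = file.path(td, "diff.tsv"))
  expect_true(file.exists(file.path(td, "diff.tsv")))
  direct <- lfq_workflow(sim$intensities, sim$groups)
  expect_equal(res$p, direct$p, tolerance = 1e-9)
})
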