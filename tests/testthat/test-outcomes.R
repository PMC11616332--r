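loc <- default_locus()
guides <- default_guides(loc)
amp <- loc$amplicon

classify_seq <- function(read) {
  classify_read(align_to_amplicon(read, loc)[[1]], loc, guides)
}

test_that("count_repeats finds the longest uninterrupted run, leftmost", {
  expect_equal(count_repeats(amp)$units, 41L)
  expect_equal(count_repeats(amp)$interval,
               c(loc$repeat_start, loc$repeat_end))
  expect_equal(count_repeats("TTTT")$units, 0L)
  r <- count_repeats("CAGCAGCAACAGCAG")
  expect_equal(r$units, 2L)            # the CAA interrupts the run
  expect_equal(r$interval, c(0L, 6L))  # leftmost of the two 2-unit runs
  # off-phase run is still found
  expect_equal(count_repeats("TTAGCAGCAGCATT")$units, 2L)
})

test_that("count_repeats agrees with brute force on random sequences", {
  set.seed(2024)
  for (i in 1:200) {
    s <- paste0(rand_dna(60), strrep("CAG", sample(0:12, 1)), rand_dna(60))
    got <- count_repeats(s)
    want <- brute_longest_run(s)
    expect_equal(got$units, want$units)
    if (want$units > 0) expect_equal(got$interval, want$interval)
  }
})

test_that("microhomology detection matches junction-repeat arithmetic", {
  toy <- "AAACCGGGTTTCCTTT"
  mh <- detect_microhomology(5, 13, toy)
  expect_equal(mh$seq, "CC")
  expect_equal(mh$len, 2L)
  expect_equal(brute_mh_len(toy, 5, 13), 2L)
  # unique junction
  expect_equal(detect_microhomology(2, 7, "ACGTACGATTGCA")$len,
               brute_mh_len("ACGTACGATTGCA", 2, 7))
  # deletion inside a pure repeat run reports the repeat-phase word
  mh2 <- detect_microhomology(loc$repeat_start + 3,
                              loc$repeat_start + 9, amp)
  expect_gte(mh2$len, 3L)
})

test_that("microhomology agrees with placement enumeration on random dels", {
  set.seed(31)
  for (i in 1:200) {
    a2 <- paste0(rand_dna(40), strrep("CAG", 8), rand_dna(40))
    s <- sample(2:90, 1)
    d <- sample(1:30, 1)
    if (s + d > nchar(a2) - 2) next
    expect_equal(detect_microhomology(s, s + d, a2)$len,
                 brute_mh_len(a2, s, s + d),
                 info = sprintf("s=%d d=%d seq=%s", s, d, a2))
  }
})

test_that("templated-insertion detection finds nearby donors only", {
  ins <- substr(amp, 40, 43)           # 4-mer copied from 12 nt upstream
  hit <- detect_templated_insertion(51, ins, amp)
  expect_false(is.null(hit))
  expect_equal(substr(amp, hit$donor[1] + 1, hit$donor[2]), hit$seq)
  expect_null(detect_templated_insertion(51, "A", amp))     # below min_len
  expect_null(detect_templated_insertion(51, "TTTTTTTT", amp))
})

test_that("staggered-cut detector requires the exact donor duplication", {
  g <- guides$up
  expect_true(detect_staggered_ins(g$blunt_cut, "A", g, amp))
  expect_true(detect_staggered_ins(g$blunt_cut - 1L, "A", g, amp))
  expect_false(detect_staggered_ins(g$blunt_cut, "T", g, amp))
  expect_false(detect_staggered_ins(g$blunt_cut, "AA", g, amp))
  expect_false(detect_staggered_ins(g$blunt_cut + 5L, "A", g, amp))
})

test_that("classify_read covers the category corners", {
  r <- classify_seq(amp)
  expect_equal(r$category, "UNEDITED")
  expect_equal(r$cag_units, 41L)
  expect_false(r$frameshift)

  # two units deleted inside the tract: in-frame, tract-only
  read <- paste0(substr(amp, 1, 100), substr(amp, 107, 242))
  r2 <- classify_seq(read)
  expect_equal(r2$category, "DEL_CAG")
  expect_equal(r2$cag_units, 39L)
  expect_false(r2$flank_changed)

  # single A at the upstream blunt cut: frameshift INS, staggered signature
  read3 <- paste0(substr(amp, 1, 52), "A", substr(amp, 53, 242))
  r3 <- classify_seq(read3)
  expect_equal(r3$category, "INS")
  expect_true(r3$frameshift)
  expect_true(r3$staggered_ins)

  # deletion spanning the tract plus 2 upstream flank nt (net -125)
  read4 <- paste0(substr(amp, 1, 56), substr(amp, 182, 242))
  r4 <- classify_seq(read4)
  expect_equal(r4$net_delta, -125L)
  expect_equal(r4$category, "DEL")
  expect_true(r4$frameshift)
  expect_true(r4$flank_changed)
  expect_true(r4$whole_tract_excised)

  # frameshift with both event kinds is INDEL
  read5 <- paste0(substr(amp, 1, 40), "TTTT", substr(amp, 41, 52),
                  substr(amp, 58, 242))
  r5 <- classify_seq(read5)
  expect_equal(r5$category, "INDEL")
})

test_that("record invariants hold on a simulated mixture", {
  spec <- outcome_spec(UNEDITED = 0.15, STUTTER = 0.05,
                       INFRAME_DEL_CAG = 0.15, INS_CAG = 0.1,
                       WHOLE_TRACT_MH_DEL = 0.1, STAGGERED_INS = 0.1,
                       TEMPLATED_INS = 0.1, FLANK_DEL = 0.1,
                       DUAL_CUT_EXCISION = 0.05, COMPLEX = 0.1)
  sim <- simulate_reads(loc, guides, spec,
                        sim_config(n_reads = 1500, seed = 17,
                                   layout = "merged"))
  res <- pipeline_classify(sim, loc, guides)
  rec <- res$records
  expect_equal(rec$frameshift, rec$net_delta %% 3 != 0)
  fs_cat <- rec$category %in% c("INS", "DEL", "INDEL")
  expect_equal(fs_cat, rec$frameshift)
  expect_true(all(rec$net_delta[rec$category == "UNEDITED"] == 0))
  expect_true(all(rec$cag_units[rec$category == "UNEDITED"] == 41L))
  s <- res$summary
  expect_equal(sum(s$category_fractions), 1, tolerance = 1e-9)
  expect_equal(sum(s$length_histogram$fraction), 1, tolerance = 1e-9)
  # frameshift fraction computed from categories vs from net length change
  expect_equal(mean(fs_cat), mean(rec$net_delta %% 3 != 0))
})

test_that("every simulator class closes back to its intended category", {
  for (cls in cagrepair:::SIM_CLASSES) {
    args <- setNames(list(1), cls)
    spec <- do.call(outcome_spec, args)
    sim <- simulate_reads(loc, guides, spec,
                          sim_config(n_reads = 120, seed = 23,
                                     layout = "merged"))
    res <- pipeline_classify(sim, loc, guides)
    m <- match(res$records$read_id, sim$truth$read_id)
    expect_equal(res$records$category, sim$truth$expected_category[m],
                 info = cls)
    expect_equal(res$records$whole_tract_excised, sim$truth$whole_tract[m],
                 info = cls)
    expect_equal(res$records$flank_changed, sim$truth$flank_changed[m],
                 info = cls)
  }
})

test_that("stutter estimation and self-deconvolution behave", {
  un <- simulate_reads(loc, guides, outcome_spec(UNEDITED = 1),
                       sim_config(n_reads = 100, seed = 2,
                                  layout = "merged"))
  run <- pipeline_classify(un, loc, guides)
  st <- estimate_stutter(run$records, 41L)
  expect_equal(unname(st[["0"]]), 1)

  ctl <- simulate_reads(loc, guides,
                        outcome_spec(STUTTER = list(prob = 1,
                                                    params = list(slip_prob = 0.1))),
                        sim_config(n_reads = 4000, seed = 9,
                                   layout = "merged"))
  rctl <- pipeline_classify(ctl, loc, guides)
  st2 <- estimate_stutter(rctl$records, 41L)
  p_ne <- 1 - attr(st2, "p0")
  expect_lt(abs(p_ne - 0.1), 3 * sqrt(0.1 * 0.9 / 4000))
  # control deconvolved against itself leaves ~no non-zero mass
  s <- summarize_outcomes(rctl$records, loc, control_records = rctl$records)
  corr <- s$stutter_corrected$corrected_delta
  expect_lt(sum(corr[names(corr) != "0"]), 1e-9)
  # a control with only flank-changed reads is unusable
  fl <- rctl$records
  fl$flank_changed <- TRUE
  expect_error(estimate_stutter(fl, 41L), "no usable")
  expect_error(estimate_stutter(fl[0, ], 41L), "empty control")
})

test_that("summaries report the expected headline fractions", {
  un <- simulate_reads(loc, guides, outcome_spec(UNEDITED = 1),
                       sim_config(n_reads = 50, seed = 2,
                                  layout = "merged"))
  r <- pipeline_classify(un, loc, guides)
  expect_equal(unname(r$summary$category_fractions[["UNEDITED"]]), 1)
  expect_true(is.na(r$summary$flank_fraction))  # nothing edited
  sim <- simulate_reads(loc, guides, closure_spec(),
                        sim_config(n_reads = 2000, seed = 13,
                                   layout = "merged"))
  res <- pipeline_classify(sim, loc, guides)
  m <- match(res$records$read_id, sim$truth$read_id)
  # closure: summary fractions equal the truth-label fractions exactly
  expect_equal(category_fracs(res$records$category),
               category_fracs(sim$truth$expected_category[m]))
  expect_equal(res$summary$staggered_ins_fraction,
               mean(sim$truth$staggered[m]))
  expect_equal(res$summary$whole_tract_fraction,
               mean(sim$truth$whole_tract[m]))
  expect_equal(nrow(res$summary$top_variants), 3L)
})
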