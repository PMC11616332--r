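loc <- default_locus()
amp <- loc$amplicon

test_that("mean-quality filter keeps the inclusive boundary", {
  reads <- structure(list(
    id = c("hi", "lo", "edge"),
    seq = rep(strrep("A", 4), 3),
    qual = list(rep(30L, 4), rep(2L, 4), c(4L, 6L, 4L, 6L))),
    class = "read_set")
  out <- quality_filter(reads, 5)
  expect_setequal(out$id, c("hi", "edge"))
  expect_equal(attr(out, "n_discarded"), 1L)
})

test_that("pair merging reconstructs templates and honours quality", {
  tpl <- substr(amp, 1, 120)
  r1 <- list(seq = substr(tpl, 1, 80), qual = rep(30L, 80))
  r2 <- list(seq = cagrepair:::.revcomp(substr(tpl, 41, 120)),
             qual = rep(30L, 80))
  m <- merge_pair(r1, r2)
  expect_equal(m$seq, tpl)
  # disagreement resolves to the higher-quality base
  r1bad <- r1
  substr(r1bad$seq, 60, 60) <- "N"
  r1bad$qual[60] <- 10L
  r2$qual <- rep(40L, 80)
  m2 <- merge_pair(r1bad, r2)
  expect_equal(m2$seq, tpl)
  expect_equal(m2$qual[60], 40L)
  # and the reverse preference when r1 is the confident read
  r2bad <- list(seq = cagrepair:::.revcomp(substr(tpl, 41, 120)),
                qual = rep(10L, 80))
  substr(r2bad$seq, 1, 1) <- "N"       # corrupts template position 120
  m3 <- merge_pair(r1, r2bad)
  expect_equal(substr(m3$seq, 1, 80), substr(tpl, 1, 80))
  # non-overlapping mates stay unmerged
  expect_equal(merge_pair(list(seq = strrep("A", 40), qual = rep(30L, 40)),
                          list(seq = strrep("C", 40), qual = rep(30L, 40))),
               "UNMERGED")
})

test_that("alignment recovers exact reads, long deletions and insertions", {
  a <- align_to_amplicon(amp, loc)[[1]]
  expect_equal(a$identity, 1)
  expect_equal(nrow(a$ins) + nrow(a$del), 0L)

  # 123-nt deletion with solid anchors on both sides
  read <- paste0(substr(amp, 1, 80), substr(amp, 204, 242))
  a2 <- align_to_amplicon(read, loc)[[1]]
  expect_equal(nrow(a2$del), 1L)
  expect_equal(a2$del$end - a2$del$start, 123L)
  expect_equal(nrow(a2$ins), 0L)

  read3 <- paste0(substr(amp, 1, 52), "A", substr(amp, 53, 242))
  a3 <- align_to_amplicon(read3, loc)[[1]]
  expect_equal(nrow(a3$ins), 1L)
  expect_equal(a3$ins$seq, "A")

  expect_error(align_to_amplicon("ACGX", loc), "invalid sequence")
})

test_that("random reads are rejected by the identity threshold", {
  set.seed(99)
  rand <- vapply(1:10, function(i) rand_dna(250), character(1))
  res <- align_to_amplicon(rand, loc)
  expect_true(all(vapply(res, is.null, logical(1))))
})

test_that("alignment scores match the Needleman-Wunsch reference", {
  # independent cross-check: Biostrings global alignment with identical
  # scoring (gap of length L costs 6 + 0.5 L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  set.seed(123)
  for (i in 1:12) {
    read <- amp
    # random small perturbations: substitutions and one indel
    p <- sample(40:200, 1)
    substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
    if (i %% 3 == 0) {
      d <- sample(1:20, 1)
      q <- sample(30:180, 1)
      read <- paste0(substr(read, 1, q), substr(read, q + d + 1, 242))
    } else if (i %% 3 == 1) {
      q <- sample(30:200, 1)
      read <- paste0(substr(read, 1, q), rand_dna(sample(1:8, 1)),
                     substr(read, q + 1, 242))
    }
    ours <- align_to_amplicon(read, loc, min_identity = 0)[[1]]
    ref <- Biostrings::pairwiseAlignment(read, amp, type = "global",
                                         substitutionMatrix = mat,
                                         gapOpening = 6, gapExtension = 0.5)
    expect_equal(ours$score, Biostrings::score(ref), tolerance = 1e-9)
  }
})

test_that("indel normalisation is leftmost, idempotent and oracle-exact", {
  # one CAG unit deleted mid-tract left-normalises to the tract edge
  read <- paste0(substr(amp, 1, 100), substr(amp, 104, 242))
  a <- align_to_amplicon(read, loc)[[1]]
  expect_equal(nrow(a$del), 1L)
  s <- a$del$start
  e <- a$del$end
  expect_equal(min(brute_del_placements(amp, s, e)), s)
  expect_identical(normalize_indels(a, loc), a)   # idempotent
  # MH-flanked deletion: leftmost equals the brute-force enumeration
  set.seed(11)
  for (i in 1:25) {
    s0 <- sample(20:200, 1)
    d <- sample(3:30, 1)
    if (s0 + d > 241) next
    read <- paste0(substr(amp, 1, s0), substr(amp, s0 + d + 1, 242))
    a <- align_to_amplicon(read, loc)[[1]]
    if (nrow(a$del) != 1L || nrow(a$ins) > 0L) next  # error-free => clean
    expect_equal(a$del$start, min(brute_del_placements(amp, a$del$start,
                                                       a$del$end)))
  }
})

test_that("greedy clustering obeys length, identity and conservation", {
  s1 <- strrep("ACGT", 25)
  s2 <- s1
  for (p in seq(1, 40, 4)) substr(s2, p, p) <- "T"   # 10 diffs in 100
  s3 <- s1
  for (p in c(1, 13, 25, 37, 49)) substr(s3, p, p) <- "G"  # 5 diffs: 95%
  cl <- cluster_reads(c(s1, s1))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$size, 2L)
  cl2 <- cluster_reads(c(s1, s1, s2))
  expect_equal(nrow(cl2), 2L)
  cl3 <- cluster_reads(c(s1, s1, s3))
  expect_equal(nrow(cl3), 1L)          # exactly 95% joins (inclusive)
  # same prefix, different length: never merged
  cl4 <- cluster_reads(c(s1, substr(s1, 1, 60)))
  expect_equal(nrow(cl4), 2L)
  # conservation over a simulated batch
  sim <- simulate_reads(default_locus(), default_guides(), closure_spec(),
                        sim_config(n_reads = 500, seed = 3,
                                   layout = "merged"))
  cl5 <- cluster_reads(sim$reads$seq)
  expect_equal(sum(cl5$size), 500L)
})

test_that("FASTQ writing and reading round-trip sequences and qualities", {
  td <- withr::local_tempdir()
  rs <- make_read_set(c("ACGTACGT", "GGGGCCCC"), q = 31L)
  f <- file.path(td, "x.fastq")
  write_fastq(rs, f)
  back <- read_fastq(f)
  expect_equal(back$seq, rs$seq)
  expect_equal(back$qual, rs$qual)
  expect_equal(back$id, rs$id)
})
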