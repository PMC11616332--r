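# Independent oracles used across the suite: brute-force searches that are
# deliberately slower and simpler than the implementation they check.

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# longest exact tandem run of motif (any phase), by trying every start
brute_longest_run <- function(seq, motif = "CAG") {
  n <- nchar(seq)
  m <- nchar(motif)
  best <- 0L
  best_start <- 0L
  for (s in seq_len(n)) {
    u <- 0L
    while (s + (u + 1L) * m - 1L <= n &&
           substr(seq, s + u * m, s + (u + 1L) * m - 1L) == motif) {
      u <- u + 1L
    }
    if (u > best) {
      best <- u
      best_start <- s - 1L
    }
  }
  list(units = best, interval = c(best_start, best_start + best * m))
}

# all equivalent placements of a deletion: intervals of the same length
# whose removal yields the same edited sequence
brute_del_placements <- function(amp, s, e) {
  len <- e - s
  edited <- paste0(substr(amp, 1L, s), substr(amp, e + 1L, nchar(amp)))
  keep <- integer(0)
  for (s2 in 0:(nchar(amp) - len)) {
    e2 <- s2 + len
    alt <- paste0(substr(amp, 1L, s2), substr(amp, e2 + 1L, nchar(amp)))
    if (alt == edited) keep <- c(keep, s2)
  }
  keep
}

# microhomology length via placement enumeration: contiguous equivalent
# placements left/right of [s, e) correspond to repeated junction bases
brute_mh_len <- function(amp, s, e, max_len = 10L) {
  pl <- brute_del_placements(amp, s, e)
  l <- 0L
  while ((s - (l + 1L)) %in% pl) l <- l + 1L
  r <- 0L
  while ((s + (r + 1L)) %in% pl) r <- r + 1L
  min(max(l, r), max_len)
}

make_read_set <- function(seqs, q = 30L, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%04d", seq_along(seqs))
  structure(list(id = ids, seq = seqs,
                 qual = lapply(nchar(seqs), function(L) rep.int(q, L))),
            class = "read_set")
}

# default study-like mixture used by the closure tests
closure_spec <- function() {
  outcome_spec(UNEDITED = 0.05, WHOLE_TRACT_MH_DEL = 0.55,
               STAGGERED_INS = 0.10, INFRAME_DEL_CAG = 0.20,
               FLANK_DEL = 0.10)
}

SIX_CATEGORIES <- c("UNEDITED", "INS_CAG", "DEL_CAG", "INS", "DEL", "INDEL")

category_fracs <- function(x, levels = c(SIX_CATEGORIES, "OTHER_INFRAME")) {
  as.numeric(table(factor(x, levels = levels))) / length(x)
}
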