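# Amplicon / repeat-tract / guide geometry. All coordinates are 0-based,
# half-open; cut sites are between-base indices (a cut at index c falls
# between bases c-1 and c).

#' Construct a repeat locus
#'
#' An amplicon reference with an annotated tandem-repeat interval. The
#' interval must consist of exact copies of the motif.
#'
#' @param name locus label.
#' @param amplicon uppercase DNA string (A/C/G/T).
#' @param repeat_start,repeat_end 0-based half-open interval of the repeat
#'   tract on the amplicon.
#' @param motif repeat unit (default \code{"CAG"}).
#' @return An object of class \code{repeat_locus} with fields
#'   \code{name}, \code{amplicon}, \code{motif}, \code{repeat_start},
#'   \code{repeat_end} and \code{expected_units}.
#' @examples
#' loc <- default_locus()
#' nchar(loc$amplicon)    # 242
#' loc$expected_units     # 41
#' @export
repeat_locus <- function(name, amplicon, repeat_start, repeat_end,
                         motif = "CAG") {
  stopifnot(is.character(amplicon), length(amplicon) == 1L)
  amplicon <- toupper(amplicon)
  if (grepl("[^ACGT]", amplicon)) stop("invalid locus: non-ACGT amplicon")
  n <- nchar(amplicon)
  if (!(repeat_start >= 0 && repeat_end <= n && repeat_end > repeat_start))
    stop("invalid locus: repeat interval out of bounds")
  len <- repeat_end - repeat_start
  if (len %% nchar(motif) != 0L)
    stop("invalid locus: tract length not a multiple of the motif")
  units <- len %/% nchar(motif)
  tract <- substr(amplicon, repeat_start + 1L, repeat_end)
  if (tract != strrep(motif, units))
    stop("invalid locus: repeat interval is not motif-pure")
  structure(list(name = name, amplicon = amplicon, motif = motif,
                 repeat_start = repeat_start, repeat_end = repeat_end,
                 expected_units = units),
            class = "repeat_locus")
}

#' @export
print.repeat_locus <- function(x, ...) {
  cat(sprintf("<repeat_locus> %s: %d bp amplicon, (%s)%d at [%d,%d)\n",
              x$name, nchar(x$amplicon), x$motif, x$expected_units,
              x$repeat_start, x$repeat_end))
  invisible(x)
}

# Bundled synthetic amplicon: 242 bp, (CAG)41 at [58,181). The flanks are
# synthetic (matched length/GC, no CAG triplet anywhere) but engineered to
# carry the hallmarks of the modelled locus: an NGG guide ending 6 nt
# upstream of the tract whose staggered-cut donor base is A, a second NGG
# guide just downstream, and CC/GG words within 10 nt of both tract
# boundaries so that whole-tract microhomology-mediated deletions exist.
.default_amplicon <- function() {
  left <- paste0("TCTGCTTCACCGCTCTGGTCACTTGGCTTCTGCTC",
                 "GCTCCTTGTCGTC", "CCTATCT", "TGG")
  right <- paste0("CCACCATGGG",
                  "TCTTCTCCTTCTGCCTCCTCTTGCTGCTTTGCTCCGCCTCCTGCTTCTGCT")
  paste0(left, strrep("CAG", 41L), right)
}

#' Bundled default CAG-repeat locus
#'
#' A deterministic synthetic 242 bp amplicon carrying a (CAG)41 tract at
#' 0-based interval [58, 181), with guide target sites in both flanks.
#' The flank sequence is synthetic (the package does not bundle genomic
#' sequence); every operation accepts a user locus loaded with
#' \code{\link{read_locus}} instead.
#'
#' @param config optional list overriding \code{name}.
#' @return a \code{\link{repeat_locus}}.
#' @export
default_locus <- function(config = list()) {
  repeat_locus(name = config$name %||% "CAG41_synthetic",
               amplicon = .default_amplicon(),
               repeat_start = 58L, repeat_end = 181L, motif = "CAG")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN",
           paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]), collapse = ""))
  }, character(1L), USE.NAMES = FALSE)
}

.pam_regex <- function(pam_pattern) {
  if (!pam_pattern %in% c("NGG", "NAG"))
    stop("pam_pattern must be NGG or NAG")
  paste0("[ACGT]", substr(pam_pattern, 2L, 3L))
}

.find_placements <- function(seqstr, protospacer, pam_regex) {
  hits <- integer(0)
  offset <- 0L
  hay <- seqstr
  repeat {
    p <- regexpr(protospacer, hay, fixed = TRUE)[1L]
    if (p < 0L) break
    hits <- c(hits, offset + p - 1L)            # 0-based protospacer start
    hay <- substr(hay, p + 1L, nchar(hay))      # allow overlapping hits
    offset <- offset + p
  }
  keep <- vapply(hits, function(h) {
    pam <- substr(seqstr, h + 21L, h + 23L)
    nchar(pam) == 3L && grepl(pam_regex, pam)
  }, logical(1L))
  hits[keep]
}

#' Locate a guide on a repeat locus
#'
#' Finds the protospacer+PAM placement on either strand and derives the
#' blunt cut (3 nt 5' of the PAM) and the staggered-cut donor base (the
#' 4th nucleotide upstream of the PAM on the non-target strand, whose
#' duplication is the signature of a staggered cut). Placements whose
#' protospacer lies fully inside the repeat tract may be multiple (a guide
#' of repeat composition cuts at several registers); the leftmost is
#' returned and the multiplicity recorded in \code{n_placements}.
#'
#' @param locus a \code{\link{repeat_locus}}.
#' @param protospacer 20-nt DNA string.
#' @param pam_pattern \code{"NGG"} or \code{"NAG"}.
#' @param name guide label.
#' @return An object of class \code{cas9_guide}: \code{name},
#'   \code{protospacer}, \code{pam}, \code{strand} (\code{"+"}/\code{"-"}),
#'   \code{blunt_cut} (between-base index), \code{staggered_donor}
#'   (0-based base index) and \code{n_placements}.
#' @export
locate_guide <- function(locus, protospacer, pam_pattern = "NGG",
                         name = "guide") {
  stopifnot(inherits(locus, "repeat_locus"))
  protospacer <- toupper(protospacer)
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt")
  pam_re <- .pam_regex(pam_pattern)
  amp <- locus$amplicon
  L <- nchar(amp)
  fwd <- .find_placements(amp, protospacer, pam_re)
  rev_hits <- .find_placements(.revcomp(amp), protospacer, pam_re)

  place <- function(p, strand) {
    if (strand == "+") {
      list(strand = "+", proto_start = p,
           pam = substr(amp, p + 21L, p + 23L),
           blunt_cut = p + 17L, staggered_donor = p + 16L)
    } else {
      a <- L - p - 20L                          # protospacer interval [a, a+20)
      list(strand = "-", proto_start = a,
           pam = .revcomp(substr(amp, a - 2L, a)),
           blunt_cut = a + 3L, staggered_donor = a + 3L)
    }
  }
  placements <- c(lapply(fwd, place, strand = "+"),
                  lapply(rev_hits, place, strand = "-"))
  if (length(placements) == 0L) stop("guide not found")
  inside <- vapply(placements, function(pl) {
    pl$proto_start >= locus$repeat_start &&
      pl$proto_start + 20L <= locus$repeat_end
  }, logical(1L))
  if (sum(!inside) > 1L || (sum(!inside) == 1L && any(inside)))
    stop("ambiguous guide")
  starts <- vapply(placements, `[[`, numeric(1L), "proto_start")
  pl <- placements[[which.min(starts)]]
  structure(list(name = name, protospacer = protospacer, pam = pl$pam,
                 strand = pl$strand, proto_start = pl$proto_start,
                 blunt_cut = pl$blunt_cut,
                 staggered_donor = pl$staggered_donor,
                 n_placements = length(placements)),
            class = "cas9_guide")
}

#' @export
print.cas9_guide <- function(x, ...) {
  cat(sprintf(
    "<cas9_guide> %s (%s strand, PAM %s): blunt cut at %d, donor base %d%s\n",
    x$name, x$strand, x$pam, x$blunt_cut, x$staggered_donor,
    if (x$n_placements > 1L)
      sprintf(" [%d placements, leftmost used]", x$n_placements) else ""))
  invisible(x)
}

#' Bundled guides for the default locus
#'
#' Two guides analogous to flank-targeting guides at a CAG tract: one with
#' its blunt cut 6 nt upstream of the tract and one cutting 3 nt downstream
#' of it. Both have an adenine donor base, so their staggered-cut signature
#' is a single inserted A.
#'
#' @param locus a \code{\link{repeat_locus}}; default bundled locus.
#' @return named list of two \code{cas9_guide} objects (\code{up},
#'   \code{down}).
#' @export
default_guides <- function(locus = default_locus()) {
  amp <- locus$amplicon
  up <- locate_guide(locus, substr(amp, 36L, 55L), "NGG", name = "gRNA_up")
  down <- locate_guide(locus, substr(amp, 168L, 187L), "NGG",
                       name = "gRNA_down")
  list(up = up, down = down)
}

#' Load a locus (and its guides) from FASTA + JSON sidecar
#'
#' The JSON sidecar has fields \code{motif}, \code{repeat_start},
#' \code{repeat_end} (0-based half-open) and optionally
#' \code{guides = [{name, protospacer, pam}, ...]}.
#'
#' @param fasta path to a single-record FASTA amplicon.
#' @param json path to the JSON annotation.
#' @return list with elements \code{locus} and \code{guides}.
#' @export
read_locus <- function(fasta, json) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) != 1L) stop("invalid locus: FASTA must hold one amplicon")
  cfg <- jsonlite::read_json(json, simplifyVector = TRUE)
  loc <- repeat_locus(name = names(seqs)[1L],
                      amplicon = as.character(seqs[[1L]]),
                      repeat_start = as.integer(cfg$repeat_start),
                      repeat_end = as.integer(cfg$repeat_end),
                      motif = cfg$motif %||% "CAG")
  guides <- list()
  if (!is.null(cfg$guides) && NROW(cfg$guides) > 0L) {
    gdf <- as.data.frame(cfg$guides)
    guides <- lapply(seq_len(nrow(gdf)), function(i) {
      locate_guide(loc, gdf$protospacer[i], gdf$pam[i] %||% "NGG",
                   name = gdf$name[i])
    })
    names(guides) <- gdf$name
  }
  list(locus = loc, guides = guides)
}
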