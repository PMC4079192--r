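# Target-site-duplication inference: direct-repeat detection in flanks,
# IUPAC motif building, insertion-context base bias, and verification of
# duplication against paralogous empty sites.

#' Detect a target-site duplication in element flanks
#'
#' Searches for the longest exact direct repeat (suffix of the left flank
#' equal to prefix of the right flank) with length in
#' `[min_len, max_len]`. Also reports the bases immediately outside the
#' repeat pair (5' of the left copy, 3' of the right copy), used for
#' insertion-context bias.
#'
#' @param left Flank ending at the element 5' boundary.
#' @param right Flank starting at the element 3' boundary.
#' @param min_len,max_len Repeat length search range (default 2-6 bp,
#'   covering the 3-4 bp TSDs typical of CMC elements).
#' @return `NULL` when no repeat is found, else a list (`tsd_call`) with
#'   `tsd`, `length`, `base_5prime_adjacent`, `base_3prime_adjacent`.
#' @export
detect_tsd <- function(left, right, min_len = 2L, max_len = 6L) {
  left <- toupper(left); right <- toupper(right)
  if (min_len < 1L || min_len > max_len) {
    stop("need 1 <= min_len <= max_len", call. = FALSE)
  }
  if (nchar(left) < max_len + 1L || nchar(right) < max_len + 1L) {
    stop("flank shorter than max_len + 1: cannot search for TSD",
         call. = FALSE)
  }
  for (len in seq(max_len, min_len)) {
    lsuf <- substr(left, nchar(left) - len + 1L, nchar(left))
    rpre <- substr(right, 1L, len)
    if (lsuf == rpre) {
      out <- list(tsd = lsuf, length = len,
                  base_5prime_adjacent = substr(left, nchar(left) - len,
                                                nchar(left) - len),
                  base_3prime_adjacent = substr(right, len + 1L, len + 1L))
      class(out) <- "tsd_call"
      return(out)
    }
  }
  NULL
}

#' IUPAC consensus motif of a set of TSD calls
#'
#' Per position, the IUPAC code covering every base observed at frequency
#' at least `noise_floor` (default 0.05, suppressing sporadic mutations).
#'
#' @param calls List of `tsd_call` objects (or plain TSD strings), all of
#'   one length.
#' @param noise_floor Minimum per-position frequency for a base to enter
#'   the code.
#' @return IUPAC motif string.
#' @export
tsd_motif <- function(calls, noise_floor = 0.05) {
  tsds <- vapply(calls, function(x) if (is.list(x)) x$tsd else x,
                 character(1))
  if (length(tsds) == 0L) stop("no TSD calls", call. = FALSE)
  if (length(unique(nchar(tsds))) != 1L) {
    stop("mixed TSD lengths: cannot build a motif", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(tsds), ""))
  paste(apply(mat, 2, function(col) {
    freq <- table(col) / length(col)
    iupac_code(names(freq)[freq >= noise_floor])
  }), collapse = "")
}

#' Frequencies of the bases adjacent to the TSD pair
#'
#' @param calls List of `tsd_call` objects.
#' @return List with `five_prime` and `three_prime`: length-4 frequency
#'   vectors over A/C/G/T, each summing to 1.
#' @export
adjacent_base_bias <- function(calls) {
  if (length(calls) == 0L) stop("no TSD calls", call. = FALSE)
  tab <- function(bases) {
    f <- table(factor(toupper(bases), levels = DNA_BASES))
    stats::setNames(as.numeric(f) / length(bases), DNA_BASES)
  }
  list(
    five_prime = tab(vapply(calls, `[[`, character(1),
                            "base_5prime_adjacent")),
    three_prime = tab(vapply(calls, `[[`, character(1),
                             "base_3prime_adjacent"))
  )
}

#' Verify duplication-upon-insertion against a paralogous empty site
#'
#' An occupied locus `L + TSD + element + TSD + R` should reduce to the
#' empty locus `L + TSD + R` when the element and exactly one TSD copy are
#' excised. The verdict is TRUE iff such a reduction reconstructs
#' `empty_locus` exactly, with the duplicated repeat actually present on
#' both sides of the element.
#'
#' @param occupied_locus Sequence containing the element (exact match, or
#'   up to 5% mismatches).
#' @param empty_locus Candidate pre-insertion (empty-site) sequence.
#' @param element The element sequence.
#' @param min_len,max_len TSD length search range.
#' @return List: `verdict` (logical), `tsd` (the duplicated repeat, when
#'   verified), `element_start0` (0-based element offset in the occupied
#'   locus).
#' @export
verify_empty_site <- function(occupied_locus, empty_locus, element,
                              min_len = 2L, max_len = 6L) {
  occupied_locus <- toupper(occupied_locus)
  empty_locus <- toupper(empty_locus)
  element <- toupper(element)
  mm <- floor(0.05 * nchar(element))
  m <- Biostrings::matchPattern(element, occupied_locus, max.mismatch = mm)
  if (length(m) == 0L) {
    stop("element not found in occupied locus (<= 5% mismatches allowed)",
         call. = FALSE)
  }
  s <- Biostrings::start(m)[1]
  e <- Biostrings::end(m)[1]
  pre <- substr(occupied_locus, 1L, s - 1L)   # L + TSD
  post <- substr(occupied_locus, e + 1L, nchar(occupied_locus)) # TSD + R
  for (len in seq(max_len, min_len)) {
    if (nchar(pre) < len || nchar(post) < len) next
    tsd_left <- substr(pre, nchar(pre) - len + 1L, nchar(pre))
    tsd_right <- substr(post, 1L, len)
    if (tsd_left != tsd_right) next
    reconstructed <- paste0(pre, substr(post, len + 1L, nchar(post)))
    if (reconstructed == empty_locus) {
      return(list(verdict = TRUE, tsd = tsd_left, element_start0 = s - 1L))
    }
  }
  list(verdict = FALSE, tsd = NA_character_, element_start0 = s - 1L)
}

#' Extract element flanks from a genome sequence
#'
#' @param genome Genome sequence (single string).
#' @param start0,end0 Element interval, 0-based half-open.
#' @param flank_len Flank length (bp; 100 for TSD work, 500 for boundary
#'   determination).
#' @return List (`flank_pair`): `left`, `right`, `flank_len`, `at_edge`
#'   (TRUE when a flank was truncated by the contig edge).
#' @export
extract_flanks <- function(genome, start0, end0, flank_len = 100L) {
  n <- nchar(genome)
  left <- substr(genome, max(1L, start0 - flank_len + 1L), start0)
  right <- substr(genome, end0 + 1L, min(n, end0 + flank_len))
  if (!nzchar(left) || !nzchar(right)) {
    stop("empty flank: element at contig edge", call. = FALSE)
  }
  out <- list(left = left, right = right, flank_len = flank_len,
              at_edge = nchar(left) < flank_len | nchar(right) < flank_len)
  class(out) <- "flank_pair"
  out
}
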