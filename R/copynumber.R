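# Copy-number calling from homology hit tables: the length/identity
# filters, fragment-merge rules (including the stricter MITE criteria and
# the 100-bp short-subfamily gap) and the presence call.

#' Thresholds for hit filtering, fragment merging and presence calls
#'
#' Defaults are the published cutoffs: hits longer than 100 bp (strict)
#' at >= 80% identity count toward copy number; fragments under 200 bp
#' apart are one insertion (100 bp for short MITE subfamilies); an optional
#' anti-chimera rule requires >= 40% coverage of the consensus; a family is
#' called present in a species when any hit is >= 80% identical over at
#' least 300 bp.
#'
#' @param min_hit_len Minimum hit length, exclusive (bp).
#' @param min_identity Minimum percent identity, inclusive.
#' @param merge_gap Fragments closer than this are merged (bp).
#' @param alt_merge_gap Merge gap for short MITE subfamilies (bp).
#' @param min_consensus_coverage Minimum merged-call coverage of the
#'   consensus (fraction; 0 disables, 0.40 is the anti-chimera setting).
#' @param presence_min_len,presence_min_identity Presence-call thresholds.
#' @return Object of class `filter_policy`.
#' @export
filter_policy <- function(min_hit_len = 100L, min_identity = 80,
                          merge_gap = 200L, alt_merge_gap = 100L,
                          min_consensus_coverage = 0,
                          presence_min_len = 300L,
                          presence_min_identity = 80) {
  stopifnot(min_hit_len > 0, min_identity > 0, merge_gap > 0,
            alt_merge_gap > 0, min_consensus_coverage >= 0,
            presence_min_len > 0, presence_min_identity > 0)
  out <- list(min_hit_len = min_hit_len, min_identity = min_identity,
              merge_gap = merge_gap, alt_merge_gap = alt_merge_gap,
              min_consensus_coverage = min_consensus_coverage,
              presence_min_len = presence_min_len,
              presence_min_identity = presence_min_identity)
  class(out) <- "filter_policy"
  out
}

#' Filter hits for copy-number calculation
#'
#' Keeps hits with alignment length strictly greater than
#' `policy$min_hit_len` and identity at least `policy$min_identity`
#' ("more than 100 bp and 80% identity"). Order is preserved.
#'
#' @param hits Normalized hit table (see [normalize_hits()]).
#' @param policy A [filter_policy()].
#' @return Filtered hit table (possibly zero rows).
#' @export
filter_hits <- function(hits, policy = filter_policy()) {
  hits[hits$aln_len > policy$min_hit_len &
         hits$pct_identity >= policy$min_identity, , drop = FALSE]
}

#' Merge hit fragments into insertion calls
#'
#' Hits are grouped per (subject, strand) and sorted by subject start;
#' adjacent hits whose inter-interval gap (end of one to start of the
#' next, subject coordinates) is strictly less than `merge_gap` are merged
#' transitively into one call. Overlapping hits always merge.
#'
#' @param hits Filtered, normalized hit table.
#' @param policy A [filter_policy()].
#' @param merge_gap Override for the merge gap (defaults to
#'   `policy$merge_gap`).
#' @return `data.frame` of insertion calls: `subject`, `strand`, `start`,
#'   `end` (0-based half-open), `n_fragments`, `total_aln_len`,
#'   `mean_identity` (alignment-length weighted).
#' @export
merge_fragments <- function(hits, policy = filter_policy(),
                            merge_gap = NULL) {
  gap_max <- merge_gap %||% policy$merge_gap
  empty <- data.frame(subject = character(), strand = character(),
                      start = integer(), end = integer(),
                      n_fragments = integer(), total_aln_len = integer(),
                      mean_identity = numeric(), stringsAsFactors = FALSE)
  if (nrow(hits) == 0L) return(empty)
  out <- list()
  for (key in unique(paste(hits$subject, hits$strand))) {
    h <- hits[paste(hits$subject, hits$strand) == key, , drop = FALSE]
    h <- h[order(h$start, h$end), , drop = FALSE]
    cur <- h[1, , drop = FALSE]
    acc <- list(start = cur$start, end = cur$end, n = 1L,
                aln = cur$aln_len, idw = cur$pct_identity * cur$aln_len)
    flush <- function(acc) {
      data.frame(subject = cur$subject, strand = cur$strand,
                 start = acc$start, end = acc$end, n_fragments = acc$n,
                 total_aln_len = acc$aln,
                 mean_identity = acc$idw / acc$aln,
                 stringsAsFactors = FALSE)
    }
    if (nrow(h) > 1L) {
      for (i in 2:nrow(h)) {
        gap <- h$start[i] - acc$end
        if (gap < gap_max) {
          acc$end <- max(acc$end, h$end[i])
          acc$n <- acc$n + 1L
          acc$aln <- acc$aln + h$aln_len[i]
          acc$idw <- acc$idw + h$pct_identity[i] * h$aln_len[i]
        } else {
          out[[length(out) + 1L]] <- flush(acc)
          acc <- list(start = h$start[i], end = h$end[i], n = 1L,
                      aln = h$aln_len[i],
                      idw = h$pct_identity[i] * h$aln_len[i])
        }
      }
    }
    out[[length(out) + 1L]] <- flush(acc)
  }
  calls <- do.call(rbind, out)
  calls[order(calls$subject, calls$strand, calls$start), , drop = FALSE]
}

#' Drop merged calls below a consensus-coverage threshold
#'
#' The anti-chimera rule: calls whose summed alignment length covers less
#' than `policy$min_consensus_coverage` of the consensus are discarded.
#' A threshold of 0 disables the filter.
#'
#' @param calls Calls from [merge_fragments()].
#' @param consensus_len Consensus sequence length (bp, > 0).
#' @param policy A [filter_policy()].
#' @return Filtered calls with a `coverage_of_consensus` column appended.
#' @export
coverage_filter <- function(calls, consensus_len, policy = filter_policy()) {
  if (consensus_len <= 0) stop("consensus_len must be > 0", call. = FALSE)
  calls$coverage_of_consensus <- pmin(1, calls$total_aln_len / consensus_len)
  if (policy$min_consensus_coverage == 0) return(calls)
  calls[calls$coverage_of_consensus >= policy$min_consensus_coverage, ,
        drop = FALSE]
}

#' Presence/absence call for a family in one species
#'
#' TRUE iff any raw hit is at least `presence_min_identity` percent
#' identical over at least `presence_min_len` bp.
#'
#' @param hits Raw normalized hit table for one species/family.
#' @param policy A [filter_policy()].
#' @return Logical flag.
#' @export
presence_call <- function(hits, policy = filter_policy()) {
  any(hits$aln_len >= policy$presence_min_len &
        hits$pct_identity >= policy$presence_min_identity)
}

#' Copy number for a family from its hit table
#'
#' Filter, merge and (optionally) coverage-filter, then count calls.
#'
#' @param hits Normalized hit table.
#' @param consensus_len Consensus length (bp).
#' @param policy A [filter_policy()].
#' @return Integer copy number.
#' @export
count_copies <- function(hits, consensus_len, policy = filter_policy()) {
  calls <- merge_fragments(filter_hits(hits, policy), policy)
  nrow(coverage_filter(calls, consensus_len, policy))
}

#' Copy number under the stricter MITE criteria
#'
#' MITE fragments must show more than 80% identity *and* more than 80%
#' coverage of the (short) consensus; fragments are then merged with the
#' usual 200-bp gap, or the 100-bp `alt_merge_gap` when
#' `short_subfamily = TRUE` (used for the shorter of two nested MITE
#' subfamilies, where the looser gap would fuse neighbours).
#'
#' @param hits Normalized hit table.
#' @param consensus_len MITE consensus length (bp; MITEs are generally
#'   < 600 bp).
#' @param policy A [filter_policy()].
#' @param short_subfamily Use the 100-bp merge gap.
#' @return Integer copy number.
#' @export
mite_copy_number <- function(hits, consensus_len, policy = filter_policy(),
                             short_subfamily = FALSE) {
  if (consensus_len <= 0) stop("consensus_len must be > 0", call. = FALSE)
  keep <- hits$pct_identity > 80 &
    hits$aln_len / consensus_len > 0.8
  h <- hits[keep, , drop = FALSE]
  gap <- if (short_subfamily) policy$alt_merge_gap else policy$merge_gap
  nrow(merge_fragments(h, policy, merge_gap = gap))
}
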