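#' Majority-rule consensus (ancestral sequence) of an aligned TE family
#'
#' Columns whose gap fraction exceeds `max_gap_frac` are dropped (the
#' column-wise reading of "after gaps were removed"); each retained column
#' is called as its most frequent unambiguous base. Ties are broken
#' lexicographically (A < C < G < T) and flagged. A single input sequence
#' is returned as its own consensus (the best-hit rule used for low-copy
#' families), with its gap columns removed by the same rule.
#'
#' @param alignment Named character vector of equal-length aligned
#'   sequences (gaps `-`).
#' @param max_gap_frac Drop columns with gap fraction strictly greater than
#'   this (default 0.5).
#' @param family Family label stored on the result.
#' @return Object of class `consensus_model`: `family`, `column_counts`
#'   (6 x n matrix over A/C/G/T/gap/ambiguous for every input column),
#'   `consensus_seq`, `n_copies_used`, `columns_dropped`, `retained`
#'   (logical per input column), `tie_columns` (indices, input
#'   coordinates).
#' @export
majority_consensus <- function(alignment, max_gap_frac = 0.5,
                               family = "family") {
  if (length(alignment) == 0L) stop("empty alignment", call. = FALSE)
  if (length(unique(nchar(alignment))) != 1L) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(alignment), ""))
  ncol_in <- ncol(mat)
  counts <- matrix(0L, nrow = 6, ncol = ncol_in,
                   dimnames = list(c("A", "C", "G", "T", "gap", "ambiguous"),
                                   NULL))
  for (b in c("A", "C", "G", "T")) counts[b, ] <- colSums(mat == b)
  counts["gap", ] <- colSums(mat == "-" | mat == ".")
  counts["ambiguous", ] <- nrow(mat) - colSums(counts[1:5, , drop = FALSE])
  gap_frac <- counts["gap", ] / nrow(mat)
  retained <- gap_frac <= max_gap_frac
  base_counts <- counts[1:4, , drop = FALSE]
  top <- apply(base_counts, 2, max)
  n_top <- colSums(base_counts == rep(top, each = 4))
  call_base <- rownames(base_counts)[apply(base_counts, 2, which.max)]
  call_base[top == 0L] <- "N" # retained column with no unambiguous base
  tie_columns <- as.integer(which(unname(retained & n_top > 1L & top > 0L)))
  consensus_seq <- paste(call_base[retained], collapse = "")
  out <- list(family = family, column_counts = counts,
              consensus_seq = consensus_seq,
              n_copies_used = length(alignment),
              columns_dropped = sum(!retained),
              retained = retained, tie_columns = tie_columns)
  class(out) <- "consensus_model"
  out
}

#' @export
print.consensus_model <- function(x, ...) {
  cat("<consensus_model>", x$family, "\n",
      " copies:", x$n_copies_used,
      " consensus length:", nchar(x$consensus_seq),
      " columns dropped:", x$columns_dropped,
      " ties:", length(x$tie_columns), "\n")
  invisible(x)
}

#' Pairwise percent identity over unambiguous, ungapped columns
#'
#' The BioEdit-style rule: columns where either sequence has a gap or a
#' non-ACGT symbol are excluded; identity is matches over the remaining
#' columns, in percent.
#'
#' @param a,b Aligned sequences of equal length.
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b) {
  ca <- seq_chars(a)
  cb <- seq_chars(b)
  if (length(ca) != length(cb)) {
    stop("sequences must have equal aligned length", call. = FALSE)
  }
  ok <- ca %in% DNA_BASES & cb %in% DNA_BASES
  if (!any(ok)) stop("no comparable columns: identity undefined",
                     call. = FALSE)
  100 * sum(ca[ok] == cb[ok]) / sum(ok)
}

#' Symmetric pairwise-identity matrix for an alignment
#'
#' @param alignment Named character vector of equal-length sequences
#'   (>= 2).
#' @return Symmetric percent matrix with 100 on the diagonal.
#' @export
identity_matrix <- function(alignment) {
  n <- length(alignment)
  if (n < 2L) stop("need at least 2 sequences", call. = FALSE)
  ids <- names(alignment) %||% as.character(seq_len(n))
  m <- diag(100, n)
  dimnames(m) <- list(ids, ids)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- pairwise_identity(alignment[[i]], alignment[[j]])
    }
  }
  m
}
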