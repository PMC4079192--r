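#' Read sequences from a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that returns plain
#' uppercase character vectors, which is what every other function in this
#' package consumes. Input order is preserved.
#'
#' @param path Path to a FASTA file.
#' @param aligned If `TRUE`, the records are treated as a multiple alignment:
#'   all sequences must have the same length (gaps `-` allowed).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path, aligned = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA input: ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  bad <- grepl("[^A-Z*.-]", seqs)
  if (any(bad)) {
    stop("unexpected characters in record(s): ",
         paste(names(seqs)[bad], collapse = ", "), call. = FALSE)
  }
  if (aligned && length(unique(nchar(seqs))) != 1L) {
    stop("ragged alignment: sequence lengths differ (",
         paste(range(nchar(seqs)), collapse = "-"), ")", call. = FALSE)
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width (default 60 columns).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

HIT_COLS <- c("query", "subject", "pct_identity", "aln_len", "mismatches",
              "gap_opens", "qstart", "qend", "sstart", "send",
              "evalue", "bitscore")

#' Read a 12-column BLAST-style tabular hit file
#'
#' Coordinates in the file are 1-based inclusive; minus-strand hits have
#' `sstart > send`. The returned table is strand-normalized: `strand` is
#' inferred from the original subject coordinate order, and `start`/`end`
#' give the 0-based half-open subject interval with `start < end`.
#'
#' @param path Path to a tab-separated file with the 12 standard columns
#'   (query, subject, % identity, alignment length, mismatches, gap opens,
#'   qstart, qend, sstart, send, e-value, bitscore), no header.
#' @return A `data.frame` of hits with normalized coordinates (columns
#'   `strand`, `start`, `end` appended). Zero rows for an empty file.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(normalize_hits(empty_hits()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    stop("malformed hit table row at line ", which(nf != 12L)[1],
         ": expected 12 tab-separated columns, got ", nf[nf != 12L][1],
         call. = FALSE)
  }
  m <- do.call(rbind, fields)
  df <- data.frame(
    query = m[, 1], subject = m[, 2],
    pct_identity = as.numeric(m[, 3]), aln_len = as.integer(m[, 4]),
    mismatches = as.integer(m[, 5]), gap_opens = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE
  )
  num_bad <- which(!stats::complete.cases(df[, c("pct_identity", "aln_len",
                                                 "qstart", "qend",
                                                 "sstart", "send")]))
  if (length(num_bad)) {
    stop("malformed hit table row at line ", num_bad[1],
         ": non-numeric coordinate or identity field", call. = FALSE)
  }
  normalize_hits(df)
}

empty_hits <- function() {
  data.frame(query = character(), subject = character(),
             pct_identity = numeric(), aln_len = integer(),
             mismatches = integer(), gap_opens = integer(),
             qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(),
             evalue = numeric(), bitscore = numeric(),
             stringsAsFactors = FALSE)
}

#' Normalize hit coordinates to 0-based half-open, strand-aware form
#'
#' @param hits Hit `data.frame` with 1-based inclusive `sstart`/`send`.
#' @return Same table with `strand` (+/-), `start`, `end` columns; after
#'   normalization `start < end` always holds.
#' @export
normalize_hits <- function(hits) {
  hits$strand <- ifelse(hits$send >= hits$sstart, "+", "-")
  hits$start <- pmin(hits$sstart, hits$send) - 1L
  hits$end <- pmax(hits$sstart, hits$send)
  hits
}

#' Invert [normalize_hits()]: restore 1-based inclusive subject coordinates
#'
#' @param hits Normalized hit table.
#' @return Table with `sstart`/`send` rewritten from `strand`/`start`/`end`,
#'   normalization columns dropped.
#' @export
denormalize_hits <- function(hits) {
  plus <- hits$strand == "+"
  hits$sstart <- ifelse(plus, hits$start + 1L, hits$end)
  hits$send <- ifelse(plus, hits$end, hits$start + 1L)
  hits[, HIT_COLS]
}

#' Write a hit table in the 12-column BLAST tabular dialect
#'
#' @param hits Hit table (normalized or not; only the 12 standard columns
#'   are written, with 1-based inclusive coordinates).
#' @param path Output path.
#' @export
write_hit_table <- function(hits, path) {
  out <- if (all(c("strand", "start", "end") %in% names(hits))) {
    denormalize_hits(hits)
  } else {
    hits[, HIT_COLS]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

REPORT_COLS <- c("family", "species_a", "species_b", "divergence_time_years",
                 "observed_identity", "observed_ds", "expected_neutral_k",
                 "obs_over_exp", "control_gene_ds", "control_ratio", "dnds",
                 "verdict", "reasons")

#' Write a tab-separated horizontal-transfer evidence report
#'
#' One row per species pair / family, fixed column set (see
#' [classify_pair()] for field semantics). Deterministic: rewriting the
#' same bundles produces a byte-identical file.
#'
#' @param bundles List of evidence bundles from [classify_pair()] (may be
#'   empty, producing a header-only file).
#' @param path Output path.
#' @export
write_report <- function(bundles, path) {
  rows <- lapply(bundles, function(b) {
    data.frame(
      family = b$family,
      species_a = b$pair$species_a,
      species_b = b$pair$species_b,
      divergence_time_years = b$pair$divergence_time_years,
      observed_identity = b$observed_identity %||% NA_real_,
      observed_ds = b$observed_ds %||% NA_real_,
      expected_neutral_k = b$expected_neutral_k,
      obs_over_exp = b$obs_over_exp,
      control_gene_ds = b$control_gene_ds %||% NA_real_,
      control_ratio = b$control_ratio %||% NA_real_,
      dnds = b$dnds %||% NA_real_,
      verdict = b$verdict,
      reasons = paste(b$reasons, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    stats::setNames(data.frame(matrix(ncol = length(REPORT_COLS), nrow = 0)),
                    REPORT_COLS)
  utils::write.table(df[, REPORT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
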