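# Shared fixtures and independent oracles used across test files.

random_cds <- function(n_codons, seed) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  withr::with_seed(seed, paste(sample(sense, n_codons, replace = TRUE),
                               collapse = ""))
}

# random point substitutions into a CDS, never creating a stop codon
mutate_cds <- function(cds, n_subs, seed) {
  withr::with_seed(seed, {
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    done <- 0L
    while (done < n_subs) {
      i <- sample(length(codons), 1)
      pos <- sample(3, 1)
      cand <- codons[i]
      substr(cand, pos, pos) <- sample(c("A", "C", "G", "T"), 1)
      if (cand == codons[i] ||
          Biostrings::GENETIC_CODE[[cand]] == "*" ||
          Biostrings::GENETIC_CODE[[codons[i]]] == "*") next
      codons[i] <- cand
      done <- done + 1L
    }
    paste(codons, collapse = "")
  })
}

# build a normalized hit table from interval vectors
make_hits <- function(start, end, subject = "chr1", strand = "+",
                      identity = 95, qstart = 1L) {
  n <- length(start)
  aln <- end - start
  normalize_hits(data.frame(
    query = rep_len("cons", n), subject = rep_len(subject, n),
    pct_identity = rep_len(identity, n), aln_len = as.integer(aln),
    mismatches = integer(n), gap_opens = integer(n),
    qstart = rep_len(as.integer(qstart), n),
    qend = rep_len(as.integer(qstart), n) + as.integer(aln) - 1L,
    sstart = as.integer(ifelse(rep_len(strand, n) == "+", start + 1L, end)),
    send = as.integer(ifelse(rep_len(strand, n) == "+", end, start + 1L)),
    evalue = numeric(n), bitscore = numeric(n), stringsAsFactors = FALSE))
}

# brute-force O(n^2) transitive-closure merge oracle: hits are nodes, an
# edge joins two hits on the same (subject, strand) whose subject-interval
# gap is < gap_max (overlap counts); calls are connected components
closure_merge_oracle <- function(hits, gap_max) {
  n <- nrow(hits)
  if (n == 0) return(data.frame(subject = character(), strand = character(),
                                start = integer(), end = integer(),
                                n_fragments = integer()))
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      same <- hits$subject[i] == hits$subject[j] &&
        hits$strand[i] == hits$strand[j]
      gap <- max(hits$start[i], hits$start[j]) -
        min(hits$end[i], hits$end[j])
      adj[i, j] <- same && gap < gap_max
    }
  }
  # transitive closure by repeated boolean multiplication
  repeat {
    nxt <- adj | (adj %*% adj > 0)
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1L
      comp[which(adj[i, ])] <- cid
    }
  }
  rows <- lapply(split(seq_len(n), comp), function(ix) {
    data.frame(subject = hits$subject[ix[1]], strand = hits$strand[ix[1]],
               start = min(hits$start[ix]), end = max(hits$end[ix]),
               n_fragments = length(ix), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

expect_calls_equal_oracle <- function(hits, gap_max) {
  got <- merge_fragments(hits, merge_gap = gap_max)
  want <- closure_merge_oracle(hits, gap_max)
  rownames(got) <- NULL
  expect_equal(got[, c("subject", "strand", "start", "end", "n_fragments")],
               want)
}
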