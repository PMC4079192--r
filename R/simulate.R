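# Synthetic-data generator: master elements, amplification bursts under a
# Kimura 2-parameter process, TSD-bearing genomic insertions, and coding
# pairs with prescribed synonymous/nonsynonymous divergence. Every
# downstream module has parameter-recovery tests against this ground truth.

#' Generate a random master (ancestral) transposon element
#'
#' The element carries the hallmarks of CMC-superfamily DNA transposons:
#' terminal inverted repeats with invariant 5'-CAC ... GTG-3' termini, a
#' short target-site-duplication motif (default the 3-bp `TWA` observed for
#' Chapaev-like elements), and a nominal coding interval.
#'
#' @param length Total element length in bp (>= 60).
#' @param tsd_len TSD length in bp (2-6).
#' @param seed Integer seed; output is deterministic given the seed.
#' @param tsd_motif IUPAC motif of length `tsd_len` (default "TWA" when
#'   `tsd_len = 3`, otherwise "T" followed by Ns).
#' @param name Element name.
#' @return An object of class `master_element`: list with `name`,
#'   `sequence`, `tir_5`, `tir_3`, `cds_intervals` (0-based half-open),
#'   `tsd_len`, `tsd_motif`.
#' @export
generate_master <- function(length, tsd_len = 3L, seed = 1L,
                            tsd_motif = NULL, name = "master") {
  if (length < 60L) stop("element length must be >= 60 bp", call. = FALSE)
  if (!(tsd_len %in% 2:6)) stop("tsd_len must be in 2..6", call. = FALSE)
  if (is.null(tsd_motif)) {
    tsd_motif <- if (tsd_len == 3L) "TWA" else
      paste0("T", strrep("N", tsd_len - 1L))
  }
  if (nchar(tsd_motif) != tsd_len) {
    stop("tsd_motif length must equal tsd_len", call. = FALSE)
  }
  tir_len <- min(15L, length %/% 4L)
  with_seed(seed, {
    tir_5 <- paste0("CAC", random_dna(tir_len - 3L))
    tir_3 <- revcomp(tir_5) # inverted repeat; ends "...GTG" by construction
    core <- random_dna(length - 2L * tir_len)
    sequence <- paste0(tir_5, core, tir_3)
    # nominal single-ORF coding interval in the element interior (0-based,
    # half-open, length a multiple of 3); plumbing for coverage bookkeeping
    cds_start <- tir_len + 3L
    cds_len <- 3L * max(1L, ((length - 2L * tir_len - 6L) %/% 3L) %/% 2L)
    el <- list(
      name = name,
      sequence = sequence,
      tir_5 = tir_5,
      tir_3 = tir_3,
      cds_intervals = list(c(cds_start, cds_start + cds_len)),
      tsd_len = as.integer(tsd_len),
      tsd_motif = tsd_motif
    )
    class(el) <- "master_element"
    el
  })
}

#' @export
print.master_element <- function(x, ...) {
  cat("<master_element>", x$name, "\n",
      " length:", nchar(x$sequence), "bp",
      " TIR:", x$tir_5, "...", x$tir_3, "\n",
      " TSD:", x$tsd_len, "bp motif", x$tsd_motif, "\n")
  invisible(x)
}

#' Describe an amplification burst to simulate
#'
#' @param burst_age_years Age of the burst (years, >= 0).
#' @param rate_per_site_year Neutral substitution rate r
#'   (substitutions/site/year, > 0).
#' @param n_copies Number of copies to emit (>= 1).
#' @param kappa Transition/transversion rate ratio R = alpha/(2 beta);
#'   `kappa = 0.5` means all substitution rates equal. Default 2.
#' @param fragment_prob Probability that a copy is truncated (5' or 3' end
#'   chosen uniformly).
#' @param seed Integer seed.
#' @return Object of class `burst_truth`.
#' @export
burst_truth <- function(burst_age_years, rate_per_site_year, n_copies,
                        kappa = 2, fragment_prob = 0, seed = 1L) {
  stopifnot(burst_age_years >= 0, rate_per_site_year > 0, n_copies >= 1,
            kappa > 0, fragment_prob >= 0, fragment_prob <= 1)
  out <- list(burst_age_years = burst_age_years,
              rate_per_site_year = rate_per_site_year,
              n_copies = as.integer(n_copies), kappa = kappa,
              fragment_prob = fragment_prob, seed = as.integer(seed))
  class(out) <- "burst_truth"
  out
}

# K2P category probabilities after d expected substitutions/site.
# alpha + 2 beta = 1 per unit distance, kappa = alpha / (2 beta).
k2p_site_probs <- function(d, kappa) {
  beta <- 1 / (2 * (kappa + 1))
  alpha <- kappa / (kappa + 1)
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  p_tv <- 0.5 - 0.5 * exp(-4 * beta * d) # total over both transversions
  c(same = 1 - p_ts - p_tv, ts = p_ts, tv = p_tv)
}

TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

# mutate one sequence to an expected K2P distance d (independent sites)
mutate_k2p <- function(sequence, d, kappa) {
  chars <- seq_chars(sequence)
  n <- length(chars)
  pr <- k2p_site_probs(d, kappa)
  cat_draw <- sample.int(3L, n, replace = TRUE, prob = pr)
  ts_idx <- which(cat_draw == 2L)
  tv_idx <- which(cat_draw == 3L)
  if (length(ts_idx)) chars[ts_idx] <- TS_PARTNER[chars[ts_idx]]
  if (length(tv_idx)) {
    pick <- sample.int(2L, length(tv_idx), replace = TRUE)
    chars[tv_idx] <- mapply(function(b, k) TV_PARTNERS[[b]][k],
                            chars[tv_idx], pick)
  }
  paste(chars, collapse = "")
}

#' Simulate a single-burst transposon family from a master element
#'
#' Each copy diverges independently from the master with expected per-site
#' substitutions `k* = 2 r T` (copy-vs-master divergence absorbs both
#' lineages, matching the `T = k/2r` dating convention downstream) under a
#' K2P process. With probability `fragment_prob` a copy is truncated from a
#' uniformly chosen end, retaining a uniform 10-90% of its length.
#'
#' @param master A `master_element`.
#' @param truth A `burst_truth`.
#' @return List with `copies` (named character vector) and `truth`, a
#'   `data.frame` with per-copy `id`, `qstart`, `qend` (1-based inclusive
#'   master coordinates retained), `fragmented`, `k_expected`.
#' @export
simulate_family <- function(master, truth) {
  stopifnot(inherits(master, "master_element"), inherits(truth, "burst_truth"))
  d <- 2 * truth$rate_per_site_year * truth$burst_age_years
  if (d >= 0.74) {
    warning("expected divergence k* = ", signif(d, 3),
            " is near the K2P saturation ceiling; dating will be unreliable",
            call. = FALSE)
  }
  L <- nchar(master$sequence)
  with_seed(truth$seed, {
    ids <- sprintf("%s_copy%03d", master$name, seq_len(truth$n_copies))
    copies <- character(truth$n_copies)
    qstart <- rep(1L, truth$n_copies)
    qend <- rep(L, truth$n_copies)
    fragmented <- logical(truth$n_copies)
    for (i in seq_len(truth$n_copies)) {
      s <- mutate_k2p(master$sequence, d, truth$kappa)
      if (stats::runif(1) < truth$fragment_prob) {
        keep <- max(1L, round(stats::runif(1, 0.1, 0.9) * L))
        if (stats::runif(1) < 0.5) { # truncate 3' end
          qstart[i] <- 1L; qend[i] <- keep
        } else {                     # truncate 5' end
          qstart[i] <- L - keep + 1L; qend[i] <- L
        }
        s <- substr(s, qstart[i], qend[i])
        fragmented[i] <- TRUE
      }
      copies[i] <- s
    }
    names(copies) <- ids
    list(copies = copies,
         truth = data.frame(id = ids, qstart = qstart, qend = qend,
                            fragmented = fragmented, k_expected = d,
                            stringsAsFactors = FALSE))
  })
}

#' Pad simulated copies back onto master coordinates
#'
#' The burst simulator introduces substitutions only, so a truncated copy
#' aligns to the master gap-free at its recorded offset; this rebuilds the
#' implied multiple alignment (gaps for truncated ends) without running an
#' aligner.
#'
#' @param copies Named copies from [simulate_family()].
#' @param truth Matching truth table.
#' @param master_length Master length in bp.
#' @return Named character vector, all of length `master_length`.
#' @export
align_copies_to_master <- function(copies, truth, master_length) {
  out <- vapply(seq_along(copies), function(i) {
    paste0(strrep("-", truth$qstart[i] - 1L),
           copies[i],
           strrep("-", master_length - truth$qend[i]))
  }, character(1))
  names(out) <- names(copies)
  out
}

#' Plant copies into a random background genome with TSDs
#'
#' Each insertion overwrites `tsd_len` background bases with a draw from the
#' master's TSD motif and duplicates it on the element's 3' side, emulating
#' target-site duplication upon insertion. With `flank_bias = TRUE` the base
#' immediately 5' of the left TSD is forced to `A` and the base immediately
#' 3' of the right TSD to `T`, the insertion-context bias seen for
#' Chapaev-like elements.
#'
#' @param copies Character vector of copy sequences (may be empty).
#' @param genome_length Background genome length in bp (before insertion).
#' @param master The `master_element` the copies derive from.
#' @param seed Integer seed.
#' @param flank_bias Emulate the A...T insertion-context bias (default TRUE).
#' @param truth Optional truth table from [simulate_family()] giving master
#'   coordinates per copy (used for the emitted hit table); full-length
#'   copies assumed when absent.
#' @param chrom Name of the simulated chromosome.
#' @return List with `genome` (single character string), `loci` (one row per
#'   insertion: `chrom`, `start0`, `end0` 0-based half-open element
#'   coordinates, `tsd`, `left_flank`, `right_flank`, `inserted_copy`) and
#'   `hits`, a normalized 12-column-style truth hit table (query = master).
#' @export
plant_insertions <- function(copies, genome_length, master, seed = 1L,
                             flank_bias = TRUE, truth = NULL,
                             chrom = "chr1") {
  tsd_len <- master$tsd_len
  n <- length(copies)
  margin <- 150L
  min_gap <- 250L
  if (n > 0) {
    need <- 2L * margin + (n - 1L) * min_gap + tsd_len + 2L
    if (genome_length < need) {
      stop("genome capacity exceeded: need at least ", need,
           " bp of background for ", n, " insertions", call. = FALSE)
    }
  }
  if (is.null(truth) && n > 0) {
    truth <- data.frame(id = names(copies) %||% sprintf("copy%03d", seq_len(n)),
                        qstart = 1L, qend = nchar(copies),
                        stringsAsFactors = FALSE)
  }
  with_seed(seed, {
    bg <- sample(DNA_BASES, genome_length, replace = TRUE)
    if (n == 0) {
      return(list(genome = paste(bg, collapse = ""),
                  loci = data.frame(chrom = character(), start0 = integer(),
                                    end0 = integer(), tsd = character(),
                                    left_flank = character(),
                                    right_flank = character(),
                                    inserted_copy = character(),
                                    stringsAsFactors = FALSE),
                  hits = normalize_hits(empty_hits())))
    }
    # TSD start positions in background coordinates, spaced >= min_gap
    pts <- NULL
    for (try in 1:200) {
      cand <- sort(sample(margin:(genome_length - margin - tsd_len), n))
      if (n == 1L || min(diff(cand)) >= min_gap) { pts <- cand; break }
    }
    if (is.null(pts)) {
      pts <- round(seq(margin, genome_length - margin - tsd_len,
                       length.out = n))
    }
    tsds <- vapply(seq_len(n), function(i) sample_motif(master$tsd_motif),
                   character(1))
    for (i in seq_len(n)) {
      p <- pts[i]
      bg[p:(p + tsd_len - 1L)] <- seq_chars(tsds[i])
      if (flank_bias) {
        bg[p - 1L] <- "A"
        bg[p + tsd_len] <- "T"
      }
    }
    # assemble: ... left-bg .. TSD | element + TSD | .. right-bg ...
    pieces <- character(0)
    loci_start0 <- integer(n)
    offset <- 0L # cumulative inserted length so far
    prev <- 1L
    for (i in seq_len(n)) {
      p <- pts[i]
      pieces <- c(pieces,
                  paste(bg[prev:(p + tsd_len - 1L)], collapse = ""),
                  copies[i], tsds[i])
      loci_start0 <- replace(loci_start0, i, p + tsd_len - 1L + offset)
      offset <- offset + nchar(copies[i]) + tsd_len
      prev <- p + tsd_len
    }
    pieces <- c(pieces, paste(bg[prev:genome_length], collapse = ""))
    genome <- paste(pieces, collapse = "")
    end0 <- loci_start0 + nchar(copies)
    flank <- 100L
    loci <- data.frame(
      chrom = chrom, start0 = loci_start0, end0 = end0, tsd = tsds,
      left_flank = substring(genome, pmax(1L, loci_start0 - flank + 1L),
                             loci_start0),
      right_flank = substring(genome, end0 + 1L, end0 + flank),
      inserted_copy = unname(copies),
      stringsAsFactors = FALSE
    )
    # truth hit table: one row per planted fragment vs the master
    ident <- mismatch <- numeric(n)
    for (i in seq_len(n)) {
      ref <- seq_chars(substr(master$sequence, truth$qstart[i], truth$qend[i]))
      obs <- seq_chars(copies[i])
      mismatch[i] <- sum(ref != obs)
      ident[i] <- 100 * (1 - mismatch[i] / length(obs))
    }
    hits <- data.frame(
      query = master$name, subject = chrom,
      pct_identity = round(ident, 2), aln_len = nchar(copies),
      mismatches = as.integer(mismatch), gap_opens = 0L,
      qstart = truth$qstart, qend = truth$qend,
      sstart = loci_start0 + 1L, send = end0,
      evalue = 0, bitscore = round(2 * nchar(copies), 1),
      stringsAsFactors = FALSE
    )
    list(genome = genome, loci = loci, hits = normalize_hits(hits))
  })
}

#' Simulate a coding-sequence pair with target ds and dn
#'
#' Introduces strictly synonymous and strictly nonsynonymous single-base
#' substitutions (at most one per codon, never creating a stop) into a copy
#' of `cds` by rejection sampling, until the package's own Nei-Gojobori
#' estimator ([ng_divergence()]) is within 10% of each target.
#'
#' @param cds In-frame coding sequence, length divisible by 3, no internal
#'   stop codons.
#' @param target_ds,target_dn Target synonymous / nonsynonymous divergences
#'   (each must be 0 or reachable below the Jukes-Cantor ceiling 0.74).
#' @param seed Integer seed.
#' @param max_attempts Proposal budget before giving up.
#' @return List with `cds_a` (= `cds`), `cds_b`, and the achieved `ds`,
#'   `dn`.
#' @export
simulate_coding_pair <- function(cds, target_ds, target_dn, seed = 1L,
                                 max_attempts = 20000L) {
  cds <- toupper(cds)
  codons <- split_codons(cds)
  if (any(is_stop_codon(codons[-length(codons)]))) {
    stop("internal stop codon in input CDS", call. = FALSE)
  }
  if (target_ds >= 0.74 || target_dn >= 0.74) {
    stop("target divergence beyond the Jukes-Cantor ceiling (0.74)",
         call. = FALSE)
  }
  if (target_ds < 0 || target_dn < 0) stop("targets must be >= 0",
                                           call. = FALSE)
  with_seed(seed, {
    b <- codons
    touched <- rep(FALSE, length(codons))
    # skip stop codons (terminal) entirely
    touched[is_stop_codon(codons)] <- TRUE
    est <- list(ds = 0, dn = 0)
    fill <- function(target, current, want_syn) {
      attempts <- 0L
      while (current < 0.9 * target && attempts < max_attempts) {
        attempts <- attempts + 1L
        open <- which(!touched)
        if (!length(open)) break
        i <- open[sample.int(length(open), 1L)]
        pos <- sample.int(3L, 1L)
        cur <- b[[i]]
        base <- substr(cur, pos, pos)
        alt <- sample(setdiff(DNA_BASES, base), 1L)
        cand <- cur
        substr(cand, pos, pos) <- alt
        if (is_stop_codon(cand)) next
        syn <- translate_codon(cand) == translate_codon(cur)
        if (syn != want_syn) next
        b_try <- b
        b_try[[i]] <- cand
        est_try <- ng_divergence(cds, paste(b_try, collapse = ""))
        new_val <- if (want_syn) est_try$ds else est_try$dn
        # achievable values form a lattice (integer difference counts);
        # never step past the closest achievable point to the target
        if (new_val > 1.1 * target &&
            abs(new_val - target) > abs(current - target)) break
        b[[i]] <<- cand
        touched[i] <<- TRUE
        est <<- est_try
        current <- new_val
      }
      current
    }
    got_dn <- fill(target_dn, 0, want_syn = FALSE)
    got_ds <- fill(target_ds, 0, want_syn = TRUE)
    ok_ds <- target_ds == 0 || abs(got_ds - target_ds) <= 0.1 * target_ds
    ok_dn <- target_dn == 0 || abs(got_dn - target_dn) <= 0.1 * target_dn
    if (!ok_ds || !ok_dn) {
      stop("could not reach target divergences (got ds = ",
           signif(got_ds, 4), ", dn = ", signif(got_dn, 4), ")",
           call. = FALSE)
    }
    list(cds_a = cds, cds_b = paste(b, collapse = ""),
         ds = got_ds, dn = got_dn)
  })
}
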