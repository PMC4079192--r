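# Purifying-selection controls: codon back-translation, Nei-Gojobori
# ds/dn (unweighted pathway method with Jukes-Cantor correction, the
# SNAP-style estimator), pairwise dn/ds profiles, and Wright's effective
# number of codons (Nc).

# fraction of the three possible changes at each position that are
# synonymous; mutations to stop codons count as nonsynonymous, so
# syn + nonsyn sites = 3 per codon exactly
codon_syn_sites <- function(codon) {
  aa <- translate_codon(codon)
  syn <- 0
  for (pos in 1:3) {
    base <- substr(codon, pos, pos)
    for (alt in setdiff(DNA_BASES, base)) {
      mut <- codon
      substr(mut, pos, pos) <- alt
      maa <- translate_codon(mut)
      if (!is.na(maa) && maa != "*" && maa == aa) syn <- syn + 1
    }
  }
  syn / 3
}

# average synonymous / nonsynonymous difference counts over all orderings
# of single-step pathways between two codons; pathways through stop codons
# are excluded; returns NULL when every pathway is stop-routed
codon_path_diffs <- function(c1, c2) {
  pos <- which(seq_chars(c1) != seq_chars(c2))
  nd <- length(pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(pos) else {
    if (nd == 2L) list(pos, rev(pos)) else {
      # nd == 3: all 6 orderings
      do.call(c, lapply(seq_len(3), function(i) {
        rest <- pos[-i]
        list(c(pos[i], rest), c(pos[i], rev(rest)))
      }))
    }
  }
  tot_syn <- tot_non <- 0
  n_valid <- 0L
  for (ord in perms) {
    cur <- c1
    syn <- non <- 0
    valid <- TRUE
    for (p in ord) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (is_stop_codon(nxt)) { valid <- FALSE; break }
      if (translate_codon(nxt) == translate_codon(cur)) syn <- syn + 1
      else non <- non + 1
      cur <- nxt
    }
    if (valid) {
      tot_syn <- tot_syn + syn
      tot_non <- tot_non + non
      n_valid <- n_valid + 1L
    }
  }
  if (n_valid == 0L) return(NULL)
  c(syn = tot_syn / n_valid, nonsyn = tot_non / n_valid)
}

jc_correct <- function(p, what) {
  if (p >= 0.75) {
    stop("Jukes-Cantor saturation on the ", what,
         " class (p = ", signif(p, 4), " >= 0.75)", call. = FALSE)
  }
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori ds, dn and dn/ds for a codon-aligned pair
#'
#' Unweighted pathway counting over all orderings of single-step
#' substitutions (pathways through stop codons excluded; codon pairs with
#' no valid pathway are skipped and recorded), site counts averaged over
#' the two sequences, proportions corrected by the Jukes-Cantor formula
#' `d = -3/4 log(1 - 4p/3)`. Codons containing gaps or ambiguity codes in
#' either sequence, and stop codons, are excluded pairwise.
#'
#' @param a,b In-frame codon-aligned CDS strings of equal length.
#' @return List (`selection_result`): `ds`, `dn`, `ratio` (NA with
#'   `ratio_undefined = TRUE` when ds = 0), `syn_sites`, `nonsyn_sites`,
#'   `syn_diffs`, `nonsyn_diffs`, `n_codons` (compared),
#'   `skipped_codons` (indices with no stop-free pathway).
#' @export
ng_divergence <- function(a, b) {
  ca <- split_codons(a)
  cb <- split_codons(b)
  if (length(ca) != length(cb)) {
    stop("codon alignments must have equal length", call. = FALSE)
  }
  clean <- function(x) grepl("^[ACGT]{3}$", x)
  usable <- clean(ca) & clean(cb) & !is_stop_codon(ca) & !is_stop_codon(cb)
  idx <- which(usable)
  if (length(idx) == 0L) stop("no comparable codons", call. = FALSE)
  S1 <- S2 <- Sd <- Nd <- 0
  skipped <- integer(0)
  for (i in idx) {
    diffs <- codon_path_diffs(ca[i], cb[i])
    if (is.null(diffs)) { skipped <- c(skipped, i); next }
    S1 <- S1 + codon_syn_sites(ca[i])
    S2 <- S2 + codon_syn_sites(cb[i])
    Sd <- Sd + diffs[["syn"]]
    Nd <- Nd + diffs[["nonsyn"]]
  }
  n_codons <- length(idx) - length(skipped)
  if (n_codons == 0L) stop("no comparable codons", call. = FALSE)
  S <- (S1 + S2) / 2
  N <- 3 * n_codons - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  ds <- jc_correct(ps, "synonymous")
  dn <- jc_correct(pn, "nonsynonymous")
  out <- list(ds = ds, dn = dn,
              ratio = if (ds > 0) dn / ds else NA_real_,
              ratio_undefined = ds == 0,
              syn_sites = S, nonsyn_sites = N,
              syn_diffs = Sd, nonsyn_diffs = Nd,
              n_codons = n_codons, skipped_codons = skipped)
  class(out) <- "selection_result"
  out
}

#' Back-translate a protein alignment onto coding sequences
#'
#' Expands each amino-acid column of the protein alignment into the codon
#' triple from the matching CDS (gaps become `---`), after checking that
#' each CDS translates exactly to its ungapped protein row (a terminal
#' stop codon on the CDS is tolerated and dropped).
#'
#' @param protein_aln Named character vector: aligned amino-acid rows.
#' @param cds_records Named character vector of unaligned CDS, names
#'   matching `protein_aln`.
#' @return Named character vector: the codon alignment.
#' @export
backtranslate_alignment <- function(protein_aln, cds_records) {
  missing <- setdiff(names(protein_aln), names(cds_records))
  if (length(missing)) {
    stop("no CDS for row(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- vapply(names(protein_aln), function(id) {
    prot <- toupper(protein_aln[[id]])
    cds <- toupper(cds_records[[id]])
    codons <- split_codons(cds)
    if (length(codons) > 0L && is_stop_codon(codons[length(codons)])) {
      codons <- codons[-length(codons)]
    }
    trans <- translate_codon(codons)
    bare <- gsub("-", "", prot, fixed = TRUE)
    if (length(trans) != nchar(bare) ||
        any(trans != strsplit(bare, "")[[1]])) {
      bad <- if (length(trans) != nchar(bare)) "length" else
        paste0("position ", which(trans != strsplit(bare, "")[[1]])[1])
      stop("CDS does not translate to protein row '", id, "' (", bad, ")",
           call. = FALSE)
    }
    j <- 0L
    paste(vapply(strsplit(prot, "")[[1]], function(aa) {
      if (aa == "-") "---" else { j <<- j + 1L; codons[j] }
    }, character(1)), collapse = "")
  }, character(1))
  names(out) <- names(protein_aln)
  out
}

#' All-pairs ds/dn table for a codon alignment
#'
#' @param codon_aln Named character vector (>= 2 rows) of codon-aligned
#'   CDS.
#' @return `data.frame`, one row per unordered pair: `id_a`, `id_b`, `ds`,
#'   `dn`, `dnds` (NA when undefined), `ratio_undefined`.
#' @export
dnds_profile <- function(codon_aln) {
  n <- length(codon_aln)
  if (n < 2L) stop("need at least 2 rows", call. = FALSE)
  ids <- names(codon_aln) %||% as.character(seq_len(n))
  rows <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      r <- ng_divergence(codon_aln[[i]], codon_aln[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        id_a = ids[i], id_b = ids[j], ds = r$ds, dn = r$dn,
        dnds = r$ratio, ratio_undefined = r$ratio_undefined,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# amino-acid families of the standard code by synonymous-codon count;
# 1-codon families (Met, Trp) enter Nc as the constant 2
codon_families <- function() {
  code <- Biostrings::GENETIC_CODE
  code <- code[code != "*"]
  split(names(code), code)
}

#' Wright's effective number of codons (Nc)
#'
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`, with the mean codon
#' homozygosity `F = (n * sum(p_i^2) - 1) / (n - 1)` averaged within each
#' degeneracy class (2-, 3-, 4-, 6-fold). Families with fewer than two
#' observed codons do not contribute; a class with no contributing family
#' is filled in by Wright's fallback (F3 as the mean of F2 and F4, other
#' classes as the mean of the observed classes). Nc is clamped to
#' `[20, 61]`. Stop codons and codons with ambiguity are excluded from the
#' counts.
#'
#' @param cds In-frame CDS string (length divisible by 3).
#' @return List (`codon_usage_result`): `nc`, `f_by_class` (named, classes
#'   "2","3","4","6"), `counts` (named codon counts over the 61 sense
#'   codons), `n_codons`.
#' @export
effective_number_of_codons <- function(cds) {
  codons <- split_codons(cds)
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  codons <- codons[!is_stop_codon(codons)]
  fams <- codon_families()
  sense <- unlist(fams, use.names = FALSE)
  counts <- table(factor(codons, levels = sense))
  fam_F <- lapply(fams, function(members) {
    n <- sum(counts[members])
    if (n < 2) return(NULL)
    p <- as.numeric(counts[members]) / n
    list(F = (n * sum(p^2) - 1) / (n - 1), size = length(members))
  })
  fam_F <- Filter(Negate(is.null), fam_F)
  class_of <- vapply(fam_F, `[[`, numeric(1), "size")
  Fv <- vapply(fam_F, `[[`, numeric(1), "F")
  class_mean <- vapply(c(2, 3, 4, 6), function(k) {
    v <- Fv[class_of == k]
    v <- v[v > 1e-9] # F = 0 families carry no usable information
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  names(class_mean) <- c("2", "3", "4", "6")
  observed <- class_mean[!is.na(class_mean)]
  if (length(observed) == 0L) {
    stop("Nc undefined: no degeneracy class has a family with >= 2 codons",
         call. = FALSE)
  }
  if (is.na(class_mean[["3"]])) {
    f2 <- class_mean[["2"]]; f4 <- class_mean[["4"]]
    class_mean[["3"]] <- if (!is.na(f2) && !is.na(f4)) mean(c(f2, f4)) else
      mean(observed)
  }
  for (k in c("2", "4", "6")) {
    if (is.na(class_mean[[k]])) class_mean[[k]] <- mean(observed)
  }
  nc <- 2 + 9 / class_mean[["2"]] + 1 / class_mean[["3"]] +
    5 / class_mean[["4"]] + 3 / class_mean[["6"]]
  out <- list(nc = min(61, max(20, nc)), f_by_class = class_mean,
              counts = counts, n_codons = length(codons))
  class(out) <- "codon_usage_result"
  out
}
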