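# Horizontal-transfer inference: neutral divergence expectation for a host
# species pair, the evidence-combining verdict (divergence ratio,
# housekeeping-gene control, purifying-selection check), and the
# star-phylogeny burst diagnostic on copy trees.

#' Describe a host species pair
#'
#' @param species_a,species_b Species labels.
#' @param divergence_time_years Host split time (years, > 0).
#' @param rate_a,rate_b Lineage-specific neutral substitution rates
#'   (substitutions/site/year, > 0); `rate_b` defaults to `rate_a`.
#' @return Object of class `species_pair`.
#' @export
species_pair <- function(species_a, species_b, divergence_time_years,
                         rate_a, rate_b = rate_a) {
  stopifnot(divergence_time_years >= 0, rate_a > 0, rate_b > 0)
  out <- list(species_a = species_a, species_b = species_b,
              divergence_time_years = divergence_time_years,
              rate_a = rate_a, rate_b = rate_b)
  class(out) <- "species_pair"
  out
}

#' Expected neutral divergence for a species pair
#'
#' Under vertical inheritance a sequence present in the common ancestor
#' accumulates `rate_a * T` substitutions/site on one lineage and
#' `rate_b * T` on the other, so the expected between-species distance is
#' `(rate_a + rate_b) * T` (the `T = k/2r` dating formula inverted).
#'
#' @param pair A [species_pair()].
#' @return Expected substitutions/site (float).
#' @export
expected_divergence <- function(pair) {
  stopifnot(inherits(pair, "species_pair"))
  (pair$rate_a + pair$rate_b) * pair$divergence_time_years
}

#' Verdict thresholds for the HT classification
#'
#' @param ht_ratio Observed/expected divergence below this supports HT
#'   (default 0.5).
#' @param vertical_floor Observed/expected at or above this is consistent
#'   with vertical inheritance (default 0.8).
#' @param control_factor Required fold-excess of the housekeeping-gene
#'   control ds over the element ds (default 10, the "at least ten times
#'   higher" control).
#' @param purifying_floor Minimum dn/ds regarded as absence of strong
#'   purifying selection (default 0.2).
#' @return Named list of thresholds.
#' @export
ht_thresholds <- function(ht_ratio = 0.5, vertical_floor = 0.8,
                          control_factor = 10, purifying_floor = 0.2) {
  list(ht_ratio = ht_ratio, vertical_floor = vertical_floor,
       control_factor = control_factor, purifying_floor = purifying_floor)
}

#' Classify a family/species-pair as HT-supported or vertical-consistent
#'
#' The quantitative core of the evidence chain: the observed
#' element divergence (ds when available, else a K2P distance) is compared
#' with the neutral expectation for the host split time. A verdict of
#' `"HT-supported"` requires (i) observed/expected below
#' `thresholds$ht_ratio`, (ii) when a housekeeping-gene control is
#' supplied, control ds at least `control_factor` times the element ds,
#' and (iii) when dn/ds is supplied, no strong purifying signal
#' (dn/ds >= `purifying_floor`). Observed/expected at or above
#' `vertical_floor` yields `"vertical-consistent"`; anything else is
#' `"indeterminate"`. Every rule consulted is recorded in `reasons`.
#'
#' @param pair A [species_pair()].
#' @param family Family label.
#' @param observed_ds Element synonymous divergence between the two
#'   species' consensus sequences (drives the ratio test when present).
#' @param observed_k Element K2P distance (fallback when `observed_ds` is
#'   absent).
#' @param observed_identity Percent identity (reported, not thresholded).
#' @param control_gene_ds Housekeeping-gene (e.g. EF-1a) ds for the same
#'   species pair, optional.
#' @param dnds Element dn/ds, optional.
#' @param thresholds See [ht_thresholds()].
#' @return Object of class `evidence_bundle` with fields `family`, `pair`,
#'   `observed_identity`, `observed_ds`, `expected_neutral_k`,
#'   `obs_over_exp`, `control_gene_ds`, `control_ratio`, `dnds`,
#'   `verdict`, `reasons`.
#' @export
classify_pair <- function(pair, family = "family",
                          observed_ds = NULL, observed_k = NULL,
                          observed_identity = NULL,
                          control_gene_ds = NULL, dnds = NULL,
                          thresholds = ht_thresholds()) {
  if (!inherits(pair, "species_pair")) {
    stop("missing or invalid species pair configuration", call. = FALSE)
  }
  obs <- observed_ds %||% observed_k
  if (is.null(obs)) {
    stop("need observed_ds or observed_k", call. = FALSE)
  }
  expected <- expected_divergence(pair)
  ratio <- if (expected > 0) obs / expected else Inf
  reasons <- sprintf("obs_over_exp=%.4g", ratio)
  low_div <- ratio < thresholds$ht_ratio
  reasons <- c(reasons, sprintf("divergence_ratio_%s_ht_threshold_%.2g",
                                if (low_div) "below" else "not_below",
                                thresholds$ht_ratio))
  control_ratio <- NULL
  control_ok <- TRUE
  if (!is.null(control_gene_ds) && !is.null(observed_ds)) {
    control_ratio <- if (observed_ds > 0) control_gene_ds / observed_ds else
      Inf
    control_ok <- control_ratio >= thresholds$control_factor
    reasons <- c(reasons, sprintf("control_ratio=%.4g_%s_%g",
                                  control_ratio,
                                  if (control_ok) "meets" else "fails",
                                  thresholds$control_factor))
  }
  selection_ok <- TRUE
  if (!is.null(dnds) && !is.na(dnds)) {
    selection_ok <- dnds >= thresholds$purifying_floor
    reasons <- c(reasons, sprintf("dnds=%.4g_%s_purifying_floor_%.2g",
                                  dnds,
                                  if (selection_ok) "above" else "below",
                                  thresholds$purifying_floor))
  }
  verdict <- if (low_div && control_ok && selection_ok) {
    "HT-supported"
  } else if (ratio >= thresholds$vertical_floor) {
    "vertical-consistent"
  } else {
    "indeterminate"
  }
  out <- list(family = family, pair = pair,
              observed_identity = observed_identity,
              observed_ds = observed_ds,
              expected_neutral_k = expected, obs_over_exp = ratio,
              control_gene_ds = control_gene_ds,
              control_ratio = control_ratio, dnds = dnds,
              verdict = verdict, reasons = reasons)
  class(out) <- "evidence_bundle"
  out
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat("<evidence_bundle>", x$family, ":", x$pair$species_a, "vs",
      x$pair$species_b, "\n",
      " obs/exp divergence:", signif(x$obs_over_exp, 4),
      " verdict:", x$verdict, "\n")
  invisible(x)
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Classic neighbor-joining (via [ape::nj()]); any negative branch length
#' is clamped to zero with the deficit moved onto its sister branch so
#' path lengths are approximately preserved.
#'
#' @param d Symmetric non-negative distance matrix (or `dist`), >= 3 taxa.
#' @return An [ape] `phylo` tree (unrooted).
#' @export
nj_tree <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 3L) stop("need at least 3 taxa", call. = FALSE)
  tree <- ape::nj(m)
  for (pass in 1:10) {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    for (e in neg) {
      parent <- tree$edge[e, 1]
      sisters <- setdiff(which(tree$edge[, 1] == parent), e)
      if (length(sisters)) {
        tree$edge.length[sisters[1]] <-
          tree$edge.length[sisters[1]] + tree$edge.length[e]
      }
      tree$edge.length[e] <- 0
    }
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Star-likeness of a copy tree
#'
#' `1 - (sum of internal branch lengths / total branch length)`: 1 for a
#' perfect star (the signature of a single rapid amplification burst from
#' one master element), smaller as internal structure accumulates.
#'
#' @param tree A `phylo` tree with >= 4 leaves and branch lengths.
#' @return Value in `[0, 1]`.
#' @export
starness <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop("need at least 4 leaves", call. = FALSE)
  total <- sum(tree$edge.length)
  if (total <= 0) stop("zero total branch length: starness undefined",
                       call. = FALSE)
  internal <- tree$edge[, 2] > ntip
  1 - sum(tree$edge.length[internal]) / total
}
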