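---
title: "The horizontal-transfer evidence chain: models, parameters and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The horizontal-transfer evidence chain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(httev)
```

# The inference problem

A transposable element found in two reproductively isolated species can
be there for two reasons: it was present in their common ancestor and
inherited vertically, or it crossed between lineages horizontally.
Under vertical inheritance and neutral evolution, the element's
between-species divergence should match that of any neutral sequence:
about $(r_a + r_b)\,T$ substitutions per site for a split $T$ years ago
with lineage rates $r_a, r_b$. Horizontal transfer (HT) is supported
when the observed divergence falls far below that expectation *and* the
mundane alternative explanations — purifying selection on the element,
strong codon bias, or simple misidentification of copies — can be
excluded. `httev` implements each link of that argument as a testable
function; this vignette records the models, the tunable parameters, and
the choices made where the method leaves room.

# Copy identification and counting

Copy number is computed from a 12-column BLAST-style hit table, not from
raw sequence. Coordinates are converted once, at the I/O boundary, to
0-based half-open intervals with an explicit strand (external tables
stay 1-based inclusive with `sstart > send` on the minus strand); this
removes the off-by-one ambiguity that plagues interval merging.

* **Filters.** Hits count toward copy number when the alignment is
  *strictly longer* than 100 bp and *at least* 80% identical. The mixed
  strict/inclusive reading follows the wording of the underlying rules
  ("more than 100 bp", "80% identity"); both are `filter_policy()`
  fields.
* **Merging.** Hits on the same subject and strand merge transitively
  when the gap between subject intervals is under 200 bp; overlapping
  hits always merge. Merging is per strand because fusing
  opposite-strand fragments would conflate independent nested
  insertions. The merge is verified in tests against a brute-force
  transitive-closure oracle on random tables.
* **Anti-chimera coverage.** Optionally, merged calls covering less
  than 40% of the consensus are dropped (useful in assemblies rich in
  chimaeric copies). Implemented per merged cluster; a per-fragment
  variant exists for MITEs (below).
* **Presence.** A family is recorded in a species when any hit reaches
  80% identity over at least 300 bp — deliberately independent of the
  counting thresholds, since short but solid hits establish presence
  without being countable copies.
* **MITEs.** Miniature inverted-repeat elements are short (< 600 bp)
  and homogeneous, so each fragment must individually exceed 80%
  identity *and* 80% coverage of the consensus; when two nested
  subfamilies differ by ~150 bp, the shorter one merges with a 100-bp
  gap instead of 200 bp to avoid fusing adjacent copies.

A caveat recorded here because tests rely on it: copy number is *not*
universally monotone in the filter thresholds. Removing a fragment that
bridges two others can split one merged call into two. Monotonicity
holds — and is tested — when each true insertion contributes a single
hit or when clusters are separated beyond the merge gap, which is how
real insertions behave; merge-gap monotonicity holds unconditionally.

# Consensus reconstruction and identity

The family's ancestral (master) sequence is estimated by majority rule
over an existing multiple alignment (the package never computes the
alignment itself). "Gap removal" is read column-wise: columns whose gap
fraction exceeds `max_gap_frac` (default 0.5) are dropped before base
calling, because removing gaps per sequence would destroy columnar
homology. Ties are broken lexicographically (A < C < G < T) and
flagged; with 4–50 copies ties are rare and a deterministic rule beats
a random one for reproducibility. A single-sequence "alignment" returns
that sequence (the best-hit-as-consensus rule for low-copy families).

Pairwise identity excludes every column where either sequence carries a
gap or a non-ACGT symbol, and is undefined (an error, not 0) when no
column survives. Whether identities are computed on pairwise or
multiple alignments is the caller's choice; the functions accept any
equal-length pair.

# TSDs and empty sites

`detect_tsd()` returns the longest exact direct repeat (left-flank
suffix = right-flank prefix) with length in a configurable range,
default 2–6 bp: the superfamily's TSDs are 3–4 bp, and one extra base
of slack on each side catches annotation slips without inviting long
spurious repeats. Exact matching only — the method targets recent
insertions, and tolerating mismatches would require a threshold nothing
in the data pins down. Because the repeat search is exact and flanks
are short, a locus can occasionally present a longer chance repeat;
motif building therefore operates on calls of one length and errors on
mixed input rather than silently mixing.

The motif is a per-position IUPAC code over all bases at frequency
≥ 0.05 (the noise floor suppresses singleton mutations; no published
rule exists, so the floor is explicit and configurable).
`verify_empty_site()` checks the defining signature of
duplication-upon-insertion: excising the element plus exactly one TSD
copy from the occupied locus must reconstruct the empty locus; zero or
two retained TSD copies both fail. Genome-wide discovery of candidate
empty sites (synteny scanning) is out of scope; the check takes a
user-supplied locus pair.

# Dating

`k2p_distance()` implements the Kimura 2-parameter correction
$k = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with pairwise deletion
of gapped/ambiguous columns, and errors (rather than returning `NaN`)
when a log argument is non-positive — saturation is a diagnosis, not a
number. Ages follow $T = k/2r$: copy-vs-consensus divergence divides by
*twice* the rate because both the copy and the consensus lineage
accumulate substitutions after the burst. Copies spanning less than 50%
of the consensus (ungapped length over ungapped consensus length) are
excluded; short fragments both date poorly and bias $k$ through their
reduced site count. Saturated copies are flagged, never fatal. Burst
periods are summarised as both min–max and interquartile range because
published "amplification periods" use range-style reporting without
defining it; reporting both avoids committing to either.

Rates are inputs, never estimated: the workflow uses the published
neutral rates 1.9×10⁻⁹ substitutions/site/year (lampreys),
2.9173×10⁻⁹ (tenrec) and 1.909×10⁻⁸ (Lepidoptera) where those lineages
appear.

# Selection and codon bias

`ng_divergence()` is the classic Nei–Gojobori pathway estimator:
synonymous site counts per codon are the fraction of single-base
changes that preserve the amino acid (changes to stops count as
nonsynonymous, so sites sum to exactly 3 per codon — an invariant the
tests assert to 1e-9); multi-substitution codons average difference
counts over all orderings of single steps with equal weights, excluding
orderings that pass through a stop codon; codons with no stop-free
pathway are skipped and recorded. Proportions are corrected by
$d = -\tfrac34\ln(1 - \tfrac43 p)$. dn/ds with $ds = 0$ is returned as
a flagged undefined value, not infinity. Only the standard genetic code
is wired in (all relevant hosts use it); the code table is a single
lookup, so other codes are a small extension.

`effective_number_of_codons()` follows Wright: per amino-acid family
homozygosity $\hat F = (n\sum \hat p_i^2 - 1)/(n-1)$ for families with
$n \ge 2$, averaged within degeneracy classes, then
$N_c = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$, clamped
to $[20, 61]$. Missing classes fall back to Wright's conventions
($\bar F_3$ as the mean of $\bar F_2$ and $\bar F_4$; otherwise the
mean of observed classes); families with $\hat F = 0$ carry no usable
information and are treated as unobserved. Note the formula's lower
limit is 20 (one codon per amino acid gives $\hat F = 1$ everywhere and
$2+9+1+5+3 = 20$), although the endpoint is sometimes quoted as 21; the
package follows the formula.

# The verdict

`classify_pair()` makes the qualitative argument explicit and
configurable. Defaults: HT requires observed/expected divergence
< 0.5; vertical consistency starts at 0.8; the housekeeping control
(e.g. EF-1α ds for the same species pair) must exceed the element ds
at least 10-fold; and dn/ds ≥ 0.2 counts as absence of strong
purifying selection, just below the smallest dn/ds observed for
conserved-yet-neutral transposase pairs (~0.26). The published analyses
argue HT from divergence deficits of two orders of magnitude, so any
defensible threshold classifies them identically; the defaults exist to
make borderline cases explicit rather than to tune the known ones. When
both identity and ds are available, ds drives the test — identity is
reported but not thresholded, because the quantitative argument rests
on synonymous divergence. Every rule consulted is recorded in
`reasons`, and a failed control yields `indeterminate`, never a quiet
HT call.

`nj_tree()` wraps classic neighbor joining (`ape::nj`) and clamps
negative branch lengths to zero, moving the deficit to the sister
branch. `starness()` is this package's own summary statistic:
$1 - \text{(internal branch length)}/\text{(total branch length)}$,
equal to 1 for a perfect star — the shape expected when all copies
radiate from one master in a single rapid burst.

# The simulator: what it emulates, and what it does not

The generator defines the conditions every recovery test runs under:

* **Master elements** carry a 15-bp terminal inverted repeat starting
  `CAC` (the 3' TIR is its reverse complement, hence ends `GTG`), a
  3-bp `TWA` TSD motif by default, and a realistic default length of
  2,289 bp.
* **Bursts** place all copies at the same expected divergence
  $k^\* = 2rT$ from the master — copy-vs-master divergence is simulated
  directly at $2rT$ because the dating estimator divides by $2r$;
  simulation and estimation must share the convention or the recovery
  test would test nothing. Substitutions follow a K2P process
  simulated per site from the exact transition probabilities, with
  $\kappa = \alpha/2\beta$ (the transition/transversion ratio;
  $\kappa = 0.5$ means all rates equal, and the transition fraction of
  substitutions is $\kappa/(\kappa+1)$). Default $\kappa = 2$, a
  typical nuclear value; nothing in the downstream estimators depends
  on it. Copies diverge independently (a pure star): the burst model
  itself.
* **Fragmentation** truncates a copy from a uniformly chosen end,
  retaining a uniform 10–90% of its length — a mechanism-free stand-in
  for the fragmented copies real assemblies contain.
* **Planting** overwrites `tsd_len` background bases with a motif draw,
  duplicates it across the element, and (by default) forces the `A`/`T`
  insertion context. Background is i.i.d. uniform A/C/G/T with no
  repeats other than planted ones, insertions are non-overlapping and
  never nested, and the emitted truth hit table has one row per planted
  fragment. Genome length is conserved exactly:
  background + Σ(copy + TSD).
* **Coding pairs** reach target ds/dn by accepting strictly synonymous
  or strictly nonsynonymous single-base substitutions (at most one per
  codon, never creating a stop) until the package's own estimator is
  within ±10% of target. Achievable values form a lattice (integer
  difference counts over fixed site counts), so the sampler stops at
  the closest achievable point and reports failure when the lattice is
  too coarse for the requested precision — short sequences cannot carry
  small targets.

What passing these tests does *not* show about real data: the simulator
has no indels (so alignment quality is never stressed), no nested or
overlapping insertions, no chimaeras, no GC heterogeneity, and no
selection on the transposase. The copy-number, TSD and dating stages
are therefore validated for their logic and conventions, not for
robustness to alignment error.

# Problem sizes and numerical conventions

The test suite and acceptance script run entirely from simulation:
200-copy bursts of a 2,289-bp element for dating recovery (mean age
within ±15% of 10 Ma), 100 random hit tables against the merge oracle,
25 planted loci for TSD recovery, 300–400 codon CDS for selection
tests, and 50-copy trees for the star diagnostic — sizes chosen to
match the published study's scale (4–50 copies per species, elements
0.3–3.4 kb) while keeping every recovery statistically comfortable.
Seeds are fixed throughout; identical configurations produce
byte-identical FASTA and table output. Degenerate inputs error loudly
and early: empty alignments, ragged "aligned" input, saturated
distances, zero comparable columns/codons, undefined Nc, and empty age
sets all raise conditions naming the problem.

# Known limitations

* Alignments are consumed, never computed; garbage alignments give
  garbage consensus, identity and dating with no internal warning.
* The HT verdict thresholds are this package's own defaults, clearly
  surfaced in output; no published numeric cutoff for
  "identity too high for the split time" exists.
* Orthologous-site discovery across genomes and vector identification
  are out of scope; patchy taxonomic distribution enters only as a
  user-supplied presence/absence table.
* The Nei–Gojobori estimator here is the unweighted-pathway original;
  it is not a maximum-likelihood codon model and inherits that
  method's known mild biases at high divergence.
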