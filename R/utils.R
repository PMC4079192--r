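# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom withr with_seed
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

DNA_BASES <- c("A", "C", "G", "T")

# IUPAC code -> base set
IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

iupac_expand <- function(code) {
  out <- IUPAC_MAP[[toupper(code)]]
  if (is.null(out)) stop("unknown IUPAC code: ", code, call. = FALSE)
  out
}

# base set -> IUPAC code
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  key <- paste(bases, collapse = "")
  hit <- vapply(IUPAC_MAP, function(b) paste(sort(b), collapse = "") == key,
                logical(1))
  if (!any(hit)) stop("no IUPAC code for base set: ", key, call. = FALSE)
  names(IUPAC_MAP)[which(hit)[1]]
}

# sample one concrete sequence realisation of an IUPAC motif
sample_motif <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1]],
               function(cc) {
                 opts <- iupac_expand(cc)
                 if (length(opts) == 1L) opts else sample(opts, 1L)
               }, character(1)),
        collapse = "")
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca",
         vapply(x, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}

seq_chars <- function(x) strsplit(toupper(x), "")[[1]]

split_codons <- function(x) {
  x <- toupper(x)
  n <- nchar(x)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

# standard genetic code only (see vignette); NA for codons with non-ACGT chars
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(aa)
}

is_stop_codon <- function(codon) {
  aa <- translate_codon(codon)
  !is.na(aa) & aa == "*"
}

translate_cds <- function(cds) {
  codons <- split_codons(cds)
  paste(translate_codon(codons), collapse = "")
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}
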