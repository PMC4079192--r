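test_that("the hand-enumerated Nei-Gojobori example is reproduced", {
  r <- ng_divergence("GCTGGTAAA", "GCCGGTAAA")
  expect_equal(r$syn_sites, 7 / 3, tolerance = 1e-12)
  expect_equal(r$nonsyn_sites, 20 / 3, tolerance = 1e-12)
  expect_equal(r$syn_diffs, 1)
  expect_equal(r$nonsyn_diffs, 0)
  expect_equal(r$dn, 0)
  # ps = 3/7; ds = -3/4 log(1 - 4/3 * 3/7) = 0.635473...
  expect_equal(r$ds, -0.75 * log(1 - 4 / 7), tolerance = 1e-12)
  expect_lt(abs(r$ds - 0.6354), 1e-3)
})

test_that("identical pairs give zero divergence and a flagged ratio", {
  r <- ng_divergence("ATGGCTAAA", "ATGGCTAAA")
  expect_equal(r$ds, 0)
  expect_equal(r$dn, 0)
  expect_true(r$ratio_undefined)
  expect_true(is.na(r$ratio))
})

test_that("multi-hit codons average over stop-free pathways", {
  # TTT (Phe) vs GTA (Val), with a GGG context codon to keep ps < 0.75:
  # path1 TTT->GTT(Val)->GTA(Val): 1 nonsyn + 1 syn
  # path2 TTT->TTA(Leu)->GTA(Val): 2 nonsyn
  r <- ng_divergence("TTTGGG", "GTAGGG")
  expect_equal(r$syn_diffs, 0.5)
  expect_equal(r$nonsyn_diffs, 1.5)

  # TGT (Cys) vs TGG (Trp) via TGA would pass a stop: only the direct
  # single change exists and it is nonsynonymous
  r2 <- ng_divergence("TGTGGG", "TGGGGG")
  expect_equal(r2$nonsyn_diffs, 1)

  # AGA (Arg) vs TGG (Trp): the ordering through TGA (stop) is excluded,
  # leaving only AGA->AGG(syn)->TGG(nonsyn)
  r3 <- ng_divergence("AGAGGGGGG", "TGGGGGGGG")
  expect_equal(r3$syn_diffs, 1)
  expect_equal(r3$nonsyn_diffs, 1)
  expect_length(r3$skipped_codons, 0)
})

test_that("sites are conserved and the estimator is symmetric", {
  for (seed in 1:10) {
    a <- random_cds(40, seed = 70 + seed)
    b <- mutate_cds(a, n_subs = 15, seed = 80 + seed)
    r <- ng_divergence(a, b)
    expect_equal(r$syn_sites + r$nonsyn_sites, 3 * r$n_codons,
                 tolerance = 1e-9)
    r_swap <- ng_divergence(b, a)
    expect_equal(r$ds, r_swap$ds)
    expect_equal(r$dn, r_swap$dn)
  }
})

test_that("codons with gaps or ambiguity are excluded pairwise", {
  r <- ng_divergence("GCTGGT---AAA", "GCCGGTGGGAAA")
  expect_equal(r$n_codons, 3)
  expect_error(ng_divergence("---", "---"), "no comparable")
  expect_error(ng_divergence("GCTGGT", "GCT"), "equal length")
})

test_that("back-translation expands protein gaps to codon gaps", {
  aln <- backtranslate_alignment(c(r1 = "M-K"),
                                 c(r1 = "ATGAAA"))
  expect_equal(unname(aln), "ATG---AAA")
  # terminal stop on the CDS is tolerated
  aln2 <- backtranslate_alignment(c(r1 = "MK"), c(r1 = "ATGAAATAA"))
  expect_equal(unname(aln2), "ATGAAA")
  expect_error(backtranslate_alignment(c(r1 = "MW"), c(r1 = "ATGAAA")),
               "translate")
  expect_error(backtranslate_alignment(c(r1 = "MK"), c(r2 = "ATGAAA")),
               "no CDS")
})

test_that("back-translation round-trips: strip gaps and translate", {
  withr::with_seed(90, {
    cds <- vapply(1:3, function(i) random_cds(30, seed = 90 + i),
                  character(1))
  })
  names(cds) <- paste0("r", 1:3)
  prot <- vapply(cds, function(x) {
    paste(Biostrings::GENETIC_CODE[substring(x, seq(1, nchar(x), 3),
                                             seq(3, nchar(x), 3))],
          collapse = "")
  }, character(1))
  prot <- gsub("\\*", "", prot) # strip stops for a clean protein row
  cds_nostop <- substr(cds, 1, 3 * nchar(prot))
  # insert a shared gap column to exercise expansion
  prot_aln <- paste0(substr(prot, 1, 5), "-", substr(prot, 6, nchar(prot)))
  names(prot_aln) <- names(cds)
  aln <- backtranslate_alignment(prot_aln, cds_nostop)
  stripped <- gsub("-", "", aln)
  expect_identical(unname(stripped), unname(cds_nostop))
})

test_that("dn/ds profiles enumerate all unordered pairs", {
  rows <- vapply(1:5, function(i) {
    mutate_cds(random_cds(40, seed = 100), n_subs = 4 * i, seed = 100 + i)
  }, character(1))
  names(rows) <- paste0("taxon", 1:5)
  prof <- dnds_profile(rows)
  expect_equal(nrow(prof), 10)
  expect_equal(nrow(dnds_profile(rows[1:2])), 1)
  # oracle: direct per-pair recomputation
  for (r in seq_len(nrow(prof))) {
    direct <- ng_divergence(rows[[prof$id_a[r]]], rows[[prof$id_b[r]]])
    expect_equal(prof$ds[r], direct$ds)
    expect_equal(prof$dn[r], direct$dn)
  }
  expect_error(dnds_profile(rows[1]), "at least 2")
})

test_that("Nc spans its theoretical limits", {
  code <- Biostrings::GENETIC_CODE
  fams <- split(names(code[code != "*"]), code[code != "*"])
  uniform <- paste(unlist(lapply(fams, rep, times = 20)), collapse = "")
  expect_equal(effective_number_of_codons(uniform)$nc, 61)
  one_per_aa <- paste(unlist(lapply(fams, function(f) rep(f[1], 10))),
                      collapse = "")
  expect_equal(effective_number_of_codons(one_per_aa)$nc, 20)
})

test_that("Nc agrees with a direct evaluation of Wright's formula", {
  for (seed in 1:5) {
    cds <- random_cds(300, seed = 110 + seed)
    got <- effective_number_of_codons(cds)
    # independent oracle: recount codons and evaluate the formula directly
    codons <- substring(cds, seq(1, nchar(cds), 3), seq(3, nchar(cds), 3))
    code <- Biostrings::GENETIC_CODE
    codons <- codons[code[codons] != "*"]
    fams <- split(names(code[code != "*"]), code[code != "*"])
    Fh <- list()
    for (aa in names(fams)) {
      n <- sum(codons %in% fams[[aa]])
      if (n < 2 || length(fams[[aa]]) == 1) next
      p <- table(factor(codons[codons %in% fams[[aa]]],
                        levels = fams[[aa]])) / n
      f <- (n * sum(p^2) - 1) / (n - 1)
      if (f > 1e-9) {
        Fh[[aa]] <- c(size = length(fams[[aa]]), f = f)
      }
    }
    fm <- do.call(rbind, Fh)
    cls <- function(k) mean(fm[fm[, "size"] == k, "f"])
    nc_direct <- 2 + 9 / cls(2) + 1 / cls(3) + 5 / cls(4) + 3 / cls(6)
    nc_direct <- min(61, max(20, nc_direct))
    expect_equal(got$nc, nc_direct, tolerance = 1e-6)
    expect_gte(got$nc, 20)
    expect_lte(got$nc, 61)
  }
})

test_that("Nc errors when no degeneracy class is observable", {
  expect_error(effective_number_of_codons("ATGTGG"), "undefined")
})
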