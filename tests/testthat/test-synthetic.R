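test_that("master elements carry CAC...GTG termini and are seed-deterministic", {
  m <- generate_master(2289, 3, seed = 1)
  expect_equal(nchar(m$sequence), 2289)
  expect_equal(substr(m$sequence, 1, 3), "CAC")
  expect_equal(substr(m$sequence, 2287, 2289), "GTG")
  expect_true(startsWith(m$sequence, m$tir_5))
  expect_true(endsWith(m$sequence, m$tir_3))
  expect_equal(m$tir_3, revcomp(m$tir_5))
  expect_equal(nchar(m$tsd_motif), m$tsd_len)
  for (iv in m$cds_intervals) {
    expect_true(iv[1] >= 0 && iv[2] <= nchar(m$sequence))
  }
  expect_identical(generate_master(2289, 3, seed = 1)$sequence, m$sequence)
  expect_false(identical(generate_master(2289, 3, seed = 2)$sequence,
                         m$sequence))
  expect_equal(nchar(generate_master(60, 3, seed = 1)$sequence), 60)
  expect_error(generate_master(59, 3, seed = 1), "60")
})

test_that("zero-age bursts reproduce the master exactly", {
  m <- generate_master(300, 3, seed = 1)
  fam <- simulate_family(m, burst_truth(0, 1.9e-9, 5, seed = 1))
  expect_true(all(fam$copies == m$sequence))
})

test_that("burst divergence matches 2rT within three standard errors", {
  m <- generate_master(2289, 3, seed = 1)
  fam <- simulate_family(m, burst_truth(1e7, 1.9e-9, 200, seed = 11))
  ks <- vapply(fam$copies, function(cp) k2p_distance(cp, m$sequence)$k,
               numeric(1))
  se <- stats::sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - 0.038), 3 * se)
})

test_that("kappa = 0.5 yields equal-rate substitutions (1/3 transitions)", {
  m <- generate_master(20000, 3, seed = 2)
  fam <- simulate_family(m, burst_truth(1e7, 5e-9, 10, kappa = 0.5,
                                        seed = 3))
  ref <- strsplit(m$sequence, "")[[1]]
  ts <- tv <- 0
  for (cp in fam$copies) {
    obs <- strsplit(cp, "")[[1]]
    d <- which(obs != ref)
    is_ts <- (ref[d] %in% c("A", "G") & obs[d] %in% c("A", "G")) |
      (ref[d] %in% c("C", "T") & obs[d] %in% c("C", "T"))
    ts <- ts + sum(is_ts)
    tv <- tv + sum(!is_ts)
  }
  expect_equal(ts / (ts + tv), 1 / 3, tolerance = 0.03)
})

test_that("near-saturation bursts raise a warning", {
  m <- generate_master(100, 3, seed = 1)
  expect_warning(simulate_family(m, burst_truth(2e8, 1.9e-9, 2, seed = 1)),
                 "saturation")
})

test_that("fragmentation truncates from one end and is recorded in truth", {
  m <- generate_master(1000, 3, seed = 1)
  fam <- simulate_family(m, burst_truth(1e6, 1.9e-9, 50,
                                        fragment_prob = 1, seed = 4))
  expect_true(all(fam$truth$fragmented))
  expect_true(all(fam$truth$qstart == 1L | fam$truth$qend == 1000L))
  expect_equal(nchar(fam$copies),
               fam$truth$qend - fam$truth$qstart + 1L,
               ignore_attr = TRUE)
})

test_that("planted genomes conserve length and carry motif TSDs", {
  m <- generate_master(400, 3, seed = 5)
  fam <- simulate_family(m, burst_truth(1e6, 1.9e-9, 10, seed = 6))
  pl <- plant_insertions(fam$copies, 20000, m, seed = 7, truth = fam$truth)
  expect_equal(nchar(pl$genome), 20000 + sum(nchar(fam$copies) + 3))
  expect_true(all(grepl("^T[AT]A$", pl$loci$tsd)))
  # TSD flanks the element on both sides, inside an A ... T context
  for (i in seq_len(nrow(pl$loci))) {
    s0 <- pl$loci$start0[i]; e0 <- pl$loci$end0[i]
    expect_equal(substr(pl$genome, s0 - 2, s0), pl$loci$tsd[i])
    expect_equal(substr(pl$genome, e0 + 1, e0 + 3), pl$loci$tsd[i])
    expect_equal(substr(pl$genome, s0 - 3, s0 - 3), "A")
    expect_equal(substr(pl$genome, e0 + 4, e0 + 4), "T")
    expect_equal(substr(pl$genome, s0 + 1, e0), pl$loci$inserted_copy[i])
  }
})

test_that("planting zero copies returns the untouched background", {
  m <- generate_master(400, 3, seed = 5)
  pl <- plant_insertions(character(0), 5000, m, seed = 8)
  expect_equal(nchar(pl$genome), 5000)
  expect_equal(nrow(pl$hits), 0)
  expect_equal(nrow(pl$loci), 0)
})

test_that("overfull genomes raise a capacity error", {
  m <- generate_master(400, 3, seed = 5)
  fam <- simulate_family(m, burst_truth(0, 1.9e-9, 50, seed = 1))
  expect_error(plant_insertions(fam$copies, 2000, m, seed = 1), "capacity")
})

test_that("simulator output is byte-identical for identical configs", {
  m <- generate_master(400, 3, seed = 5)
  fam <- simulate_family(m, burst_truth(1e6, 1.9e-9, 5, seed = 6))
  run <- function() {
    pl <- plant_insertions(fam$copies, 10000, m, seed = 7,
                           truth = fam$truth)
    fa <- withr::local_tempfile(fileext = ".fasta")
    tsv <- withr::local_tempfile(fileext = ".tsv")
    write_fasta(c(genome = pl$genome), fa)
    write_hit_table(pl$hits, tsv)
    list(fa = readLines(fa), tsv = readLines(tsv))
  }
  expect_identical(run(), run())
})

test_that("synonymous-only coding pairs hit their ds target with dn = 0", {
  cds <- random_cds(200, seed = 9)
  sp <- simulate_coding_pair(cds, target_ds = 0.05, target_dn = 0,
                             seed = 10)
  expect_identical(sp$dn, 0)
  expect_equal(sp$ds, 0.05, tolerance = 0.1)
  est <- ng_divergence(sp$cds_a, sp$cds_b)
  expect_identical(est$dn, 0)

  same <- simulate_coding_pair(cds, 0, 0, seed = 11)
  expect_identical(same$cds_a, same$cds_b)
})

test_that("coding pairs recover a prescribed dn/ds of 0.25", {
  cds <- random_cds(300, seed = 12)
  sp <- simulate_coding_pair(cds, target_ds = 0.60, target_dn = 0.15,
                             seed = 13)
  expect_equal(sp$dn / sp$ds, 0.25, tolerance = 0.15)
})

test_that("unreachable divergence targets are rejected", {
  cds <- random_cds(50, seed = 14)
  expect_error(simulate_coding_pair(cds, 0.8, 0, seed = 1), "ceiling")
  expect_error(simulate_coding_pair(cds, 0, 0.75, seed = 1), "ceiling")
})

test_that("estimated ds increases with the target (monotone recovery)", {
  cds <- random_cds(250, seed = 15)
  targets <- c(0.05, 0.15, 0.3)
  got <- vapply(targets, function(t) {
    simulate_coding_pair(cds, t, 0, seed = 16)$ds
  }, numeric(1))
  expect_true(all(diff(got) > 0))
})
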