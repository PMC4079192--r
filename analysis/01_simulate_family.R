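#!/usr/bin/env Rscript
# Step 1 — simulate the study system: a Chapaev-like master element
# (2,289 bp, CAC...GTG termini, 3-bp TWA TSD), a 10-Ma amplification burst
# of 50 copies at the lamprey neutral rate, and a background genome with
# the copies planted behind TSDs. Writes the inputs every later step
# consumes. All downstream numbers trace back to the ground truth fixed
# here.

library(httev)
dir.create("results", showWarnings = FALSE)

master <- generate_master(2289, tsd_len = 3, seed = 101, name = "famA")
cat("master element:", master$name, nchar(master$sequence), "bp, TIRs",
    master$tir_5, "/", master$tir_3, "\n")

fam <- simulate_family(master, burst_truth(
  burst_age_years = 1e7, rate_per_site_year = 1.9e-9,
  n_copies = 50, kappa = 2, fragment_prob = 0.2, seed = 102))
cat("simulated", length(fam$copies), "copies;",
    sum(fam$truth$fragmented), "fragmented; expected k* =",
    unique(fam$truth$k_expected), "\n")

pl <- plant_insertions(fam$copies, genome_length = 2e5, master,
                       seed = 103, truth = fam$truth)
cat("planted genome:", nchar(pl$genome), "bp carrying",
    nrow(pl$loci), "insertions\n")

write_fasta(c(famA_master = master$sequence), "results/master.fasta")
write_fasta(fam$copies, "results/copies.fasta")
write_fasta(align_copies_to_master(fam$copies, fam$truth,
                                   nchar(master$sequence)),
            "results/copies_aligned.fasta")
write_fasta(c(chr1 = pl$genome), "results/genome.fasta")
write_hit_table(pl$hits, "results/hits.tsv")
utils::write.table(pl$loci[, c("chrom", "start0", "end0", "tsd")],
                   "results/loci.tsv", sep = "\t", quote = FALSE,
                   row.names = FALSE)
utils::write.table(fam$truth, "results/burst_truth.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("wrote results/{master,copies,copies_aligned,genome}.fasta,",
    "hits.tsv, loci.tsv, burst_truth.tsv\n")
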