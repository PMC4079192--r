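test_that("hit filters read 'more than 100 bp' strictly and identity inclusively", {
  hits <- make_hits(start = c(0, 0, 0), end = c(150, 100, 150),
                    identity = c(85, 85, 79.9))
  kept <- filter_hits(hits)
  expect_equal(nrow(kept), 1)
  expect_equal(kept$aln_len, 150)
  # exactly 80% identity is kept
  expect_equal(nrow(filter_hits(make_hits(0, 150, identity = 80))), 1)
})

test_that("fragments under the merge gap form a single insertion call", {
  one <- merge_fragments(make_hits(start = c(100, 550), end = c(400, 900)))
  expect_equal(nrow(one), 1)      # gap 150 < 200
  expect_equal(one$n_fragments, 1 + 1)
  expect_equal(one$start, 100)
  expect_equal(one$end, 900)

  two <- merge_fragments(make_hits(start = c(100, 700), end = c(400, 1000)))
  expect_equal(nrow(two), 2)      # gap 300 >= 200

  # opposite strands never merge
  strands <- merge_fragments(make_hits(start = c(100, 550),
                                       end = c(400, 900),
                                       strand = c("+", "-")))
  expect_equal(nrow(strands), 2)
})

test_that("merging equals transitive-closure merging on random hit tables", {
  for (case in 1:100) {
    hits <- withr::with_seed(1000 + case, {
      n <- sample(5:50, 1)
      start <- sample(0:5000, n)
      make_hits(start = start, end = start + sample(101:800, n, TRUE),
                subject = sample(c("chr1", "chr2"), n, TRUE),
                strand = sample(c("+", "-"), n, TRUE))
    })
    expect_calls_equal_oracle(hits, gap_max = 200)
  }
})

test_that("merging is idempotent", {
  hits <- withr::with_seed(31, {
    start <- sample(0:4000, 30)
    make_hits(start = start, end = start + sample(101:600, 30, TRUE))
  })
  calls <- merge_fragments(hits)
  # re-feed calls as single-fragment hits
  again <- merge_fragments(make_hits(start = calls$start, end = calls$end))
  expect_equal(nrow(again), nrow(calls))
  expect_equal(again$start, calls$start)
  expect_equal(again$end, calls$end)
})

test_that("copy number is monotone in the filter thresholds and merge gap", {
  # one hit per true insertion (clusters farther apart than any merge gap
  # used), identities and lengths spread by divergence and fragmentation
  m <- generate_master(1500, 3, seed = 32)
  fam <- simulate_family(m, burst_truth(4e7, 1.9e-9, 25,
                                        fragment_prob = 0.5, seed = 33))
  hits <- plant_insertions(fam$copies, 100000, m, seed = 34,
                           truth = fam$truth)$hits
  cn <- function(min_id, min_len, cov) {
    pol <- filter_policy(min_hit_len = min_len, min_identity = min_id,
                         min_consensus_coverage = max(cov, 1e-9))
    count_copies(hits, consensus_len = 1500, policy = pol)
  }
  expect_true(all(diff(sapply(c(70, 80, 90, 95), function(id)
    cn(id, 100, 0))) <= 0))
  expect_true(all(diff(sapply(c(50, 100, 400, 1200), function(len)
    cn(80, len, 0))) <= 0))
  expect_true(all(diff(sapply(c(0, 0.2, 0.4, 0.8), function(cov)
    cn(80, 100, cov))) <= 0))
  # widening the merge gap can only merge more: non-increasing counts
  rand <- withr::with_seed(35, {
    start <- sample(0:8000, 40)
    make_hits(start = start, end = start + sample(101:900, 40, TRUE))
  })
  expect_true(all(diff(sapply(c(50, 200, 1000, 5000), function(gap)
    nrow(merge_fragments(rand, merge_gap = gap)))) <= 0))
})

test_that("coverage filter drops calls below the anti-chimera threshold", {
  pol40 <- filter_policy(min_consensus_coverage = 0.40)
  calls <- merge_fragments(make_hits(start = c(0, 2000),
                                     end = c(900, 2780)))
  kept <- coverage_filter(calls, consensus_len = 2000, policy = pol40)
  expect_equal(nrow(kept), 1)              # 45% kept, 39% dropped
  expect_equal(kept$coverage_of_consensus, 0.45)
  all_kept <- coverage_filter(calls, consensus_len = 2000)
  expect_equal(nrow(all_kept), 2)          # threshold 0 disables
  expect_error(coverage_filter(calls, consensus_len = 0), "consensus_len")
})

test_that("presence calls need >= 80% identity over at least 300 bp", {
  expect_true(presence_call(make_hits(0, 350, identity = 85)))
  expect_false(presence_call(make_hits(0, 250, identity = 85)))
  expect_false(presence_call(make_hits(0, 350, identity = 75)))
  expect_true(presence_call(make_hits(0, 300, identity = 80)))
  expect_false(presence_call(make_hits(integer(0), integer(0))))
})

test_that("MITE counting applies the strict filters and the 100-bp gap", {
  # two high-coverage fragments of a 295-bp consensus, 80 bp apart
  frag <- make_hits(start = c(1000, 1360), end = c(1280, 1640),
                    identity = 95)
  expect_equal(mite_copy_number(frag, 295, short_subfamily = TRUE), 1)
  apart <- make_hits(start = c(1000, 1400), end = c(1280, 1680),
                     identity = 95)
  expect_equal(mite_copy_number(apart, 295, short_subfamily = TRUE), 2)
  # the default 200-bp gap would still merge them
  expect_equal(mite_copy_number(apart, 295, short_subfamily = FALSE), 1)
  # fragments failing identity or coverage are discarded first
  weak <- make_hits(start = c(1000, 3000), end = c(1280, 3100),
                    identity = c(79, 95))
  expect_equal(mite_copy_number(weak, 295), 0)
})

test_that("planted insertion counts are recovered exactly without fragmentation", {
  m <- generate_master(2289, 3, seed = 41)
  fam <- simulate_family(m, burst_truth(1e6, 1.9e-9, 10, seed = 42))
  pl <- plant_insertions(fam$copies, 60000, m, seed = 43,
                         truth = fam$truth)
  expect_equal(count_copies(pl$hits, consensus_len = 2289), 10)

  mite <- generate_master(577, 3, seed = 44, name = "mite")
  mfam <- simulate_family(mite, burst_truth(1e6, 1.9e-9, 18, seed = 45))
  mpl <- plant_insertions(mfam$copies, 60000, mite, seed = 46,
                          truth = mfam$truth)
  expect_equal(mite_copy_number(mpl$hits, consensus_len = 577), 18)
})
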