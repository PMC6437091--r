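# Synthetic-data generators.

test_that("generators are pure functions of their seeds", {
  expect_identical(simulate_pangenome(10, 200, 0.8, 100, seed = 5),
                   simulate_pangenome(10, 200, 0.8, 100, seed = 5))
  expect_identical(simulate_alignment(8, 400, 0.05, seed = 9),
                   simulate_alignment(8, 400, 0.05, seed = 9))
  expect_identical(simulate_alignment(8, 400, 0.05, n_events = 3, seed = 9),
                   simulate_alignment(8, 400, 0.05, n_events = 3, seed = 9))
  sc <- simulate_recomb_scenario(paste0("G", 1:5), seed = 3)
  sc2 <- simulate_recomb_scenario(paste0("G", 1:5), seed = 3)
  expect_identical(sc$events, sc2$events)
  expect_identical(sc$hits, sc2$hits)
})

test_that("simulated pan-genomes keep core families universal", {
  pm <- simulate_pangenome(12, 300, 0.9, core_size = 50, seed = 2)
  expect_true(all(pm$presence[, 1:50]))
  pm2 <- simulate_pangenome(12, 300, 0.9, core_size = 50, seed = 2,
                            method = "sequential")
  expect_true(all(pm2$presence[, 1:50]))
})

test_that("sequential construction realizes round(kappa * g^-alpha) new families", {
  kappa <- 300; alpha <- 0.9; core <- 50
  pm <- simulate_pangenome(15, kappa, alpha, core, retention = 0.3,
                           seed = 6, method = "sequential")
  pres <- pm$presence
  first_seen <- apply(pres, 2, function(col) which(col)[1L])
  realized <- tabulate(first_seen, nbins = 15)
  expect_equal(realized[1L], core + round(kappa))
  expect_equal(realized[2:15], round(kappa * (2:15)^(-alpha)))
})

test_that("fixture matrices reproduce the requested composition exactly", {
  counts <- c(`10` = 30, `9` = 12, `5` = 40, `1` = 100)
  pm <- make_fixture_matrix(10, counts, seed = 3)
  occ <- colSums(pm$presence)
  expect_equal(unname(table(occ)[c("10", "9", "5", "1")]),
               unname(counts), ignore_attr = TRUE)
  # infeasible and degenerate requests
  expect_error(make_fixture_matrix(5, c(`7` = 3)),
               class = "panrecom_parameter_error")
  one <- make_fixture_matrix(1, c(`1` = 8), seed = 1)
  expect_equal(summarize_pangenome(one)$pct_core, 100)
})

test_that("clonal alignments carry no recombination signal structure", {
  aln <- simulate_alignment(10, 600, divergence = 0.04, seed = 21)
  expect_equal(aln$length, 600L)
  expect_equal(length(aln$ids), 10L)
  m <- alignment_matrix(aln)
  expect_true(all(m %in% c("A", "C", "G", "T")))
})

test_that("mosaic alignments move recipient segments to the other group", {
  aln0 <- simulate_alignment(8, 500, divergence = 0.1, n_events = 0,
                             seed = 14)
  aln <- simulate_alignment(8, 500, divergence = 0.1, n_events = 6,
                            event_mean_length = 100, seed = 14)
  # two-group structure: with no events each group is internally identical
  expect_gt(length(informative_sites(aln)), 0L)
  expect_gt(length(unique(aln$seqs)), 2L)   # transfers break group identity
})

test_that("fragment lengths are geometric with the planted mean", {
  sc <- simulate_recomb_scenario(paste0("G", 1:12), base_rate = 35,
                                 fragment_mean = 230, seed = 17)
  lens <- sc$events$length
  expect_gt(length(lens), 4000L)
  expect_lt(abs(mean(lens) - 230) / 230, 0.1)
  # geometric (discrete exponential) median is mean * ln 2
  expect_lt(abs(median(lens) - 230 * log(2)) / (230 * log(2)), 0.15)
})

test_that("scenario hit tables plant the donor as the top qualifying hit", {
  sc <- simulate_recomb_scenario(paste0("G", 1:6), base_rate = 2, seed = 8)
  byq <- split(sc$hits, sc$hits$query_id)
  for (i in seq_len(min(20, nrow(sc$events)))) {
    h <- byq[[sc$events$event_id[i]]]
    top <- h$subject_genome[which.max(h$bitscore)]
    expect_equal(top, sc$events$donor_lineage[i])
  }
})
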