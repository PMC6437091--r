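# Informative sites, refined incompatibility and the PHI test.

test_that("informative sites need two states carried twice", {
  aln <- alignment_from_columns(list(
    c("A", "A", "A", "T", "T"),     # informative
    c("A", "A", "A", "A", "T"),     # singleton state
    c("A", "-", "-", "-", "-"),     # one effective state
    c("A", "A", "T", "T", "N"),     # informative (N ignored)
    c("C", "C", "C", "C", "C")))    # constant
  expect_equal(informative_sites(aln), c(1L, 4L))
})

test_that("refined incompatibility scores follow E - V + C", {
  expect_equal(refined_incompatibility(c("A", "A", "T", "T"),
                                       c("A", "A", "T", "T")), 0)
  # classic four-gamete case
  expect_equal(refined_incompatibility(c("A", "A", "T", "T"),
                                       c("A", "T", "A", "T")), 1)
  # three-state site vs binary site, 5 joint pairs, connected: 5 - 5 + 1
  expect_equal(refined_incompatibility(c("A", "A", "C", "C", "G", "G"),
                                       c("A", "T", "A", "T", "A", "A")), 1)
  # pairwise deletion can leave too few sequences
  expect_true(is.na(refined_incompatibility(c("A", "-", "T", "-"),
                                            c("-", "A", "-", "T"))))
})

test_that("incompatibility equals exhaustive parsimony over all topologies", {
  skip_if_not_installed("phangorn")
  set.seed(71)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    si <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    sj <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    expect_equal(refined_incompatibility(si, sj),
                 oracle_incompatibility(si, sj),
                 info = paste(paste(si, collapse = ""),
                              paste(sj, collapse = "")))
  }
})

# six sequences, three informative sites: only the first two sites are
# incompatible, so the mean over the three qualifying pairs is 1/3
phi_fixture <- alignment_from_columns(list(
  c("A", "A", "A", "T", "T", "T"),
  c("A", "A", "T", "T", "A", "A"),
  c("A", "A", "A", "A", "T", "T")))

test_that("the hand-built alignment gives Phi_w = 1/3", {
  expect_equal(phi_statistic(phi_fixture, w = 10), 1 / 3)
  # window saturation: any w >= L gives the all-pairs mean
  expect_equal(phi_statistic(phi_fixture, w = 1000), 1 / 3)
})

test_that("Phi_w is invariant to sequence order and state relabeling", {
  base <- simulate_alignment(12, 500, divergence = 0.08, n_events = 4,
                             seed = 19)
  v <- phi_statistic(base, w = 100)
  set.seed(5)
  perm <- sample(length(base$ids))
  shuffled <- site_alignment(base$ids[perm], base$seqs[perm])
  expect_equal(phi_statistic(shuffled, w = 100), v)
  # relabel states A<->G, C<->T within every column
  relabeled <- site_alignment(base$ids,
                              chartr("AGCT", "GATC", base$seqs))
  expect_equal(phi_statistic(relabeled, w = 100), v)
})

test_that("the permutation test is deterministic with valid p-values", {
  aln <- simulate_alignment(10, 800, divergence = 0.05, n_events = 5,
                            seed = 33)
  r1 <- phi_test(aln, w = 100, n_permutations = 199, seed = 7)
  r2 <- phi_test(aln, w = 100, n_permutations = 199, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
  expect_equal((r1$p_value * (1 + 199)) %% 1, 0)  # (1+b)/(1+m) form
  expect_error(phi_test(aln, n_permutations = 0),
               class = "panrecom_parameter_error")
})

test_that("alignments without informative sites are an analysis error", {
  aln <- site_alignment(c("a", "b", "c", "d"),
                        rep(strrep("ACGT", 5), 4))
  expect_error(phi_statistic(aln), class = "panrecom_analysis_error")
  expect_error(phi_test(aln), class = "panrecom_analysis_error")
})

test_that("a clonal alignment leaves the score multiset permutation-stable", {
  # permuting columns of a clonal alignment must not change pooled scores,
  # so the observed statistic is typical of its own permutation null
  aln <- simulate_alignment(16, 1000, divergence = 0.05, seed = 55)
  res <- phi_test(aln, w = 100, n_permutations = 99, seed = 2)
  expect_gt(res$p_value, 0.0099)
})
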