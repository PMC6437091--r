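# Donor assignment, recombination network, highways, counts, sizes.

event300 <- recomb_events("geneA", "strainR", "L2", 101, 400)[1, ]

hits_for <- function(...) {
  rows <- list(...)
  blast_hits(query_id = "ev",
             subject_id = vapply(rows, `[[`, "", 1L),
             percent_identity = vapply(rows, function(r) r[[2L]], 0),
             alignment_length = vapply(rows, function(r) r[[3L]], 0),
             evalue = 1e-50,
             bitscore = vapply(rows, function(r) r[[4L]], 0))
}

test_that("donor assignment keeps the top bit score among qualifying hits", {
  h <- hits_for(list("gB|c", 99.5, 180, 500), list("gC|c", 99.9, 210, 450))
  a <- assign_donor(event300, h)
  expect_equal(a$status, "assigned")
  expect_equal(a$donor_genome, "gB")       # bits 500 wins despite lower id
  # identity below 99 disqualifies
  expect_equal(assign_donor(event300,
                            hits_for(list("gB|c", 98.5, 300, 600)))$status,
               "unresolved")
  # coverage 147/300 = 0.49 disqualifies
  expect_equal(assign_donor(event300,
                            hits_for(list("gB|c", 99.9, 147, 600)))$status,
               "unresolved")
  expect_equal(assign_donor(event300, NULL)$status, "unresolved")
})

test_that("exact bitscore ties across genomes are ambiguous, order-invariant", {
  h <- hits_for(list("gC|c", 99.5, 300, 500), list("gB|c", 99.5, 300, 500))
  a <- assign_donor(event300, h)
  expect_equal(a$status, "ambiguous")
  expect_equal(a$candidate_genome, "gB")   # lexicographically smallest
  expect_true(is.na(a$donor_genome))
  # shuffling hit order changes nothing
  a2 <- assign_donor(event300, h[2:1, ])
  expect_equal(a2$status, a$status)
  expect_equal(a2$candidate_genome, a$candidate_genome)
})

stub_assignment <- function(donor, recipient) {
  structure(list(status = "assigned", donor_genome = donor,
                 event = list(recipient = recipient)),
            class = "donor_assignment")
}

test_that("the network counts directed pairs and conserves assigned events", {
  assn <- c(replicate(3, stub_assignment("A", "B"), simplify = FALSE),
            list(stub_assignment("C", "B")),
            list(structure(list(status = "unresolved",
                                donor_genome = NA_character_,
                                event = list(recipient = "B")),
                           class = "donor_assignment")))
  net <- build_network(assn)
  expect_equal(net$edges$count[net$edges$donor == "A"], 3L)
  expect_equal(net$edges$count[net$edges$donor == "C"], 1L)
  expect_equal(sum(net$edges$count), 4L)   # unresolved events excluded
  # group-by oracle on shuffled input
  set.seed(8)
  donors <- sample(c("A", "B", "C", "D"), 60, replace = TRUE)
  recips <- sample(c("E", "F", "G"), 60, replace = TRUE)
  net2 <- build_network(mapply(stub_assignment, donors, recips,
                               SIMPLIFY = FALSE))
  oracle <- table(paste(donors, recips))
  got <- setNames(net2$edges$count,
                  paste(net2$edges$donor, net2$edges$recipient))
  expect_equal(got[names(oracle)], oracle[names(oracle)],
               ignore_attr = TRUE)
  expect_equal(sum(net2$edges$count), 60L)
})

test_that("empty assignment lists give an empty network", {
  net <- build_network(list())
  expect_equal(nrow(net$edges), 0L)
  expect_true(is.na(net$mean_count))
  expect_equal(nrow(detect_highways(net)), 0L)
})

test_that("highways are edges at least one sd above the mean", {
  mk_net <- function(counts) {
    assn <- unlist(lapply(seq_along(counts), function(i) {
      replicate(counts[i], stub_assignment(paste0("D", i), "R"),
                simplify = FALSE)
    }), recursive = FALSE)
    build_network(assn)
  }
  net <- mk_net(c(40, 10, 5))
  hw <- detect_highways(net)              # mean 18.33, sd 18.93 -> thr 37.26
  expect_equal(nrow(hw), 1L)
  expect_equal(hw$donor, "D1")
  expect_equal(attr(hw, "threshold"), mean(c(40, 10, 5)) + sd(c(40, 10, 5)))
  # single edge: no sd, no highways
  expect_equal(nrow(detect_highways(mk_net(7))), 0L)
  # zero dispersion: ties are not highways
  expect_equal(nrow(detect_highways(mk_net(c(5, 5, 5)))), 0L)
})

test_that("per-gene counts split recent from ancestral", {
  ev <- rbind(recomb_events(c("geneA", "geneA", "geneB"), "r", "L", 1, 10,
                            "recent"),
              recomb_events("geneA", "r", "L", 1, 10, "ancestral"))
  counts <- gene_recombination_counts(ev)
  expect_equal(counts$recent[counts$gene_id == "geneA"], 2L)
  expect_equal(counts$ancestral[counts$gene_id == "geneA"], 1L)
  expect_equal(counts$ancestral[counts$gene_id == "geneB"], 0L)
  empty <- gene_recombination_counts(ev[0, ])
  expect_equal(nrow(empty), 0L)
  # permutation-stable group-by
  set.seed(3)
  shuf <- ev[sample(nrow(ev)), ]
  expect_equal(gene_recombination_counts(shuf), counts)
})

test_that("size statistics use the lower-median convention and count fractions", {
  ev <- recomb_events(c("a", "b", "c"), "r", "L", 1, c(100, 230, 300))
  st <- size_statistics(ev)
  expect_equal(st$median_length, 230)
  expect_equal(st$max_length, 300)
  ev2 <- recomb_events(c("a", "b"), "r", "L", 1, c(100, 600))
  expect_equal(size_statistics(ev2)$fraction_below_cutoff, 0.5)
  expect_equal(size_statistics(ev2)$median_length, 100)   # lower of the two
  expect_equal(size_statistics(ev2, median_mode = "midpoint")$median_length,
               350)
  expect_error(size_statistics(ev[0, ]), class = "panrecom_parameter_error")
})

test_that("the exponential MLE rate is consistent", {
  set.seed(99)
  lens <- pmax(1L, stats::rgeom(10000, 1 / 230) + 1L)
  ev <- recomb_events(sprintf("g%05d", seq_along(lens)), "r", "L",
                      1, lens)
  st <- size_statistics(ev)
  expect_lt(abs(st$exp_rate - 1 / 230) / (1 / 230), 0.02)
})
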