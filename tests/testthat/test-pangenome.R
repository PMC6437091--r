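# Family classification, summaries and accumulation curves.

test_that("occupancy boundaries are decided exactly", {
  mk <- function(k, n) {
    pres <- matrix(FALSE, n, 1, dimnames = list(sprintf("g%02d", 1:n), "f"))
    pres[seq_len(k), 1] <- TRUE
    pan_matrix(pres)
  }
  expect_equal(as.character(classify_families(mk(32, 32))), "core")
  expect_equal(as.character(classify_families(mk(31, 32))), "soft_core")
  expect_equal(as.character(classify_families(mk(1, 32))), "cloud")
  # 19/20 = 0.95 exactly: soft core, not shell
  expect_equal(as.character(classify_families(mk(19, 20))), "soft_core")
  # 3/20 = 0.15 exactly: shell, not cloud
  expect_equal(as.character(classify_families(mk(3, 20))), "shell")
  expect_error(classify_families(mk(2, 4), thresholds = c(cloud = 0.95,
                                                          soft_core = 0.15,
                                                          core = 0.99)),
               class = "panrecom_parameter_error")
})

test_that("classification matches the brute-force oracle and is order-invariant", {
  for (seed in 1:5) {
    pm <- toy_pan_matrix(5, 40, seed = seed, p = 0.4)
    cls <- classify_families(pm)
    expect_equal(as.character(cls), oracle_classify(pm$presence))
    # conservation
    expect_equal(sum(table(cls)), 40L)
    # genome/family reordering leaves category counts unchanged
    set.seed(seed + 100)
    perm <- pan_matrix(pm$presence[sample(nrow(pm$presence)),
                                   sample(ncol(pm$presence))])
    expect_equal(as.vector(table(classify_families(perm))),
                 as.vector(table(cls)))
  }
})

test_that("summaries count singletons and per-genome core fractions", {
  pm <- toy_pan_matrix(5, 40, seed = 7, p = 0.4)
  s <- summarize_pangenome(pm)
  expect_equal(s$n_core + s$n_soft_core + s$n_shell + s$n_cloud, s$n_pan)
  expect_equal(s$n_singletons, sum(colSums(pm$presence) == 1L))
  core_fams <- classify_families(pm) == "core"
  expect_equal(unname(s$per_genome_core_fraction[1L]),
               sum(pm$presence[1L, core_fams]) / sum(pm$presence[1L, ]))
  # single genome: everything is core
  single <- pan_matrix(matrix(TRUE, 1, 3,
                              dimnames = list("g1", c("a", "b", "c"))))
  expect_equal(summarize_pangenome(single)$pct_core, 100)
})

test_that("accumulation curves obey monotonicity and conservation", {
  pm <- toy_pan_matrix(6, 50, seed = 3, p = 0.35)
  cur <- accumulation_curves(pm, n_permutations = 20, seed = 11)
  for (p in 1:20) {
    expect_true(all(diff(cur$pan_sizes[p, ]) >= 0))
    expect_true(all(diff(cur$core_sizes[p, ]) <= 0))
    expect_equal(sum(cur$new_genes[p, ]), ncol(pm$presence))
    expect_equal(cur$new_genes[p, 1L], cur$pan_sizes[p, 1L])
    expect_equal(cur$pan_sizes[p, 1L], cur$core_sizes[p, 1L])
  }
  # determinism under a fixed seed
  expect_identical(cur, accumulation_curves(pm, 20, seed = 11))
})

test_that("three-genome curves match the exhaustive-orderings oracle", {
  pm <- toy_pan_matrix(3, 15, seed = 9, p = 0.5)
  pres <- pm$presence
  orderings <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                    c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  oracle <- lapply(orderings, function(o) {
    pan <- vapply(1:3, function(g) sum(colSums(pres[o[1:g], , drop = FALSE]) > 0), 0)
    core <- vapply(1:3, function(g) sum(colSums(pres[o[1:g], , drop = FALSE]) == g), 0)
    uniq <- vapply(1:3, function(g) sum(colSums(pres[o[1:g], , drop = FALSE]) == 1), 0)
    list(pan = pan, core = core, uniq = uniq)
  })
  cur <- accumulation_curves(pm, n_permutations = 30, seed = 4)
  for (p in 1:30) {
    hit <- any(vapply(oracle, function(or) {
      all(or$pan == cur$pan_sizes[p, ]) && all(or$core == cur$core_sizes[p, ]) &&
        all(or$uniq == cur$unique_genes[p, ])
    }, logical(1)))
    expect_true(hit)
  }
})

test_that("identical genomes give a flat pan curve with no new genes", {
  pres <- matrix(TRUE, 4, 10,
                 dimnames = list(sprintf("g%d", 1:4), sprintf("f%02d", 1:10)))
  cur <- accumulation_curves(pan_matrix(pres), 5, seed = 1)
  expect_true(all(cur$pan_sizes == 10L))
  expect_true(all(cur$new_genes[, -1L] == 0L))
})

test_that("core_min_count relaxes the accumulation core curve", {
  pres <- matrix(TRUE, 4, 6,
                 dimnames = list(sprintf("g%d", 1:4), sprintf("f%d", 1:6)))
  pres[1L, 6L] <- FALSE                    # one family missing from one genome
  pm <- pan_matrix(pres)
  strict <- accumulation_curves(pm, 3, seed = 2)
  relaxed <- accumulation_curves(pm, 3, seed = 2, core_min_count = 3L)
  expect_true(all(strict$core_sizes[, 4L] == 5L))
  expect_true(all(relaxed$core_sizes[, 4L] == 6L))
})
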