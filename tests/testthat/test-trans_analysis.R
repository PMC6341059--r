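# full-enumeration oracle for the two-sided Fisher test (sum of tables with
# hypergeometric likelihood <= observed, fixed margins)
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, n - r1, c1)
  obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

test_that("Fisher's exact test reproduces printed and enumerated values", {
  # the published trans-overlap table: heart/liver x cardiac/hepatic genes
  tab <- matrix(c(540, 63, 243, 433), 2, byrow = TRUE)
  res <- fisher_exact(tab)
  expect_lte(res$p, 2.2e-16)
  expect_gt(res$odds_ratio, 1)

  expect_equal(fisher_exact(matrix(1, 2, 2))$p, 1)
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2))$p, 2 / 252,
               tolerance = 1e-12)
  # zero margin: p = 1 by convention, odds ratio undefined
  res0 <- fisher_exact(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(res0$p, 1)
  expect_true(is.na(res0$odds_ratio))

  set.seed(31)
  for (k in 1:15) {
    tab <- matrix(sample(0:12, 4, TRUE), 2)
    if (sum(tab) == 0 || any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      next
    expect_equal(fisher_exact(tab)$p, fisher_oracle(tab), tolerance = 1e-7)
  }
})

test_that("trans overlap table counts interactions by anchor-gene overlap", {
  bins <- tiny_bins(100, res = 5000)  # c1: 0-99... two chroms of 100 bins
  genes <- make_genes(data.frame(
    id = c("gx", "gy"), chrom = c("c1", "c1"), strand = "+",
    tss = c(50000, 250000), tes = c(60000, 260000)))
  # three trans interactions: one at gx, one at gy, one at neither
  callsX <- make_iset(bins, c(10, 50, 80), c(120, 130, 140), kind = "trans")
  callsY <- make_iset(bins, 90, 150, kind = "trans")
  tab <- trans_overlap_table(callsX, callsY, "gx", "gy", genes)
  expect_equal(unname(tab["X", ]), c(1, 1))
  expect_equal(unname(tab["Y", ]), c(0, 0))

  # an interaction joining a gx gene and a gy gene counts in both cells
  both <- make_iset(bins, 10, 150, kind = "trans")
  # bin 10 covers gx? no: gx body [50000,60000) = bins 10-11. bin 150 on c2
  genes2 <- make_genes(data.frame(
    id = c("gx", "gy"), chrom = c("c1", "c2"), strand = "+",
    tss = c(50000, 250000), tes = c(60000, 260000)))
  tab2 <- trans_overlap_table(both, callsY, "gx", "gy", genes2)
  expect_equal(unname(tab2["X", ]), c(1, 1))

  # empty sets give an all-zero table
  tab0 <- trans_overlap_table(callsX, callsY, character(0), character(0),
                              genes)
  expect_true(all(tab0 == 0))
})

test_that("random-gene simulation is seed-deterministic and null-calibrated", {
  fx <- make_fixture_genome(synth_params(
    seed = 61, chrom_sizes = c(chrA = 1e6, chrB = 1e6)))
  bins <- fx$bins
  set.seed(99)
  # trans calls placed uniformly at random over the genome
  i <- sample(0:199, 120, TRUE); j <- sample(0:199, 120, TRUE)
  keep <- bins$bins$chrom[i + 1] != bins$bins$chrom[j + 1]
  calls <- make_iset(bins, pmin(i, j)[keep], pmax(i, j)[keep],
                     kind = "trans")
  p1 <- random_gene_simulation(calls, calls, 20, 20, fx$genes,
                               trans_sim_params(50, seed = 5))
  p2 <- random_gene_simulation(calls, calls, 20, 20, fx$genes,
                               trans_sim_params(50, seed = 5))
  expect_identical(p1$median_table, p2$median_table)

  # uniform placement, equal set sizes: Fisher p stays large
  ps <- vapply(1:5, function(sd)
    random_gene_simulation(calls, calls, 20, 20, fx$genes,
                           trans_sim_params(100, seed = sd))$fisher$p,
    numeric(1))
  expect_gt(mean(ps > 0.5), 0.5)

  # repetitions = 1: the median is the single draw
  one <- random_gene_simulation(calls, calls, 5, 5, fx$genes,
                                trans_sim_params(1, seed = 2))
  expect_true(all(one$median_table == floor(one$median_table)))
})

test_that("median tables stabilize as repetitions grow", {
  fx <- make_fixture_genome(synth_params(
    seed = 62, chrom_sizes = c(chrA = 1e6, chrB = 1e6)))
  bins <- fx$bins
  set.seed(3)
  i <- sample(0:99, 80, TRUE); j <- sample(100:199, 80, TRUE)
  calls <- make_iset(bins, i, j, kind = "trans")
  spread <- function(reps) {
    meds <- vapply(1:6, function(sd)
      random_gene_simulation(calls, calls, 15, 15, fx$genes,
                             trans_sim_params(reps, seed = sd))$median_table[1, 1],
      numeric(1))
    diff(range(meds))
  }
  expect_lte(spread(80), spread(5) + 1)
})

test_that("bridge classification reproduces the printed fractions", {
  # printed category counts: heart 7,884 / 20,151 / 23,335 -> AB ~ 45%;
  # liver 14,466 / 40,071 / 39,764 -> AB ~ 42%
  heart <- bridge_table(7884, 20151, 23335)
  expect_equal(round(100 * heart$fractions[["AB"]]), 45)
  liver <- bridge_table(14466, 40071, 39764)
  expect_equal(round(100 * liver$fractions[["AB"]]), 42)
  expect_equal(sum(heart$fractions), 1, tolerance = 1e-9)

  bins <- tiny_bins(10)
  tr <- make_track(bins, c(rep("A", 5), rep("B", 4), NA))
  # single AA call
  bt1 <- classify_bridges(make_iset(bins, 0, 12, kind = "trans"),
                          make_track(bins, rep("A", 20)))
  expect_equal(unname(bt1$counts), c(1, 0, 0))
  expect_equal(bt1$fractions[["AB"]], 0)

  # NA anchor label: excluded and tallied
  tr2 <- make_track(tiny_bins(10), c(rep("A", 10), rep(NA, 10)))
  bt2 <- classify_bridges(make_iset(tiny_bins(10), c(0, 1), c(12, 13),
                                    kind = "trans"), tr2)
  expect_equal(sum(bt2$counts), 0)
  expect_equal(bt2$excluded, 2)

  # anchor order within records does not change the table
  bins2 <- tiny_bins(10)
  trm <- make_track(bins2, rep(c("A", "B"), 10))
  ba <- classify_bridges(make_iset(bins2, c(0, 3), c(11, 14),
                                   kind = "trans"), trm)
  bb <- classify_bridges(make_iset(bins2, c(11, 14), c(0, 3),
                                   kind = "trans"), trm)
  expect_equal(ba$counts, bb$counts)
})
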