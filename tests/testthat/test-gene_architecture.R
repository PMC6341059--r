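test_that("median-of-ratios normalization matches the hand formula", {
  counts <- matrix(c(10, 20, 30, 100,
                     20, 40, 60, 200), ncol = 2,
                   dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  ex <- expression_table(counts, c("X", "Y"))
  nm <- normalize_expression(ex, min_total = 1)
  # second sample is exactly twice the first: size factors in ratio 2 and
  # identical normalized values (samples collapse to their organs here)
  expect_equal(nm$size_factors[["Y"]] / nm$size_factors[["X"]], 2)
  expect_equal(nm$normalized[, 1], nm$normalized[, 2])

  # hand-computed oracle on an arbitrary table
  set.seed(8)
  cts <- matrix(rpois(60, 50) + 1, ncol = 3,
                dimnames = list(paste0("g", 1:20), c("a", "b", "c")))
  loggeo <- rowMeans(log(cts))
  sf_hand <- apply(cts, 2, function(col)
    exp(median((log(col) - loggeo)[is.finite(loggeo)])))
  ex2 <- expression_table(cts, c("A", "B", "C"))
  nm2 <- normalize_expression(ex2, min_total = 1)
  expect_equal(unname(nm2$size_factors), unname(sf_hand), tolerance = 1e-12)
})

test_that("prefilter and replicate collapse follow the stated rules", {
  counts <- matrix(c(3, 50, 4, 60, 2, 70), ncol = 3,
                   dimnames = list(c("low", "high"),
                                   c("X_1", "X_2", "Y_1")))
  ex <- expression_table(counts, c("X", "X", "Y"))
  nm <- normalize_expression(ex, min_total = 10)
  expect_false("low" %in% rownames(nm$normalized))  # 3+4+2 = 9 < 10
  expect_equal(unname(nm$counts["high", "X"]), 110)  # replicates summed
  expect_error(normalize_expression(ex, min_total = 1000), "all genes")

  # single collapsed sample: identity normalization
  ex1 <- expression_table(matrix(c(5, 50), 2, 1,
                                 dimnames = list(c("a", "b"), "s")), "X")
  nm1 <- normalize_expression(ex1, min_total = 1)
  expect_equal(unname(nm1$normalized[, 1]), c(5, 50))
})

test_that("tissue enrichment uses the at-least-fivefold rule", {
  vals <- rbind(g1 = c(heart = 100, liver = 10, kidney = 5),
                g2 = c(40, 10, 9),
                g3 = c(50, 10, 2),
                g4 = c(0, 0, 0))
  sets <- designate_enriched(vals)
  expect_true("g1" %in% sets$heart)
  expect_false("g2" %in% sets$heart)   # 40 < 5 * 10
  expect_true("g3" %in% sets$heart)    # boundary: exactly 5-fold counts
  expect_false("g4" %in% unlist(sets))
  # invariant to a common positive scaling
  sets2 <- designate_enriched(vals * 37.5)
  expect_equal(sets2, sets)
})

test_that("interaction counts at genes follow the one-anchor rule", {
  bins <- tiny_bins(400, res = 5000, chroms = "c1")
  genes <- make_genes(data.frame(
    id = "g1", chrom = "c1", strand = "+", tss = 50000, tes = 64000))
  calls <- make_iset(bins, c(10, 11, 200), c(50, 80, 300))
  cnt <- interactions_at_genes(calls, genes)
  expect_equal(unname(cnt["g1"]), 2)

  # both anchors inside the gene: counts once
  calls2 <- make_iset(bins, 10, 12)
  expect_equal(unname(interactions_at_genes(calls2, genes)["g1"]), 1)

  # no interactions
  calls0 <- make_iset(bins, integer(0), integer(0))
  expect_equal(unname(interactions_at_genes(calls0, genes)["g1"]), 0)
})

test_that("log2 interaction ratios and the rank-sum comparison behave", {
  cX <- c(a = 7, b = 0, c = 3); cY <- c(a = 1, b = 0, c = 3)
  r <- log2_ratio_by_geneset(cX, cY, "a", "b", pseudocount = 1)
  expect_equal(unname(r$ratio["a"]), 2)   # log2(8/2)
  expect_equal(unname(r$ratio["b"]), 0)
  expect_true(is.na(r$p))  # sets of one gene cannot be tested

  # identical counts: all ratios 0, p = 1
  cc <- c(a = 2, b = 5, c = 1, d = 9)
  rid <- suppressWarnings(
    log2_ratio_by_geneset(cc, cc, c("a", "b"), c("c", "d")))
  expect_true(all(rid$ratio == 0))
  expect_equal(rid$p, 1)

  # planted effect: own-set genes get extra planted loops per condition
  fx <- make_fixture_genome(synth_params(
    seed = 44, chrom_sizes = c(chrA = 1.5e6, chrB = 1.5e6), depth = 1.2e6))
  mX <- ice_normalize(simulate_contact_map(fx, "X"))
  mY <- ice_normalize(simulate_contact_map(fx, "Y"))
  cisX <- call_cis_interactions(mX, fit_distance_decay(mX, b = 100))
  cisY <- call_cis_interactions(mY, fit_distance_decay(mY, b = 100))
  res <- suppressWarnings(log2_ratio_by_geneset(
    interactions_at_genes(cisX, fx$genes),
    interactions_at_genes(cisY, fx$genes),
    fx$sets$setX, fx$sets$setY))
  expect_lt(res$p, 0.05)
  expect_gt(median(res$ratioX), median(res$ratioY))
})

test_that("promoter-TES loop detection is strand-aware and anchor-symmetric", {
  bins <- tiny_bins(400, res = 5000, chroms = "c1")
  gplus <- make_genes(data.frame(id = "gp", chrom = "c1", strand = "+",
                                 tss = 100000, tes = 150000))
  # promoter window [98000, 100200): bin of 98500 = bin 19; TES bin 30
  looped <- promoter_tes_loops(make_iset(bins, 19, 30), gplus)
  expect_equal(looped, "gp")
  # promoter-to-gene-middle only: not a loop
  expect_length(promoter_tes_loops(make_iset(bins, 19, 25), gplus), 0)
  # anchor order within the record does not matter
  expect_equal(promoter_tes_loops(make_iset(bins, 30, 19), gplus), "gp")

  # minus strand: TSS 150000, promoter window [149800, 152000)
  gminus <- make_genes(data.frame(id = "gm", chrom = "c1", strand = "-",
                                  tss = 150000, tes = 100000))
  looped_m <- promoter_tes_loops(make_iset(bins, 30, 20), gminus)
  expect_equal(looped_m, "gm")  # bin 30 covers 151000; TES bin 20
})

test_that("anchor feature annotation applies precedence and doubles counts", {
  bins <- tiny_bins(100, res = 5000, chroms = "c1")
  genes <- make_genes(
    data.frame(id = c("g1", "g2"), chrom = "c1", strand = "+",
               tss = c(100000, 202000), tes = c(140000, 260000)),
    exons = data.frame(id = "g1", chrom = "c1", start = 100000,
                       end = 103000))
  # bin 20 covers [100000,105000): g1 promoter (98000..100200) + g1 exon;
  # promoter wins. bin 25 = [125000,130000): inside g1 body, no exon ->
  # intron. bin 90: gene desert -> intergenic. bin 41 = [205000,210000):
  # inside g2 body -> intron.
  calls <- make_iset(bins, c(20, 90), c(25, 41))
  feat <- annotate_anchor_features(calls, genes)
  expect_equal(sum(feat$count), 2 * 2)
  got <- setNames(feat$count, feat$class)
  expect_equal(unname(got["promoter"]), 1)
  expect_equal(unname(got["intron"]), 2)
  expect_equal(unname(got["intergenic"]), 1)
  expect_equal(sum(feat$fraction), 1, tolerance = 1e-9)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  # closed-form oracle by direct combinatorial summation
  hyper_oracle <- function(N, K, n, k) {
    sum(vapply(k:min(K, n), function(x)
      choose(K, x) * choose(N - K, n - x), numeric(1))) / choose(N, n)
  }
  universe <- paste0("g", 1:100)
  coll <- list(path = universe[1:10])
  query <- c(universe[1:5], universe[90:94])
  res <- geneset_enrichment(query, coll, universe)
  expect_equal(res$p, hyper_oracle(100, 10, 10, 5), tolerance = 1e-12)

  # zero overlap: p = 1
  res0 <- geneset_enrichment(universe[50:59], list(s = universe[1:10]),
                             universe)
  expect_equal(res0$p, 1)
  # forced complete overlap: p = 1
  resf <- geneset_enrichment(universe, list(s = universe), universe)
  expect_equal(resf$p, 1)
  expect_error(geneset_enrichment("g1", list(s = "g1"), character(0)),
               "universe")

  # random small cases against the enumeration oracle
  set.seed(13)
  for (k in 1:10) {
    N <- sample(10:30, 1)
    uni <- paste0("x", seq_len(N))
    K <- sample(2:N, 1); n <- sample(2:N, 1)
    cl <- list(c = sample(uni, K))
    qu <- sample(uni, n)
    ov <- length(intersect(qu, cl$c))
    expect_equal(geneset_enrichment(qu, cl, uni)$p,
                 hyper_oracle(N, K, n, ov), tolerance = 1e-12)
  }
})

test_that("rank-sum p matches exact permutation enumeration for small groups", {
  perm_oracle <- function(x, y) {
    # two-sided exact rank-sum by full enumeration of group assignments
    all_v <- c(x, y)
    n <- length(x)
    ranks <- rank(all_v)
    W_obs <- sum(ranks[seq_len(n)])
    combs <- combn(length(all_v), n)
    Ws <- apply(combs, 2, function(idx) sum(ranks[idx]))
    mu <- mean(Ws)
    mean(abs(Ws - mu) >= abs(W_obs - mu) - 1e-9)
  }
  set.seed(17)
  for (k in 1:8) {
    x <- round(rnorm(sample(3:6, 1)), 1)
    y <- round(rnorm(sample(3:6, 1)), 1)
    if (anyDuplicated(c(x, y))) next  # exact test defined for untied data
    got <- stats::wilcox.test(x, y)$p.value
    expect_equal(got, perm_oracle(x, y), tolerance = 1e-9)
  }
})

test_that("gene compartments and grouped expression detect planted contrast", {
  bins <- tiny_bins(100, res = 5000, chroms = "c1")
  lab <- rep(c("A", "B"), each = 50)
  tr <- make_track(bins, lab)
  set.seed(23)
  ng <- 60
  starts <- seq(5000, by = 8000, length.out = ng)
  genes <- make_genes(data.frame(
    id = sprintf("g%02d", seq_len(ng)), chrom = "c1", strand = "+",
    tss = starts, tes = starts + 4000))
  gc <- gene_compartment(genes, tr)
  expect_true(all(gc[starts + 4000 <= 250000] == "A"))

  # planted 4x expression in A genes
  inA <- gc == "A"
  mu <- ifelse(inA, 400, 100)
  counts <- matrix(rpois(ng, mu), ncol = 1,
                   dimnames = list(names(gc), "s1"))
  ex <- normalize_expression(expression_table(counts, "X"), min_total = 1)
  res <- suppressWarnings(expression_by_group(ex, list(
    A = list(genes = names(gc)[inA], organ = "X"),
    B = list(genes = names(gc)[!inA], organ = "X"))))
  expect_lt(res$tests$p, 0.01)
  expect_gt(res$summary$median[res$summary$group == "A"],
            res$summary$median[res$summary$group == "B"])

  # degenerate groups
  res2 <- expression_by_group(ex, list(
    A = list(genes = names(gc)[inA], organ = "X"),
    none = list(genes = character(0), organ = "X")))
  expect_true(is.na(res2$tests$p))
  expect_equal(res2$summary$n[2], 0)

  # compartment fractions of a set
  fr <- compartment_fractions(gc, names(gc)[inA])
  expect_equal(unname(fr["A"]), 100)
})
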