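test_that("radial positions average normalized radii across structures", {
  tads <- make_tads(rep("c1", 3), c(0, 1e5, 2e5), c(1e5, 2e5, 3e5))
  coords <- rbind(c(0, 0, 0), c(5000, 0, 0), c(0, 1250, 0))
  pop <- make_pop(coords, tads, R_nuc = 5000, S = 2)
  # mix radii 0.25 and 0.75 across two structures -> mean 0.5
  pop$coords[2, 3, ] <- c(0, 3750, 0)
  rp <- radial_positions(pop)
  expect_equal(unname(rp), c(0, 1, 0.5))
})

test_that("shell partition yields equal counts with the remainder innermost", {
  set.seed(41)
  coords <- matrix(rnorm(300), ncol = 3)
  sh <- shell_partition(coords, 5)
  expect_equal(as.vector(table(sh)), rep(20, 5))
  # remainder rule: 101 domains -> sizes 21 20 20 20 20
  sh2 <- shell_partition(matrix(rnorm(303), ncol = 3), 5)
  expect_equal(as.vector(table(sh2)), c(21, 20, 20, 20, 20))
  # the domain nearest the center lands in shell 1
  r <- sqrt(rowSums(coords^2))
  expect_equal(sh[which.min(r)], 1)
  expect_error(shell_partition(coords[1:3, ], 5), "fewer")
  # invariant to global rotation
  Q <- random_rotation()
  expect_equal(shell_partition(coords %*% Q, 5), sh)
})

test_that("shell profiles are normalized and detect forced placements", {
  tads <- make_tads(rep("c1", 10), seq(0, 9e5, 1e5), seq(1e5, 1e6, 1e5),
                    label = rep(c("A", "B"), each = 5))
  # all A inside 0.3 R, all B outside
  dirs <- matrix(rnorm(30), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  rr <- c(runif(5, 0.05, 0.29), runif(5, 0.5, 0.99)) * 5000
  pop <- make_pop(dirs * rr, tads, S = 3)
  pr <- shell_localization_profile(pop, tads$label)
  expect_equal(rowSums(pr$mean), c(A = 1, B = 1), tolerance = 1e-9)
  # 10 domains, 5 shells -> 2 per shell; A occupies shells 1-2/3 exactly
  expect_equal(sum(pr$mean["A", 1:3]), 1)
  expect_equal(sum(pr$mean["B", 4:5]), 0.8, tolerance = 1e-9)
  expect_true(all(pr$sd == 0))  # identical structures
})

test_that("isotropic unlabeled-bias populations give near-uniform profiles", {
  fx <- make_fixture_genome(synth_params(seed = 51, beta = 0))
  tads <- fx$tad_truth
  set.seed(1)
  tads$label <- sample(c("A", "B"), nrow(tads), TRUE)
  pop <- simulate_structure_population(fx, tads, S = 200)
  pr <- shell_localization_profile(pop, tads$label)
  # binomial spread per cell: sqrt(p(1-p)/n_label) / sqrt(S)
  for (L in c("A", "B")) {
    nl <- sum(tads$label == L)
    tol <- 3 * sqrt(0.2 * 0.8 / nl) / sqrt(200)
    expect_true(all(abs(pr$mean[L, ] - 0.2) < 3 * tol + 0.02))
  }
})

test_that("radial bias produces monotone A/B shell profiles", {
  fx <- make_fixture_genome(synth_params(seed = 52, beta = -3))
  tads <- fx$tad_truth
  tads$label <- rep(c("A", "B"), length.out = nrow(tads))
  pop <- simulate_structure_population(fx, tads, S = 100)
  pr <- shell_localization_profile(pop, tads$label)
  expect_true(all(diff(pr$mean["A", ]) <= 0))
  expect_true(all(diff(pr$mean["B", ]) >= 0))
})

test_that("trans neighbor composition counts labeled cross-chromosome domains", {
  # constructed fixture: an A query with 3 A and 1 B trans neighbors
  tads <- make_tads(c("c1", rep("c2", 4)), rep(0:4 * 1e5, 1)[1:5],
                    rep(1:5 * 1e5, 1)[1:5],
                    label = c("A", "A", "A", "A", "B"))
  coords <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0), c(0, 0, 100),
                  c(100, 100, 0))
  pop <- make_pop(coords, tads, R_nuc = 5000)
  res <- trans_neighbor_composition(pop, tads$label,
                                    shell_params(threshold = 500))
  a_row <- res$composition[res$composition$query_label == "A", ]
  # the c1 query sees 3 A + 1 B; c2 domains see only the c1 A domain
  expect_equal(a_row$pctA, mean(c(3 / 4, 1, 1, 1)) * 100)
  expect_equal(a_row$pctA + a_row$pctB, 100)

  # chromosomes too far apart: no neighbors, NaN composition
  coords_far <- rbind(c(-4000, 0, 0), matrix(rep(c(4000, 0, 0), 4),
                                             ncol = 3, byrow = TRUE))
  pop_far <- make_pop(coords_far, tads, R_nuc = 5000)
  res_far <- trans_neighbor_composition(pop_far, c("A", "B", "B", "B", "B"),
                                        shell_params(threshold = 500))
  expect_true(is.nan(res_far$composition$pctA[1]))
})

test_that("geometric statistics are invariant to rotation and joint scaling", {
  fx <- make_fixture_genome(synth_params(seed = 53))
  tads <- fx$tad_truth
  tads$label <- rep(c("A", "B"), length.out = nrow(tads))
  pop <- simulate_structure_population(fx, tads, S = 10)
  set.seed(2)
  Q <- random_rotation()
  pop_rot <- pop
  for (s in seq_len(pop$S))
    pop_rot$coords[s, , ] <- pop$coords[s, , , drop = TRUE] %*% Q
  expect_equal(radial_positions(pop_rot), radial_positions(pop),
               tolerance = 1e-12)
  nb1 <- trans_neighbor_composition(pop, tads$label)
  nb2 <- trans_neighbor_composition(pop_rot, tads$label)
  expect_equal(nb2$composition$pctA, nb1$composition$pctA,
               tolerance = 1e-9)
  # joint scaling of coordinates and R_nuc leaves radial positions unchanged
  pop_sc <- pop
  pop_sc$coords <- pop$coords * 2.5
  pop_sc$R_nuc <- pop$R_nuc * 2.5
  expect_equal(radial_positions(pop_sc), radial_positions(pop))
})

test_that("gene-centric shell profiles restrict to gene-bearing domains", {
  fx <- make_fixture_genome(synth_params(seed = 54))
  tads <- fx$tad_truth
  tads$label <- rep(c("A", "B"), length.out = nrow(tads))
  pop <- simulate_structure_population(fx, tads, S = 20)
  # a set covering every gene gives domains spanning most of the genome
  allg <- list(all = fx$genes$genes$id)
  pr <- gene_shell_profile(pop, fx$genes, allg)
  expect_equal(sum(pr$mean["all", ]), 1, tolerance = 1e-9)
  # empty set: NA row
  pr0 <- gene_shell_profile(pop, fx$genes, list(none = character(0)))
  expect_true(all(is.na(pr0$mean["none", ])))

  # centrally biased membership concentrates mass in inner shells
  rp <- radial_positions(pop)
  dom_mid <- (tads$start + tads$end) / 2
  g <- fx$genes$genes
  central_doms <- which(rank(rp) <= nrow(tads) / 3)
  members <- g$id[vapply(seq_len(nrow(g)), function(k) {
    mid <- (g$start[k] + g$end[k]) / 2
    any(tads$chrom[central_doms] == g$chrom[k] &
          tads$start[central_doms] <= mid & mid < tads$end[central_doms])
  }, logical(1))]
  prc <- gene_shell_profile(pop, fx$genes, list(central = members))
  expect_gt(sum(prc$mean["central", 1:2]), sum(prc$mean["central", 4:5]))
})
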