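#' Parameters of the synthetic-data generators
#'
#' Defaults describe a two-chromosome miniature genome with the statistical
#' features the analyses assume: power-law cis distance decay, checkerboard
#' compartments, block-diagonal TADs, per-bin coverage biases, planted
#' enriched bin pairs, overdispersed tissue-biased expression, and structure
#' populations with a tunable radial compartment bias.
#'
#' @param seed Master seed; every generator is a pure function of
#'   (params, seed).
#' @param chrom_sizes Named chromosome lengths in bp.
#' @param resolution Bin width in bp.
#' @param alpha Distance-decay exponent (cis rate ~ d^-alpha).
#' @param comp_block Compartment block length in bins (checkerboard period).
#' @param contrast Within- vs between-compartment (and within-TAD) rate ratio.
#' @param tad_range Min/max TAD length in bins.
#' @param loops List of planted loops, each `list(chrom=, i=, j=, fold=)`
#'   with i/j local bin indices (0-based).
#' @param bias_sigma Lognormal sigma of per-bin coverage biases.
#' @param depth Total expected contact count (cis + trans).
#' @param trans_frac Trans baseline rate as a fraction of the
#'   shortest-distance cis rate (default 0.01).
#' @param n_gene_loops Promoter-TES loops planted per condition at genes of
#'   that condition's organ set (default 40).
#' @param gene_loop_fold Enrichment of planted gene loops (default 10).
#' @param n_trans_loops Enriched trans bin pairs per condition: half anchored
#'   at own-organ-set genes, half uniform (default 80).
#' @param trans_loop_fold Enrichment of planted trans pairs (default 20).
#' @param switch_frac Fraction of compartment blocks flipped in condition Y.
#' @param n_genes Number of genes to place.
#' @param set_size Genes per planted organ set.
#' @param expr_fold Expression fold of planted set genes in their organ.
#' @param expr_disp Gamma overdispersion of expression counts.
#' @param beta Radial preference strength for compartment A (negative =
#'   interior); B uses `-beta`.
#' @param R_nuc Nuclear radius in nm.
#' @export
synth_params <- function(seed = 1,
                         chrom_sizes = c(chrA = 2.5e6, chrB = 2.5e6),
                         resolution = 5000,
                         alpha = 1.0,
                         comp_block = 10,
                         contrast = 2,
                         tad_range = c(8, 15),
                         loops = list(),
                         bias_sigma = 0.3,
                         depth = 2e6,
                         trans_frac = 0.01,
                         n_gene_loops = 40,
                         gene_loop_fold = 10,
                         n_trans_loops = 80,
                         trans_loop_fold = 20,
                         switch_frac = 0.1,
                         n_genes = 240,
                         set_size = 50,
                         expr_fold = 6,
                         expr_disp = 0.02,
                         beta = 0,
                         R_nuc = 5000) {
  stopifnot(alpha > 0, contrast >= 1, depth > 0, expr_fold >= 1,
            length(chrom_sizes) >= 2)
  as.list(environment())
}

#' Generate the fixture genome: assembly, bins, genes, organ gene sets
#'
#' Compartment labels form an A/B checkerboard of `comp_block` bins (per
#' condition; condition Y flips a seeded `switch_frac` of blocks); TAD blocks
#' tile each chromosome with lengths drawn from `tad_range`. Genes are placed
#' preferentially in A blocks (70%); the two disjoint organ sets are planted
#' inside blocks that are A in their own condition.
#'
#' @param params `synth_params()`.
#' @return List: `assembly`, `bins` (`BinTable`), `genes` (`GeneTable`),
#'   `sets` (list setX / setY), `comp_labels` (list X / Y, per bin),
#'   `tad_truth` (`TADSet`), `boundary_bins` (per chromosome local indices),
#'   `params`.
#' @export
make_fixture_genome <- function(params = synth_params()) {
  set.seed(params$seed)
  assembly <- genome_assembly(names(params$chrom_sizes),
                              params$chrom_sizes)
  bins <- bin_table(assembly, params$resolution)
  nb <- n_bins(bins)
  # checkerboard compartments, condition X
  block <- bins$bins$start %/% (params$comp_block * params$resolution)
  labX <- ifelse(block %% 2 == 0, "A", "B")
  # condition Y: flip a fraction of blocks (whole blocks, seeded)
  blk_key <- paste(bins$bins$chrom, block)
  blocks <- unique(blk_key)
  n_flip <- round(length(blocks) * params$switch_frac)
  flipped <- sample(blocks, n_flip)
  labY <- ifelse(blk_key %in% flipped,
                 ifelse(labX == "A", "B", "A"), labX)
  # TAD truth: tile each chromosome with blocks of random length
  tad_rows <- list(); boundary_bins <- list()
  for (cm in assembly$chrom) {
    sp <- bin_span(bins, cm)
    nloc <- sp["n"]
    lens <- integer(0); tot <- 0
    while (tot < nloc) {
      l <- sample(params$tad_range[1]:params$tad_range[2], 1)
      lens <- c(lens, min(l, nloc - tot))
      tot <- tot + l
    }
    ends <- cumsum(lens)
    starts <- c(0, head(ends, -1))
    tad_rows[[cm]] <- data.frame(
      chrom = cm, start = starts * params$resolution,
      end = pmin(ends * params$resolution, params$chrom_sizes[[cm]]),
      stringsAsFactors = FALSE)
    boundary_bins[[cm]] <- head(ends, -1)  # local bin index of first bin after
  }
  tad_truth <- do.call(rbind, tad_rows)
  tad_truth$id <- sprintf("TAD_%04d", seq_len(nrow(tad_truth)))
  tad_truth$label <- NA_character_
  rownames(tad_truth) <- NULL
  class(tad_truth) <- c("TADSet", "data.frame")
  # genes: 70% in A-blocks of X, strand mix; organ sets planted in own-A blocks
  res <- params$resolution
  gene_rows <- list()
  pickA <- runif(params$n_genes) < 0.7
  binsA <- which(labX == "A"); binsB <- which(labX == "B")
  for (k in seq_len(params$n_genes)) {
    home <- if (pickA[k]) sample(binsA, 1) else sample(binsB, 1)
    cm <- bins$bins$chrom[home]
    glen <- round(runif(1, 3000, 30000))
    gstart <- bins$bins$start[home] + sample.int(res, 1) - 1
    gend <- min(gstart + glen, params$chrom_sizes[[cm]] - 1)
    strand <- sample(c("+", "-"), 1)
    gene_rows[[k]] <- data.frame(
      id = sprintf("gene_%04d", k), chrom = cm, strand = strand,
      tss = if (strand == "+") gstart else gend,
      tes = if (strand == "+") gend else gstart,
      stringsAsFactors = FALSE)
  }
  genes_df <- do.call(rbind, gene_rows)
  # exons: split each gene body into 2-4 exons covering ~half the body
  ex_rows <- list()
  for (k in seq_len(nrow(genes_df))) {
    s <- min(genes_df$tss[k], genes_df$tes[k])
    e <- max(genes_df$tss[k], genes_df$tes[k])
    nex <- sample(2:4, 1)
    cuts <- sort(runif(nex * 2, s, e))
    for (x in seq_len(nex)) {
      ex_rows[[length(ex_rows) + 1]] <- data.frame(
        id = genes_df$id[k], chrom = genes_df$chrom[k],
        start = floor(cuts[2 * x - 1]), end = ceiling(cuts[2 * x]),
        stringsAsFactors = FALSE)
    }
  }
  gt <- new_gene_table(genes_df, do.call(rbind, ex_rows))
  # organ sets: setX genes lying in A-of-X blocks, setY in A-of-Y blocks
  g <- gt$genes
  home_bin <- bin_of(bins, g$chrom, pmin(g$start, params$chrom_sizes[g$chrom] - 1))
  inAX <- labX[home_bin + 1L] == "A"
  inAY <- labY[home_bin + 1L] == "A"
  candX <- which(inAX)
  setX <- g$id[sample(candX, min(params$set_size, length(candX)))]
  candY <- setdiff(which(inAY), match(setX, g$id))
  setY <- g$id[sample(candY, min(params$set_size, length(candY)))]
  # planted enriched bin pairs per condition:
  #  - promoter-TES loops at own-organ-set genes (testable pairs only,
  #    i.e. promoter and TES bins >= 2 bins apart)
  #  - trans pairs, half anchored at own-set gene bins, half uniform
  prom_bin <- bin_of(bins, g$chrom, pmax(g$tss, 0))
  tes_bin <- bin_of(bins, g$chrom, pmin(g$tes, params$chrom_sizes[g$chrom] - 1))
  plant_for <- function(set_ids) {
    rows <- match(set_ids, g$id)
    eligible <- abs(prom_bin[rows] - tes_bin[rows]) >= 2
    take <- rows[order(!eligible)][seq_len(min(params$n_gene_loops,
                                               length(rows)))]
    # each looped gene gets a small cluster of enriched promoter-anchored
    # pairs: the promoter-TES contact where testable (separation >= 2 bins)
    # plus flanking enhancer-like contacts around the gene end
    cis_lp <- do.call(rbind, lapply(take, function(rw) {
      pb <- prom_bin[rw]; tb <- tes_bin[rw]
      span <- bin_span(bins, g$chrom[rw])
      cand <- tb + c(0L, 2L, -2L, 3L, -3L)
      cand <- cand[cand >= span["first"] & cand < span["first"] + span["n"] &
                     abs(cand - pb) >= 2]
      cand <- cand[seq_len(min(5, length(cand)))]
      data.frame(i = pmin(pb, cand), j = pmax(pb, cand),
                 fold = params$gene_loop_fold)
    }))
    if (params$n_trans_loops < 1)
      return(rbind(cis_lp,
                   data.frame(i = integer(), j = integer(),
                              fold = numeric())))
    # trans pairs: anchor bins of set genes to a uniform bin on another chrom
    n_half <- params$n_trans_loops %/% 2
    anchors <- sample(rep(prom_bin[rows], length.out = n_half))
    partners <- vapply(anchors, function(a) {
      other <- which(bins$bins$chrom != bins$bins$chrom[a + 1L]) - 1L
      sample(other, 1)
    }, integer(1))
    u1 <- sample.int(nb, params$n_trans_loops - n_half) - 1L
    u2 <- vapply(u1, function(a) {
      other <- which(bins$bins$chrom != bins$bins$chrom[a + 1L]) - 1L
      sample(other, 1)
    }, integer(1))
    trans_lp <- data.frame(i = pmin(c(anchors, u1), c(partners, u2)),
                           j = pmax(c(anchors, u1), c(partners, u2)),
                           fold = params$trans_loop_fold)
    rbind(cis_lp, trans_lp)
  }
  planted_loops <- list(X = plant_for(setX), Y = plant_for(setY))
  list(assembly = assembly, bins = bins, genes = gt,
       sets = list(setX = setX, setY = setY),
       comp_labels = list(X = labX, Y = labY),
       planted_loops = planted_loops,
       tad_truth = tad_truth, boundary_bins = boundary_bins,
       params = params)
}

#' Simulate a raw Hi-C contact map for one condition
#'
#' Expected cis rate of a pair is `d^-alpha` times `contrast` when the bins
#' share a compartment label, times `contrast` when they share a TAD, times
#' the bin biases; trans pairs get a small constant baseline times the
#' compartment factor and biases. Planted loop pairs are multiplied by their
#' fold. Rates are scaled to the total depth and counts drawn Poisson.
#'
#' @param fixture From [make_fixture_genome()].
#' @param condition `"X"` or `"Y"` (selects the compartment pattern and a
#'   condition-specific seed stream).
#' @param params Defaults to the fixture's params.
#' @param loops Planted loops for this condition (default `params$loops`).
#' @return A raw `ContactMap`; the true bias vector is attached as attribute
#'   `true_biases`.
#' @export
simulate_contact_map <- function(fixture, condition = "X",
                                 params = fixture$params,
                                 loops = params$loops) {
  offset <- if (condition == "X") 1000L else 2000L
  set.seed(params$seed + offset)
  bins <- fixture$bins
  nb <- n_bins(bins)
  lab <- fixture$comp_labels[[condition]]
  res <- params$resolution
  biases <- exp(rnorm(nb, 0, params$bias_sigma))
  # TAD membership per bin
  tadid <- rep(NA_integer_, nb)
  tt <- fixture$tad_truth
  for (k in seq_len(nrow(tt))) {
    sel <- bins$bins$chrom == tt$chrom[k] & bins$bins$start >= tt$start[k] &
      bins$bins$start < tt$end[k]
    tadid[sel] <- k
  }
  ii <- integer(0); jj <- integer(0); rate <- numeric(0)
  for (cm in fixture$assembly$chrom) {
    sp <- bin_span(bins, cm)
    first <- sp["first"]; nloc <- sp["n"]
    li <- unlist(lapply(seq_len(nloc - 1), function(a) rep(a, nloc - a)))
    lj <- unlist(lapply(seq_len(nloc - 1), function(a) (a + 1):nloc))
    gi <- first + li - 1L; gj <- first + lj - 1L
    d <- (lj - li)
    r <- d^(-params$alpha)
    r <- r * ifelse(lab[gi + 1L] == lab[gj + 1L], params$contrast, 1)
    r <- r * ifelse(!is.na(tadid[gi + 1L]) & tadid[gi + 1L] == tadid[gj + 1L],
                    params$contrast, 1)
    r <- r * biases[gi + 1L] * biases[gj + 1L]
    ii <- c(ii, gi); jj <- c(jj, gj); rate <- c(rate, r)
  }
  # trans: all cross-chromosome pairs at a small baseline
  chroms <- fixture$assembly$chrom
  for (a in seq_along(chroms)) for (b in seq_along(chroms)) {
    if (b <= a) next
    spa <- bin_span(bins, chroms[a]); spb <- bin_span(bins, chroms[b])
    gi <- rep(spa["first"] + seq_len(spa["n"]) - 1L, each = spb["n"])
    gj <- rep(spb["first"] + seq_len(spb["n"]) - 1L, times = spa["n"])
    r <- params$trans_frac *
      ifelse(lab[gi + 1L] == lab[gj + 1L], params$contrast, 1) *
      biases[gi + 1L] * biases[gj + 1L]
    ii <- c(ii, gi); jj <- c(jj, gj); rate <- c(rate, r)
  }
  # planted loops: fixture-level enriched pairs plus explicit extras
  plant <- fixture$planted_loops[[condition]]
  if (is.null(plant)) plant <- data.frame(i = integer(), j = integer(),
                                          fold = numeric())
  for (lp in loops) {
    sp <- bin_span(bins, lp$chrom)
    plant <- rbind(plant, data.frame(i = sp["first"] + min(lp$i, lp$j),
                                     j = sp["first"] + max(lp$i, lp$j),
                                     fold = lp$fold))
  }
  if (nrow(plant)) {
    pos <- match(paste(plant$i, plant$j), paste(ii, jj))
    ok <- !is.na(pos)
    rate[pos[ok]] <- rate[pos[ok]] * plant$fold[ok]
  }
  lambda <- rate / sum(rate) * params$depth
  if (max(lambda) < 0.5)
    warning("depth too small to populate any pair reliably")
  counts <- rpois(length(lambda), lambda)
  keep <- counts > 0
  map <- contact_map(bins, data.frame(i = ii[keep], j = jj[keep],
                                      count = counts[keep]))
  attr(map, "true_biases") <- biases
  map
}

#' Simulate replicate expression counts for two organs
#'
#' Counts are Poisson-gamma (negative-binomial-like): per-gene baseline means
#' are lognormal; planted set genes have `expr_fold` higher means in their
#' own organ; per-replicate library sizes vary mildly.
#'
#' @param fixture From [make_fixture_genome()].
#' @param params Defaults to the fixture's params.
#' @param replicates Named counts of replicates, e.g. `c(X = 3, Y = 2)`.
#' @return An `ExpressionTable` of raw counts with organ labels.
#' @export
simulate_expression_counts <- function(fixture, params = fixture$params,
                                       replicates = c(X = 3, Y = 2)) {
  set.seed(params$seed + 3000L)
  g <- fixture$genes$genes
  ng <- nrow(g)
  base <- exp(rnorm(ng, log(300), 1))
  meanX <- base * ifelse(g$id %in% fixture$sets$setX, params$expr_fold, 1)
  meanY <- base * ifelse(g$id %in% fixture$sets$setY, params$expr_fold, 1)
  organ <- rep(names(replicates), replicates)
  counts <- matrix(0L, ng, length(organ),
                   dimnames = list(g$id, paste0(organ, "_rep",
                                                unlist(lapply(replicates, seq_len)))))
  for (s in seq_along(organ)) {
    mu <- if (organ[s] == "X") meanX else meanY
    libfac <- exp(rnorm(1, 0, 0.1))
    shape <- 1 / params$expr_disp
    lam <- rgamma(ng, shape = shape, scale = mu * libfac / shape)
    counts[, s] <- rpois(ng, lam)
  }
  expression_table(counts, organ)
}

#' Write a complete synthetic fixture directory
#'
#' Generates the fixture genome, both conditions' contact maps, expression
#' counts, labeled TAD truth and a structure population, and writes them in
#' the package's plain-text formats (HiC-Pro triplets, TSV gene table, GMT
#' sets, count TSV, structure TSV) plus a YAML manifest with the seed and
#' parameters.
#'
#' @param params `synth_params()`.
#' @param out_dir Output directory (created).
#' @param S Structures to simulate (default 50).
#' @return Invisibly, the fixture list.
#' @export
simulate_fixture_bundle <- function(params = synth_params(), out_dir,
                                    S = 50) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fx <- make_fixture_genome(params)
  for (cond in c("X", "Y")) {
    m <- simulate_contact_map(fx, cond)
    write_contact_map(m, file.path(out_dir, paste0("map_", cond, ".matrix")),
                      file.path(out_dir, paste0("map_", cond, "_abs.bed")))
  }
  write_gene_table(fx$genes, file.path(out_dir, "genes.tsv"))
  write_gmt(fx$sets, file.path(out_dir, "organ_sets.gmt"))
  expr <- simulate_expression_counts(fx)
  write.table(data.frame(gene = rownames(expr$counts), expr$counts),
              file.path(out_dir, "expression_counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tads <- fx$tad_truth
  tads$label <- ifelse(fx$comp_labels$X[bin_of(fx$bins, tads$chrom,
                                               tads$start) + 1L] == "A",
                       "A", "B")
  write_tads(tads, file.path(out_dir, "tads_truth.tsv"))
  pop <- simulate_structure_population(fx, tads, S)
  write_structure_population(pop, file.path(out_dir, "structures.tsv"))
  yaml::write_yaml(list(seed = params$seed, S = S,
                        params = params[setdiff(names(params), "loops")]),
                   file.path(out_dir, "manifest.yaml"))
  invisible(fx)
}

# inverse-CDF sampler for radial density ~ r^2 * exp(c * r) on [0, 1]
sample_radius <- function(n, c_bias, grid = 512) {
  r <- seq(0, 1, length.out = grid)
  dens <- r^2 * exp(c_bias * r)
  cdf <- cumsum(dens); cdf <- cdf / cdf[grid]
  u <- runif(n)
  r[findInterval(u, cdf) + 1]
}

#' Simulate a 3D structure population over labeled TADs
#'
#' Per structure, each chromosome is laid out as a random-walk chain of TAD
#' center directions; each TAD's radial coordinate is drawn from a density
#' proportional to `r^2 exp(c r)` with `c = beta` for compartment A domains
#' and `c = -beta` for B (negative beta pulls A inward). All points lie
#' inside the nuclear sphere.
#'
#' @param fixture From [make_fixture_genome()] (only the seed stream is used).
#' @param tads Labeled `TADSet` (A/B/NA per domain).
#' @param S Number of structures.
#' @param params Defaults to the fixture's params.
#' @return A `StructurePopulation`.
#' @export
simulate_structure_population <- function(fixture, tads, S,
                                          params = fixture$params) {
  if (S < 1) stop("S must be >= 1")
  set.seed(params$seed + 4000L)
  T <- nrow(tads)
  cA <- params$beta
  cB <- -params$beta
  coords <- array(NA_real_, c(S, T, 3))
  for (s in seq_len(S)) {
    for (cm in unique(tads$chrom)) {
      idx <- which(tads$chrom == cm)
      # correlated directions along the chain
      dir <- matrix(rnorm(3), 1, 3)
      dir <- dir / sqrt(sum(dir^2))
      dirs <- matrix(0, length(idx), 3)
      dirs[1, ] <- dir
      for (k in seq_along(idx)[-1]) {
        step <- dirs[k - 1, ] + 0.5 * rnorm(3)
        dirs[k, ] <- step / sqrt(sum(step^2))
      }
      cbias <- ifelse(is.na(tads$label[idx]), 0,
                      ifelse(tads$label[idx] == "A", cA, cB))
      rr <- numeric(length(idx))
      for (cb in unique(cbias)) {
        sel <- cbias == cb
        rr[sel] <- sample_radius(sum(sel), cb)
      }
      coords[s, idx, ] <- dirs * rr * params$R_nuc
    }
  }
  structure_population(coords, tads, params$R_nuc)
}
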