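#' Permutation-simulation parameters
#' @param repetitions Number of random-gene draws (default 10000).
#' @param seed Random seed.
#' @export
trans_sim_params <- function(repetitions = 10000, seed = 1) {
  stopifnot(repetitions >= 1)
  list(repetitions = repetitions, seed = seed)
}

# interactions in `calls` with >= 1 anchor bin overlapping the body of >= 1
# gene of `set`
n_overlapping_calls <- function(calls, set, genes) {
  r <- calls$records
  if (!nrow(r)) return(0L)
  g <- genes$genes[genes$genes$id %in% set, , drop = FALSE]
  if (!nrow(g)) return(0L)
  hits <- anchor_hits(calls, g[, c("chrom", "start", "end")])
  sum(hits[, 1] | hits[, 2])
}

#' Overlap table of trans interactions at two gene sets
#'
#' Cell (condition, set) counts the interactions of that condition with at
#' least one anchor bin overlapping at least one gene body of the set; an
#' interaction may contribute to both sets' cells.
#'
#' @param callsX,callsY Trans `InteractionSet`s for the two conditions.
#' @param setX,setY Gene id vectors.
#' @param genes A `GeneTable`.
#' @return 2x2 integer matrix, rows = conditions (X, Y), columns = sets.
#' @export
trans_overlap_table <- function(callsX, callsY, setX, setY, genes) {
  if (!nrow(callsX$records)) warning("condition X has no trans calls")
  if (!nrow(callsY$records)) warning("condition Y has no trans calls")
  m <- matrix(c(n_overlapping_calls(callsX, setX, genes),
                n_overlapping_calls(callsX, setY, genes),
                n_overlapping_calls(callsY, setX, genes),
                n_overlapping_calls(callsY, setY, genes)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("X", "Y"), c("setX", "setY")))
  m
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p by summation of hypergeometric probabilities no larger than
#' that of the observed table; the odds ratio is the sample estimate
#' `ad / bc`.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List `p`, `odds_ratio` (Inf when bc = 0, NA when both products are
#'   0 or a margin is zero).
#' @export
fisher_exact <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (a * d == 0 && b * c == 0) NA_real_
  else if (b * c == 0) Inf else (a * d) / (b * c)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(list(p = 1, odds_ratio = NA_real_))
  p <- stats::fisher.test(round(table))$p.value
  list(p = p, odds_ratio = or)
}

#' Random-gene permutation simulation of the trans overlap table
#'
#' Per repetition, `nX` and `nY` genes are sampled uniformly without
#' replacement (independently per set) from the universe and the overlap
#' table recomputed; the per-cell median across repetitions (rounded half-up)
#' is reported together with its Fisher test. Fully determined by the seed.
#'
#' @param callsX,callsY Trans `InteractionSet`s.
#' @param nX,nY Number of genes to draw for each set.
#' @param genes `GeneTable`; the sampling universe is all its genes.
#' @param params `trans_sim_params()`.
#' @return List `median_table`, `fisher` (list p / odds_ratio), `repetitions`,
#'   `seed`.
#' @export
random_gene_simulation <- function(callsX, callsY, nX, nY, genes,
                                   params = trans_sim_params()) {
  universe <- genes$genes$id
  stopifnot(nX <= length(universe), nY <= length(universe))
  set.seed(params$seed)
  # precompute per-gene anchor hits once: interactions x genes incidence
  per_gene_hit <- function(calls) {
    g <- genes$genes
    r <- calls$records
    b <- calls$bins$bins
    if (!nrow(r)) return(matrix(FALSE, 0, nrow(g)))
    a1 <- data.frame(chrom = r$chrom1, start = b$start[r$bin1 + 1L],
                     end = b$end[r$bin1 + 1L])
    a2 <- data.frame(chrom = r$chrom2, start = b$start[r$bin2 + 1L],
                     end = b$end[r$bin2 + 1L])
    body <- g[, c("chrom", "start", "end")]
    inc <- matrix(FALSE, nrow(r), nrow(g))
    ov1 <- overlap_features(a1, body)
    ov2 <- overlap_features(a2, body)
    inc[cbind(ov1$a_idx, ov1$b_idx)] <- TRUE
    inc[cbind(ov2$a_idx, ov2$b_idx)] <- TRUE
    inc
  }
  incX <- per_gene_hit(callsX)
  incY <- per_gene_hit(callsY)
  tallies <- matrix(0, params$repetitions, 4)
  ng <- length(universe)
  for (rep_k in seq_len(params$repetitions)) {
    sx <- sample.int(ng, nX)
    sy <- sample.int(ng, nY)
    tallies[rep_k, ] <- c(
      sum(rowSums(incX[, sx, drop = FALSE]) > 0),
      sum(rowSums(incX[, sy, drop = FALSE]) > 0),
      sum(rowSums(incY[, sx, drop = FALSE]) > 0),
      sum(rowSums(incY[, sy, drop = FALSE]) > 0))
  }
  med <- apply(tallies, 2, median)
  med <- floor(med + 0.5)  # half-up
  mtab <- matrix(med, nrow = 2, byrow = TRUE,
                 dimnames = list(c("X", "Y"), c("setX", "setY")))
  list(median_table = mtab, fisher = fisher_exact(mtab),
       repetitions = params$repetitions, seed = params$seed)
}

#' Bridge table from A/B pair counts
#'
#' @param AA,BB,AB Counts of trans interactions whose anchors are both A,
#'   both B, or one of each.
#' @param excluded Interactions dropped for carrying an NA anchor label.
#' @return A `BridgeTable`: counts plus fractions over classified calls.
#' @export
bridge_table <- function(AA, BB, AB, excluded = 0) {
  tot <- AA + BB + AB
  fr <- if (tot > 0) c(AA = AA, BB = BB, AB = AB) / tot else
    c(AA = NA_real_, BB = NA_real_, AB = NA_real_)
  structure(list(counts = c(AA = AA, BB = BB, AB = AB),
                 fractions = fr, excluded = excluded),
            class = "BridgeTable")
}

#' @export
print.BridgeTable <- function(x, ...) {
  cat(sprintf("BridgeTable: AA %d, BB %d, AB %d (AB fraction %.1f%%; %d excluded)\n",
              x$counts["AA"], x$counts["BB"], x$counts["AB"],
              100 * x$fractions["AB"], x$excluded))
  invisible(x)
}

#' Classify trans interactions by their anchors' compartments
#'
#' Each call becomes AA, BB, or AB from the track labels of its two anchor
#' bins; calls with any NA anchor label are excluded and tallied separately.
#'
#' @param calls A trans `InteractionSet`.
#' @param track A `CompartmentTrack` on the same bin table.
#' @return A `BridgeTable`.
#' @export
classify_bridges <- function(calls, track) {
  r <- calls$records
  l1 <- track$label[r$bin1 + 1L]
  l2 <- track$label[r$bin2 + 1L]
  ok <- !is.na(l1) & !is.na(l2)
  both <- paste0(pmin(l1[ok], l2[ok]), pmax(l1[ok], l2[ok]))
  bridge_table(AA = sum(both == "AA"), BB = sum(both == "BB"),
               AB = sum(both == "AB"), excluded = sum(!ok))
}
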