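#' Iterative correction (ICE) of a contact map
#'
#' Alternating-scaling balancing: per-bin bias factors `B` are found such that
#' the balanced matrix `w_ij = raw_ij / (B_i B_j)` has equal marginal sums
#' (mean 1) over covered bins. Bins with zero coverage are masked (bias NA).
#'
#' @param map A raw-count `ContactMap`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance: max-norm relative change of the bias
#'   vector between iterations (default 1e-5).
#' @return The map with `biases` set; attributes `converged` and `iterations`
#'   record the run.
#' @export
ice_normalize <- function(map, max_iter = 200, tol = 1e-5) {
  stopifnot(max_iter >= 1, tol > 0)
  if (map$total <= 0) stop("cannot balance an all-zero contact map")
  n <- n_bins(map$bins)
  e <- map$entries
  B <- rep(1, n)
  # symmetric marginals from upper-triangular entries (diagonal counted once)
  marginal <- function(vals) {
    m <- numeric(n)
    inc <- rowsum(vals, e$i, reorder = FALSE)
    m[as.integer(rownames(inc)) + 1L] <- m[as.integer(rownames(inc)) + 1L] + inc
    off <- e$i != e$j
    if (any(off)) {
      inc2 <- rowsum(vals[off], e$j[off], reorder = FALSE)
      m[as.integer(rownames(inc2)) + 1L] <-
        m[as.integer(rownames(inc2)) + 1L] + inc2
    }
    m
  }
  covered <- marginal(e$count) > 0
  if (!any(covered)) stop("cannot balance an all-zero contact map")
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    w <- e$count / (B[e$i + 1L] * B[e$j + 1L])
    m <- marginal(w)
    s <- m / mean(m[covered])
    s[!covered | s == 0] <- 1
    B <- B * s
    delta <- max(abs(s[covered] - 1))
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("ICE did not converge in %d iterations (last delta %.2e)",
                    max_iter, delta))
  # rescale so balanced marginals have mean 1
  w <- e$count / (B[e$i + 1L] * B[e$j + 1L])
  B <- B * sqrt(mean(marginal(w)[covered]))
  B[!covered] <- NA_real_
  out <- map
  out$biases <- B
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  out
}

# Weighted pooled-adjacent-violators for a NON-INCREASING fit.
# Returns the fitted values; preserves the weighted sum.
pav_nonincreasing <- function(y, w) {
  n <- length(y)
  if (n <= 1) return(y)
  val <- y; wt <- w; size <- rep(1L, n)
  k <- 0
  for (i in seq_len(n)) {
    k <- k + 1
    val[k] <- y[i]; wt[k] <- w[i]; size[k] <- 1L
    while (k > 1 && val[k - 1] < val[k]) {
      tw <- wt[k - 1] + wt[k]
      val[k - 1] <- (val[k - 1] * wt[k - 1] + val[k] * wt[k]) / tw
      wt[k - 1] <- tw
      size[k - 1] <- size[k - 1] + size[k]
      k <- k - 1
    }
  }
  rep(val[seq_len(k)], size[seq_len(k)])
}

#' Fit the equal-occupancy distance-decay background
#'
#' Tested cis pairs (same chromosome, separation >= `min_sep` bins) are sorted
#' by genomic distance and split into `b` bins of near-equal pair counts
#' (whole distance groups are never split). The mean contact probability per
#' bin, `f(d) = sum(bias-corrected counts) / (total corrected count * pairs in
#' bin)`, is made non-increasing by weighted pooled-adjacent-violators. Prior
#' probabilities over all tested pairs sum to 1.
#'
#' @param map A cis `ContactMap` (uses ICE biases when present).
#' @param b Number of distance bins (default 200).
#' @param min_sep Minimum pair separation in bins (default 2: self and
#'   adjacent pairs excluded).
#' @return A `DecayModel`: data frame `d_min d_max npairs f` plus attributes
#'   `total_count`, `min_sep`, `resolution`.
#' @export
fit_distance_decay <- function(map, b = 200, min_sep = 2) {
  stopifnot(b >= 1, min_sep >= 0)
  bt <- map$bins
  res <- bt$resolution
  B <- map$biases
  usable <- if (is.null(B)) rep(TRUE, n_bins(bt)) else !is.na(B)
  # possible tested pairs per separation, summed over chromosomes
  chroms <- unique(bt$bins$chrom)
  npairs <- integer(0)  # indexed by separation in bins
  for (cm in chroms) {
    sp <- bin_span(bt, cm)
    nc_usable <- bt$bins$index[bt$bins$chrom == cm]
    ok <- usable[nc_usable + 1L]
    nloc <- sp["n"]
    if (nloc <= min_sep) next
    seps <- min_sep:(nloc - 1)
    # count usable pairs at each separation
    cnt <- vapply(seps, function(s) {
      sum(ok[seq_len(nloc - s)] & ok[seq_len(nloc - s) + s])
    }, numeric(1))
    old <- length(npairs)
    if (max(seps) > old) npairs <- c(npairs, integer(max(seps) - old))
    npairs[seps] <- npairs[seps] + cnt
  }
  seps <- which(npairs > 0)
  if (!length(seps)) stop("no tested pairs at min_sep = ", min_sep)
  # observed bias-corrected counts per separation
  e <- map$entries
  same <- chrom_of_bin(bt, e$i) == chrom_of_bin(bt, e$j)
  sep_e <- e$j - e$i
  keep <- same & sep_e >= min_sep
  if (!is.null(B)) keep <- keep & !is.na(B[e$i + 1L]) & !is.na(B[e$j + 1L])
  vals <- e$count[keep]
  if (!is.null(B)) vals <- vals / (B[e$i[keep] + 1L] * B[e$j[keep] + 1L])
  csum <- numeric(length(npairs))
  if (length(vals)) {
    agg <- rowsum(vals, sep_e[keep], reorder = FALSE)
    csum[as.integer(rownames(agg))] <- agg[, 1]
  }
  total <- sum(csum)
  if (total <= 0) stop("no contacts among tested pairs")
  if (length(seps) < b) {
    warning(sprintf("only %d distinct distances; reducing b from %d",
                    length(seps), b))
    b <- length(seps)
  }
  # equal-occupancy assignment of whole distance groups
  cum <- cumsum(npairs[seps])
  tot_pairs <- cum[length(cum)]
  binid <- pmin(b, ceiling(cum / tot_pairs * b))
  binid <- match(binid, unique(binid))  # densify
  d_min <- tapply(seps, binid, min) * res
  d_max <- tapply(seps, binid, max) * res
  np <- as.numeric(tapply(npairs[seps], binid, sum))
  cs <- as.numeric(tapply(csum[seps], binid, sum))
  f <- cs / (total * np)
  f <- pav_nonincreasing(f, np)
  f <- f / sum(f * np)  # defensive renormalization; PAV preserves the sum
  model <- data.frame(d_min = as.numeric(d_min), d_max = as.numeric(d_max),
                      npairs = np, f = f)
  attr(model, "total_count") <- total
  attr(model, "min_sep") <- min_sep
  attr(model, "resolution") <- res
  class(model) <- c("DecayModel", "data.frame")
  model
}

#' Evaluate a decay model at genomic distances
#' @param model A `DecayModel`.
#' @param d Genomic distances in bp.
#' @return Per-pair prior contact probability f(d); NA outside the fitted span.
#' @export
decay_prob <- function(model, d) {
  idx <- findInterval(d, model$d_min)
  out <- rep(NA_real_, length(d))
  ok <- idx >= 1 & d <= model$d_max[pmax(idx, 1)]
  out[ok] <- model$f[idx[ok]]
  out
}
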