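#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, capped at 1, mapped back to input
#' order.
#'
#' @param p P-values in `[0, 1]`.
#' @param m Number of tests (default `length(p)`; pass a larger m when the
#'   supplied vector omits tests with p = 1).
#' @return Q-values in input order.
#' @export
bh_adjust <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  if (!n) return(numeric(0))
  ord <- order(p)
  q <- pmin(1, rev(cummin(rev(m * p[ord] / seq_len(n)))))
  out <- numeric(n)
  out[ord] <- q
  out
}

#' Significance caller parameters
#' @param b Distance bins for the decay model (default 200).
#' @param q_max Significance threshold (default 0.01).
#' @param min_sep Minimum cis pair separation in bins (default 2).
#' @export
caller_params <- function(b = 200, q_max = 0.01, min_sep = 2) {
  stopifnot(q_max > 0, q_max < 1, b >= 1)
  list(b = b, q_max = q_max, min_sep = min_sep)
}

# shared tail-test: upper-tail binomial p-values over tested pairs
binomial_tail <- function(k, N, prob) {
  p <- stats::pbinom(k - 1, N, prob, lower.tail = FALSE)
  zero_prior <- prob == 0 & k > 0
  if (any(zero_prior)) {
    warning(sprintf("%d pairs have zero prior but nonzero counts (model misfit)",
                    sum(zero_prior)))
    p[zero_prior] <- 0
  }
  p
}

#' Call significant cis interactions
#'
#' All same-chromosome bin pairs with separation >= `min_sep` and defined
#' biases are tested. The prior probability of pair (i, j) is proportional to
#' `f(d_ij) * B_i * B_j`, normalized to sum to 1 over tested pairs; the
#' p-value is the upper-tail binomial probability `P(X >= k_ij)` with `N` the
#' total raw count over tested pairs; q-values are Benjamini-Hochberg over the
#' full cis test family.
#'
#' @param map Raw-count `ContactMap` with `biases` set (or NULL for unbiased).
#' @param decay `DecayModel` fitted on the same map.
#' @param params `caller_params()`.
#' @param keep_all Return all tested nonzero pairs, not only `q < q_max`
#'   (zero-count pairs always have p = 1 and are never significant).
#' @return An `InteractionSet` of kind `"cis"`.
#' @export
call_cis_interactions <- function(map, decay, params = caller_params(),
                                  keep_all = FALSE) {
  bt <- map$bins
  res <- bt$resolution
  B <- if (is.null(map$biases)) rep(1, n_bins(bt)) else map$biases
  min_sep <- attr(decay, "min_sep")
  if (is.null(min_sep)) min_sep <- params$min_sep
  pairs <- list(); kn <- 0
  for (cm in unique(bt$bins$chrom)) {
    sp <- bin_span(bt, cm)
    first <- sp["first"]; nloc <- sp["n"]
    if (nloc <= min_sep) next
    # enumerate all (i, j) with j - i >= min_sep
    li <- unlist(lapply(seq_len(nloc - min_sep), function(a) rep(a, nloc - a - min_sep + 1)))
    lj <- unlist(lapply(seq_len(nloc - min_sep), function(a) (a + min_sep):nloc))
    kn <- kn + 1
    pairs[[kn]] <- data.frame(i = first + li - 1L, j = first + lj - 1L,
                              chrom = cm, stringsAsFactors = FALSE)
  }
  if (!kn) return(new_interaction_set("cis", empty_records(), res, bt))
  pr <- do.call(rbind, pairs)
  ok <- !is.na(B[pr$i + 1L]) & !is.na(B[pr$j + 1L])
  pr <- pr[ok, , drop = FALSE]
  if (!nrow(pr)) return(new_interaction_set("cis", empty_records(), res, bt))
  d <- (pr$j - pr$i) * res
  f <- decay_prob(decay, d)
  f[is.na(f)] <- 0
  prior <- f * B[pr$i + 1L] * B[pr$j + 1L]
  prior <- prior / sum(prior)
  # observed counts
  e <- map$entries
  key_pairs <- paste(pr$i, pr$j)
  cnt <- numeric(nrow(pr))
  mt <- match(paste(e$i, e$j), key_pairs)
  hit <- !is.na(mt)
  cnt[mt[hit]] <- e$count[hit]
  N <- sum(cnt)
  p <- binomial_tail(cnt, N, prior)
  q <- bh_adjust(p)
  keep <- if (keep_all) cnt > 0 else q < params$q_max
  rec <- data.frame(bin1 = pr$i[keep], bin2 = pr$j[keep],
                    chrom1 = pr$chrom[keep], chrom2 = pr$chrom[keep],
                    count = cnt[keep], p_exp = prior[keep],
                    p = p[keep], q = q[keep])
  new_interaction_set("cis", rec, res, bt)
}

empty_records <- function() {
  data.frame(bin1 = integer(), bin2 = integer(),
             chrom1 = character(), chrom2 = character(),
             count = numeric(), p_exp = numeric(),
             p = numeric(), q = numeric())
}

#' Call significant trans interactions
#'
#' Only cross-chromosome pairs are tested; the prior is proportional to
#' `B_i * B_j` with no distance term. By default the test family consists of
#' the observed (nonzero) trans pairs, which is anti-conservative for the
#' multiple-testing correction; `n_zero_pairs` adds a seeded sample of
#' zero-count pairs to the family.
#'
#' @param map Raw-count `ContactMap` with biases.
#' @param params `caller_params()`.
#' @param n_zero_pairs Number of zero-count trans pairs to include in the test
#'   family (default 0).
#' @param zero_seed Seed for the zero-pair sample.
#' @param keep_all Return all tested pairs regardless of q.
#' @return An `InteractionSet` of kind `"trans"`.
#' @export
call_trans_interactions <- function(map, params = caller_params(),
                                    n_zero_pairs = 0, zero_seed = 1,
                                    keep_all = FALSE) {
  bt <- map$bins
  B <- if (is.null(map$biases)) rep(1, n_bins(bt)) else map$biases
  e <- map$entries
  chrom_i <- chrom_of_bin(bt, e$i)
  chrom_j <- chrom_of_bin(bt, e$j)
  sel <- chrom_i != chrom_j & !is.na(B[e$i + 1L]) & !is.na(B[e$j + 1L])
  tested <- data.frame(i = e$i[sel], j = e$j[sel], count = e$count[sel],
                       chrom1 = chrom_i[sel], chrom2 = chrom_j[sel],
                       stringsAsFactors = FALSE)
  if (n_zero_pairs > 0 && nrow(tested)) {
    set.seed(zero_seed)
    seen <- paste(tested$i, tested$j)
    add <- 0; ztry <- 0
    zi <- integer(0); zj <- integer(0)
    nb <- n_bins(bt)
    while (add < n_zero_pairs && ztry < 20) {
      ztry <- ztry + 1
      ci <- sample.int(nb, n_zero_pairs, replace = TRUE) - 1L
      cj <- sample.int(nb, n_zero_pairs, replace = TRUE) - 1L
      a <- pmin(ci, cj); b2 <- pmax(ci, cj)
      ok <- chrom_of_bin(bt, a) != chrom_of_bin(bt, b2) &
        !is.na(B[a + 1L]) & !is.na(B[b2 + 1L]) &
        !(paste(a, b2) %in% seen)
      a <- a[ok]; b2 <- b2[ok]
      take <- min(length(a), n_zero_pairs - add)
      zi <- c(zi, a[seq_len(take)]); zj <- c(zj, b2[seq_len(take)])
      seen <- c(seen, paste(a[seq_len(take)], b2[seq_len(take)]))
      add <- add + take
    }
    if (length(zi)) {
      tested <- rbind(tested,
                      data.frame(i = zi, j = zj, count = 0,
                                 chrom1 = chrom_of_bin(bt, zi),
                                 chrom2 = chrom_of_bin(bt, zj),
                                 stringsAsFactors = FALSE))
    }
  }
  if (!nrow(tested))
    return(new_interaction_set("trans", empty_records(), bt$resolution, bt))
  prior <- B[tested$i + 1L] * B[tested$j + 1L]
  prior <- prior / sum(prior)
  N <- sum(tested$count)
  p <- binomial_tail(tested$count, N, prior)
  q <- bh_adjust(p)
  keep <- if (keep_all) rep(TRUE, nrow(tested)) else q < params$q_max
  rec <- data.frame(bin1 = tested$i[keep], bin2 = tested$j[keep],
                    chrom1 = tested$chrom1[keep], chrom2 = tested$chrom2[keep],
                    count = tested$count[keep], p_exp = prior[keep],
                    p = p[keep], q = q[keep])
  new_interaction_set("trans", rec, bt$resolution, bt)
}
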