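#' Shell / neighbor parameters
#' @param n_shells Number of equal-count concentric shells (default 5).
#' @param threshold Trans-neighbor distance threshold in nm (default 500).
#' @export
shell_params <- function(n_shells = 5, threshold = 500) {
  stopifnot(n_shells >= 2, threshold > 0)
  list(n_shells = n_shells, threshold = threshold)
}

#' Mean normalized radial position of each domain
#'
#' @param pop A `StructurePopulation`.
#' @return Numeric vector in `[0, 1]` per domain (0 = nuclear center,
#'   1 = periphery), averaged over structures.
#' @export
radial_positions <- function(pop) {
  r <- sqrt(pop$coords[, , 1]^2 + pop$coords[, , 2]^2 + pop$coords[, , 3]^2)
  out <- colMeans(matrix(r, nrow = pop$S)) / pop$R_nuc
  names(out) <- pop$domains$id
  out
}

#' Partition one structure's domains into equal-count radial shells
#'
#' Domains are ranked by radius (ties broken by domain order) and split into
#' `n_shells` consecutive rank blocks; with `T` domains the first `T mod n`
#' shells receive one extra member. Shell 1 is innermost.
#'
#' @param coords Matrix T x 3 of one structure's coordinates.
#' @param n_shells Number of shells.
#' @return Integer shell index per domain.
#' @export
shell_partition <- function(coords, n_shells) {
  T <- nrow(coords)
  if (T < n_shells) stop("fewer domains than shells")
  r <- sqrt(rowSums(coords^2))
  ord <- order(r, seq_len(T))
  sizes <- rep(T %/% n_shells, n_shells)
  extra <- T %% n_shells
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  shell <- integer(T)
  shell[ord] <- rep(seq_len(n_shells), sizes)
  shell
}

#' Shell localization profile of compartments
#'
#' Per structure, domains are partitioned into equal-count shells; for each
#' compartment label and shell, the probability that a domain of that label
#' lies in that shell. Mean and standard deviation are taken across
#' structures.
#'
#' @param pop A `StructurePopulation`.
#' @param labels Compartment label per domain (NA excluded).
#' @param params `shell_params()`.
#' @return A `ShellProfile`: list of `mean` and `sd` matrices
#'   (labels x shells).
#' @export
shell_localization_profile <- function(pop, labels, params = shell_params()) {
  labs <- sort(unique(labels[!is.na(labels)]))
  if (!length(labs)) stop("no labeled domains")
  n_sh <- params$n_shells
  acc <- array(NA_real_, c(pop$S, length(labs), n_sh))
  for (s in seq_len(pop$S)) {
    shell <- shell_partition(pop$coords[s, , , drop = TRUE], n_sh)
    for (li in seq_along(labs)) {
      sel <- which(labels == labs[li])
      tot <- length(sel)
      cnt <- tabulate(shell[sel], nbins = n_sh)
      acc[s, li, ] <- cnt / tot
    }
  }
  mu <- apply(acc, c(2, 3), mean)
  sdv <- apply(acc, c(2, 3), sd)
  dimnames(mu) <- dimnames(sdv) <-
    list(labs, paste0("shell", seq_len(n_sh)))
  structure(list(mean = mu, sd = sdv, n_shells = n_sh, S = pop$S),
            class = "ShellProfile")
}

#' @export
print.ShellProfile <- function(x, ...) {
  cat(sprintf("ShellProfile over %d structures:\n", x$S))
  print(round(x$mean, 3))
  invisible(x)
}

#' Compartment composition of interchromosomal neighbors
#'
#' For each query domain in each structure, neighbors are the domains on
#' other chromosomes within `threshold` nm (center-to-center). The fraction
#' of A (and B) among labeled neighbors is averaged over structures per query
#' domain (structures with zero neighbors are excluded for that query), then
#' over query domains of each label. A second statistic reports the fraction
#' of queries whose majority neighbor label matches their own (ties count as
#' non-matching).
#'
#' @param pop A `StructurePopulation` whose domains carry chromosomes.
#' @param labels Compartment label per domain.
#' @param params `shell_params()`.
#' @return List: `composition` data frame (`query_label pctA pctB n_queries`)
#'   and `majority` data frame (`query_label pct_same_majority`).
#' @export
trans_neighbor_composition <- function(pop, labels, params = shell_params()) {
  T <- nrow(pop$domains)
  chrom <- pop$domains$chrom
  diff_chrom <- outer(chrom, chrom, "!=")
  isA <- !is.na(labels) & labels == "A"
  isB <- !is.na(labels) & labels == "B"
  pctA_acc <- matrix(NA_real_, pop$S, T)
  match_acc <- matrix(NA_real_, pop$S, T)
  for (s in seq_len(pop$S)) {
    D <- as.matrix(stats::dist(pop$coords[s, , , drop = TRUE]))
    nb <- D <= params$threshold & diff_chrom
    nA <- as.vector(nb %*% isA)
    nB <- as.vector(nb %*% isB)
    tot <- nA + nB
    has <- tot > 0
    pctA_acc[s, has] <- nA[has] / tot[has]
    match_acc[s, has & isA] <- (nA > nB)[has & isA]
    match_acc[s, has & isB] <- (nB > nA)[has & isB]
  }
  per_query_pctA <- colMeans(pctA_acc, na.rm = TRUE)
  per_query_match <- colMeans(match_acc, na.rm = TRUE)
  comp <- do.call(rbind, lapply(c("A", "B"), function(L) {
    sel <- !is.na(labels) & labels == L & !is.nan(per_query_pctA)
    data.frame(query_label = L,
               pctA = 100 * mean(per_query_pctA[sel]),
               pctB = 100 * (1 - mean(per_query_pctA[sel])),
               n_queries = sum(sel))
  }))
  maj <- do.call(rbind, lapply(c("A", "B"), function(L) {
    sel <- !is.na(labels) & labels == L & !is.nan(per_query_match)
    data.frame(query_label = L,
               pct_same_majority = 100 * mean(per_query_match[sel]))
  }))
  list(composition = comp, majority = maj)
}

#' Shell profile of domains carrying genes of given sets
#'
#' Genes are mapped to domains by body-midpoint containment; for each set the
#' shell localization profile of the domains holding at least one member gene
#' is computed.
#'
#' @param pop A `StructurePopulation`.
#' @param genes A `GeneTable`.
#' @param sets Named list of gene id vectors.
#' @param params `shell_params()`.
#' @return A `ShellProfile` with one row per set (NA row when a set maps to
#'   no domain).
#' @export
gene_shell_profile <- function(pop, genes, sets, params = shell_params()) {
  dom <- pop$domains
  g <- genes$genes
  mid <- floor((g$start + g$end) / 2)
  gene_dom <- rep(NA_integer_, nrow(g))
  for (k in seq_len(nrow(dom))) {
    sel <- g$chrom == dom$chrom[k] & mid >= dom$start[k] & mid < dom$end[k]
    gene_dom[sel] <- k
  }
  names(gene_dom) <- g$id
  profs <- list()
  for (nm in names(sets)) {
    doms <- unique(gene_dom[names(gene_dom) %in% sets[[nm]]])
    doms <- doms[!is.na(doms)]
    if (!length(doms)) {
      profs[[nm]] <- matrix(NA_real_, 1, params$n_shells)
      next
    }
    labels <- rep(NA_character_, nrow(dom))
    labels[doms] <- nm
    pr <- shell_localization_profile(pop, labels, params)
    profs[[nm]] <- list(mean = pr$mean[1, ], sd = pr$sd[1, ])
  }
  mu <- do.call(rbind, lapply(profs, function(p)
    if (is.list(p)) p$mean else p[1, ]))
  sdv <- do.call(rbind, lapply(profs, function(p)
    if (is.list(p)) p$sd else p[1, ]))
  rownames(mu) <- rownames(sdv) <- names(sets)
  colnames(mu) <- colnames(sdv) <- paste0("shell", seq_len(params$n_shells))
  structure(list(mean = mu, sd = sdv, n_shells = params$n_shells, S = pop$S),
            class = "ShellProfile")
}

#' Write a shell profile as TSV
#' @param profile A `ShellProfile`.
#' @param path Output path.
#' @export
write_shell_profile <- function(profile, path) {
  df <- data.frame(label = rownames(profile$mean), profile$mean,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(profile)
}

#' Per-chromosome radial position profile
#'
#' Mean radial position of each domain keyed by chromosome and start
#' coordinate, for plotting radial profiles along chromosomes.
#'
#' @param pop A `StructurePopulation`.
#' @return Data frame `chrom start end id radial`.
#' @export
radial_profile_table <- function(pop) {
  data.frame(chrom = pop$domains$chrom, start = pop$domains$start,
             end = pop$domains$end, id = pop$domains$id,
             radial = unname(radial_positions(pop)))
}
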