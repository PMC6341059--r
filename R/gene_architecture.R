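#' Loop / enrichment parameter bundles
#'
#' @param upstream,downstream Promoter window extent around the TSS in
#'   transcription direction (defaults 2000 / 200 bp).
#' @export
loop_params <- function(upstream = 2000, downstream = 200) {
  stopifnot(upstream >= 0, downstream >= 0)
  list(upstream = upstream, downstream = downstream)
}

#' @rdname loop_params
#' @param fold Tissue-enrichment fold threshold (default 5).
#' @param pseudocount Pseudocount for log2 interaction ratios (default 1).
#' @export
enrichment_params <- function(fold = 5, pseudocount = 1) {
  stopifnot(fold > 1, pseudocount > 0)
  list(fold = fold, pseudocount = pseudocount)
}

#' Construct an expression table
#' @param counts Integer matrix genes x samples (rownames = gene ids).
#' @param organ Character vector: organ label per sample.
#' @export
expression_table <- function(counts, organ) {
  stopifnot(ncol(counts) == length(organ), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  structure(list(counts = counts, organ = organ, normalized = NULL),
            class = "ExpressionTable")
}

#' Filter, collapse and normalize expression counts
#'
#' Genes with fewer than `min_total` reads summed across all samples are
#' removed; replicates are collapsed by summation per organ; the collapsed
#' samples are normalized by median-of-ratios size factors (the DESeq2
#' scheme), yielding one normalized value per gene per organ.
#'
#' @param expr An `ExpressionTable` of raw replicate counts.
#' @param min_total Prefilter threshold (default 10).
#' @return The table with `normalized` set (matrix genes x organs) and the
#'   filtered/collapsed counts.
#' @export
normalize_expression <- function(expr, min_total = 10) {
  keep <- rowSums(expr$counts) >= min_total
  if (!any(keep)) stop("all genes removed by the prefilter")
  counts <- expr$counts[keep, , drop = FALSE]
  organs <- unique(expr$organ)
  collapsed <- vapply(organs, function(o) {
    rowSums(counts[, expr$organ == o, drop = FALSE])
  }, numeric(nrow(counts)))
  if (!is.matrix(collapsed))
    collapsed <- matrix(collapsed, nrow = nrow(counts),
                        dimnames = list(rownames(counts), organs))
  if (any(colSums(collapsed) == 0)) stop("an organ has all-zero counts")
  if (ncol(collapsed) == 1) {
    sf <- 1
  } else {
    sf <- DESeq2::estimateSizeFactorsForMatrix(collapsed)
  }
  normalized <- sweep(collapsed, 2, sf, "/")
  structure(list(counts = collapsed, organ = organs, normalized = normalized,
                 size_factors = sf, n_filtered = sum(!keep)),
            class = "ExpressionTable")
}

#' Designate tissue-enriched genes
#'
#' A gene is assigned to tissue t iff its value there is at least
#' `fold` times the maximum over all other tissues. Genes at zero everywhere
#' are unassigned.
#'
#' @param values Matrix genes x tissues of normalized expression
#'   (rownames = gene ids); needs >= 2 tissues.
#' @param params `enrichment_params()`.
#' @return Named list (per tissue) of enriched gene id vectors.
#' @export
designate_enriched <- function(values, params = enrichment_params()) {
  stopifnot(ncol(values) >= 2)
  out <- lapply(seq_len(ncol(values)), function(t) {
    other_max <- apply(values[, -t, drop = FALSE], 1, max)
    hit <- values[, t] >= params$fold * other_max & values[, t] > 0
    rownames(values)[hit]
  })
  names(out) <- colnames(values)
  out
}

# bins overlapped by a set of intervals -> logical over anchors
anchor_hits <- function(iset, intervals) {
  b <- iset$bins$bins
  r <- iset$records
  hit_bin <- rep(FALSE, nrow(b))
  if (nrow(intervals)) {
    ov <- overlap_features(intervals, b[, c("chrom", "start", "end")])
    hit_bin[unique(ov$b_idx)] <- TRUE
  }
  cbind(a1 = hit_bin[r$bin1 + 1L], a2 = hit_bin[r$bin2 + 1L])
}

#' Count significant interactions at each gene
#'
#' An interaction counts for a gene when at least one anchor bin overlaps the
#' gene body; an interaction with both anchors in the same gene counts once.
#'
#' @param calls An `InteractionSet`.
#' @param genes A `GeneTable`.
#' @return Named integer vector: interactions per gene.
#' @export
interactions_at_genes <- function(calls, genes) {
  g <- genes$genes
  out <- setNames(integer(nrow(g)), g$id)
  r <- calls$records
  if (!nrow(r) || !nrow(g)) return(out)
  b <- calls$bins$bins
  a1 <- data.frame(chrom = r$chrom1, start = b$start[r$bin1 + 1L],
                   end = b$end[r$bin1 + 1L])
  a2 <- data.frame(chrom = r$chrom2, start = b$start[r$bin2 + 1L],
                   end = b$end[r$bin2 + 1L])
  body <- g[, c("chrom", "start", "end")]
  ov1 <- overlap_features(a1, body)
  ov2 <- overlap_features(a2, body)
  pairs <- unique(rbind(ov1, ov2))  # (interaction, gene), counted once
  if (nrow(pairs)) {
    tab <- table(pairs$b_idx)
    out[as.integer(names(tab))] <- as.integer(tab)
  }
  out
}

#' Per-gene log2 interaction ratios and the between-set rank-sum test
#'
#' For each gene, `r = log2((countX + pc) / (countY + pc))`; the ratio
#' distributions restricted to two gene sets are compared by a two-sided
#' Wilcoxon rank-sum test.
#'
#' @param countsX,countsY Named per-gene interaction counts from the two
#'   conditions (same gene universe).
#' @param setX,setY Character vectors of gene ids.
#' @param pseudocount Added to both counts (default 1).
#' @return List: `ratio` (all genes), `ratioX`, `ratioY` (per set), `p`
#'   (two-sided rank-sum p; NA if either set has < 2 resolvable members).
#' @export
log2_ratio_by_geneset <- function(countsX, countsY, setX, setY,
                                  pseudocount = 1) {
  stopifnot(identical(names(countsX), names(countsY)))
  r <- log2((countsX + pseudocount) / (countsY + pseudocount))
  rx <- r[names(r) %in% setX]
  ry <- r[names(r) %in% setY]
  p <- if (length(rx) >= 2 && length(ry) >= 2) ranksum_p(rx, ry) else
    NA_real_
  list(ratio = r, ratioX = rx, ratioY = ry, p = p)
}

# two-sided rank-sum p; completely tied data carries no evidence (p = 1)
ranksum_p <- function(x, y) {
  p <- stats::wilcox.test(x, y)$p.value
  if (is.nan(p)) 1 else p
}

#' Detect promoter-to-TES gene loops
#'
#' A gene is looped when at least one significant cis interaction has one
#' anchor bin overlapping the promoter window (strand-aware) and the other
#' anchor bin containing the TES coordinate.
#'
#' @param calls A cis `InteractionSet`.
#' @param genes A `GeneTable`.
#' @param params `loop_params()`.
#' @return Character vector of looped gene ids.
#' @export
promoter_tes_loops <- function(calls, genes, params = loop_params()) {
  r <- calls$records
  g <- genes$genes
  if (!nrow(r) || !nrow(g)) return(character(0))
  bt <- calls$bins
  prom <- promoter_windows(genes, params$upstream, params$downstream)
  b <- bt$bins
  # per gene: promoter bins (any overlap) and the single TES bin
  ovp <- overlap_features(prom[, c("chrom", "start", "end")],
                          b[, c("chrom", "start", "end")])
  # the TES is a point; for + strand genes it is the half-open body end and
  # may fall in the bin after the last body bin (clamped at chromosome ends)
  tes_bin <- bin_of(bt, g$chrom, g$tes)
  clamp <- is.na(tes_bin)
  tes_bin[clamp] <- bin_of(bt, g$chrom[clamp], g$tes[clamp] - 1)
  looped <- logical(nrow(g))
  # index anchors by bin for fast lookup
  for (k in seq_len(nrow(g))) {
    pbins <- ovp$b_idx[ovp$a_idx == k] - 1L  # 0-based bin ids
    tb <- tes_bin[k]
    if (!length(pbins) || is.na(tb)) next
    hit <- (r$bin1 %in% pbins & r$bin2 == tb) |
      (r$bin2 %in% pbins & r$bin1 == tb)
    looped[k] <- any(hit)
  }
  g$id[looped]
}

#' Annotate interaction anchors by genomic feature
#'
#' Every anchor (two per interaction) gets exactly one class with precedence
#' promoter > exon > intron > intergenic: any promoter overlap wins, else any
#' exon overlap, else any gene-body overlap is intron, else intergenic.
#'
#' @param calls An `InteractionSet`.
#' @param genes A `GeneTable`.
#' @param params `loop_params()` (promoter window).
#' @return Data frame `class count fraction`; counts sum to 2x the number of
#'   interactions.
#' @export
annotate_anchor_features <- function(calls, genes, params = loop_params()) {
  r <- calls$records
  classes <- c("promoter", "exon", "intron", "intergenic")
  if (!nrow(r)) {
    return(data.frame(class = classes, count = 0, fraction = NA_real_))
  }
  prom <- promoter_windows(genes, params$upstream, params$downstream)
  hp <- anchor_hits(calls, prom[, c("chrom", "start", "end")])
  he <- anchor_hits(calls, genes$exons[, c("chrom", "start", "end"),
                                       drop = FALSE])
  hb <- anchor_hits(calls, genes$genes[, c("chrom", "start", "end")])
  classify <- function(p, e, bdy) {
    ifelse(p, "promoter", ifelse(e, "exon", ifelse(bdy, "intron",
                                                   "intergenic")))
  }
  anchors <- c(classify(hp[, 1], he[, 1], hb[, 1]),
               classify(hp[, 2], he[, 2], hb[, 2]))
  counts <- table(factor(anchors, classes))
  data.frame(class = classes, count = as.numeric(counts),
             fraction = as.numeric(counts) / length(anchors))
}

#' Hypergeometric gene-set enrichment
#'
#' Upper-tail hypergeometric test of the overlap between a query set and each
#' collection, within a universe; BH q-values appended, rows sorted by p.
#'
#' @param query Character vector of gene ids (will be intersected with the
#'   universe).
#' @param collections Named list of gene id vectors.
#' @param universe Character vector of gene ids.
#' @return Data frame `collection n_collection n_query overlap p q`.
#' @export
geneset_enrichment <- function(query, collections, universe) {
  if (!length(universe)) stop("empty universe")
  universe <- unique(universe)
  query <- intersect(query, universe)
  rows <- lapply(names(collections), function(nm) {
    coll <- intersect(collections[[nm]], universe)
    k <- length(intersect(query, coll))
    p <- stats::phyper(k - 1, length(coll), length(universe) - length(coll),
                       length(query), lower.tail = FALSE)
    data.frame(collection = nm, n_collection = length(coll),
               n_query = length(query), overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign each gene a compartment label by majority vote over its body bins
#' @param genes A `GeneTable`.
#' @param track A `CompartmentTrack`.
#' @return Named character vector (A/B/NA) per gene.
#' @export
gene_compartment <- function(genes, track) {
  g <- genes$genes
  b <- track$bins$bins
  out <- setNames(rep(NA_character_, nrow(g)), g$id)
  ov <- overlap_features(g[, c("chrom", "start", "end")],
                         b[, c("chrom", "start", "end")])
  for (k in seq_len(nrow(g))) {
    bins <- ov$b_idx[ov$a_idx == k]
    if (!length(bins)) next
    lab <- track$label[bins]
    nA <- sum(lab == "A", na.rm = TRUE)
    nB <- sum(lab == "B", na.rm = TRUE)
    if (nA + nB == 0) next
    if (nA > nB) out[k] <- "A"
    else if (nB > nA) out[k] <- "B"
    else {
      mu <- mean(track$value[bins], na.rm = TRUE)
      if (is.finite(mu) && mu > 0) out[k] <- "A"
      else if (is.finite(mu) && mu < 0) out[k] <- "B"
    }
  }
  out
}

#' Compare expression between gene groups
#'
#' Generic grouped comparison used for the compartment- and
#' switch-stratified expression analyses: each group is a set of genes and a
#' column of the normalized expression matrix; groups are summarized and
#' compared pairwise by two-sided Wilcoxon rank-sum tests.
#'
#' @param expr A normalized `ExpressionTable`.
#' @param groups Named list; each element is `list(genes = <ids>,
#'   organ = <column>)`.
#' @return List: `summary` data frame (`group n median`) and `tests` data
#'   frame (`group1 group2 p`; NA when a group has < 2 genes).
#' @export
expression_by_group <- function(expr, groups) {
  if (is.null(expr$normalized)) stop("expression table is not normalized")
  vals <- lapply(groups, function(gr) {
    v <- expr$normalized[rownames(expr$normalized) %in% gr$genes, gr$organ]
    unname(v)
  })
  summary <- data.frame(group = names(groups),
                        n = vapply(vals, length, numeric(1)),
                        median = vapply(vals, function(v)
                          if (length(v)) median(v) else NA_real_, numeric(1)))
  combos <- if (length(groups) >= 2) utils::combn(names(groups), 2) else
    matrix(character(0), 2, 0)
  tests <- data.frame(group1 = character(), group2 = character(),
                      p = numeric())
  for (k in seq_len(ncol(combos))) {
    v1 <- vals[[combos[1, k]]]; v2 <- vals[[combos[2, k]]]
    p <- if (length(v1) >= 2 && length(v2) >= 2) ranksum_p(v1, v2) else
      NA_real_
    tests <- rbind(tests, data.frame(group1 = combos[1, k],
                                     group2 = combos[2, k], p = p))
  }
  list(summary = summary, tests = tests)
}

#' Compartment fractions of a gene set
#' @param gene_labels Named A/B/NA labels from [gene_compartment()].
#' @param set Character vector of gene ids.
#' @return Named numeric: percent of labeled set genes in A and in B.
#' @export
compartment_fractions <- function(gene_labels, set) {
  lab <- gene_labels[names(gene_labels) %in% set]
  nA <- sum(lab == "A", na.rm = TRUE)
  nB <- sum(lab == "B", na.rm = TRUE)
  tot <- nA + nB
  c(A = if (tot) 100 * nA / tot else NA_real_,
    B = if (tot) 100 * nB / tot else NA_real_)
}
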