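#' A/B compartment eigenvector track
#'
#' Per chromosome: the balanced map is aggregated to the working resolution,
#' converted to observed/expected by dividing each diagonal by its mean, the
#' Pearson correlation matrix of O/E columns is formed over unmasked bins, and
#' the leading eigenvector is taken. The sign is oriented so that it
#' correlates positively with gene density; positive values are labeled A,
#' negative B. The result is projected back to the map resolution.
#'
#' @param map Balanced `ContactMap` (biases set).
#' @param genes `GeneTable` used for sign orientation.
#' @param working_res Resolution for the eigen-decomposition (default 1e5);
#'   must be a multiple of the map resolution.
#' @return A `CompartmentTrack`: list `bins`, `value`, `label` at the map
#'   resolution.
#' @export
compartment_track <- function(map, genes, working_res = 1e5) {
  bt <- map$bins
  res <- bt$resolution
  if (working_res %% res != 0) stop("working_res must be a multiple of the map resolution")
  fac <- working_res %/% res
  btw <- bin_table(bt$assembly, working_res)
  nW <- n_bins(btw)
  value_w <- rep(NA_real_, nW)
  # gene density per working bin (gene bodies overlapping each bin)
  gb <- genes$genes
  dens <- numeric(nW)
  if (nrow(gb)) {
    ov <- overlap_features(gb[, c("chrom", "start", "end")], btw$bins)
    if (nrow(ov)) {
      tab <- table(ov$b_idx)
      dens[as.integer(names(tab))] <- as.integer(tab)
    }
  }
  for (cm in unique(bt$bins$chrom)) {
    spw <- bin_span(btw, cm)
    firstw <- spw["first"]; nw <- spw["n"]
    W <- aggregate_balanced_chrom(map, btw, cm)
    marg <- rowSums(W)
    unmasked <- which(marg > 0)
    ev <- rep(NA_real_, nw)
    if (length(unmasked) >= 10) {
      Wu <- W[unmasked, unmasked, drop = FALSE]
      nu <- nrow(Wu)
      # O/E: divide each diagonal by its mean (0/0 -> 0)
      OE <- Wu
      for (k in 0:(nu - 1)) {
        idx <- cbind(seq_len(nu - k), seq_len(nu - k) + k)
        mu <- mean(Wu[idx])
        v <- if (mu > 0) Wu[idx] / mu else 0
        OE[idx] <- v
        OE[idx[, c(2, 1), drop = FALSE]] <- v
      }
      sds <- apply(OE, 2, sd)
      good <- sds > 0
      if (sum(good) >= 10) {
        CC <- cor(OE[good, good, drop = FALSE])
        eg <- eigen(CC, symmetric = TRUE)
        v1 <- eg$vectors[, 1]
        dsub <- dens[firstw + unmasked[good]]
        if (sd(dsub) > 0 && sd(v1) > 0) {
          r <- cor(v1, dsub)
          if (!is.na(r) && r < 0) v1 <- -v1
        }
        ev[unmasked[good]] <- v1
      } else {
        warning(sprintf("chromosome %s: degenerate contact structure, compartments set NA", cm))
      }
    } else {
      warning(sprintf("chromosome %s has < 10 unmasked working bins; compartments set NA", cm))
    }
    value_w[firstw + seq_len(nw)] <- ev
  }
  # project back to fine bins
  parent <- bin_of(btw, bt$bins$chrom, bt$bins$start)
  value <- value_w[parent + 1L]
  label <- ifelse(is.na(value) | value == 0, NA_character_,
                  ifelse(value > 0, "A", "B"))
  structure(list(bins = bt, value = value, label = label,
                 working_res = working_res),
            class = "CompartmentTrack")
}

# balanced contact matrix of one chromosome aggregated to working bins
aggregate_balanced_chrom <- function(map, btw, cm) {
  bt <- map$bins
  sp <- bin_span(bt, cm)
  spw <- bin_span(btw, cm)
  e <- map$entries
  B <- map$biases
  sel <- e$i >= sp["first"] & e$i < sp["first"] + sp["n"] &
    e$j >= sp["first"] & e$j < sp["first"] + sp["n"]
  e <- e[sel, , drop = FALSE]
  nw <- spw["n"]
  W <- matrix(0, nw, nw)
  if (nrow(e)) {
    bb <- B[e$i + 1L] * B[e$j + 1L]
    ok <- !is.na(bb)
    e <- e[ok, , drop = FALSE]
    v <- e$count / bb[ok]
    fac <- btw$resolution %/% bt$resolution
    li <- (e$i - sp["first"]) %/% fac + 1L
    lj <- (e$j - sp["first"]) %/% fac + 1L
    # both triangles of the symmetric fine matrix (diagonal fine entries once)
    off <- e$i != e$j
    lin <- c((lj - 1L) * nw + li, ((li - 1L) * nw + lj)[off])
    vv <- c(v, v[off])
    agg <- rowsum(vv, lin, reorder = FALSE)
    W[as.integer(rownames(agg))] <- W[as.integer(rownames(agg))] + agg[, 1]
  }
  W
}

#' @export
print.CompartmentTrack <- function(x, ...) {
  tab <- table(factor(x$label, c("A", "B")))
  cat(sprintf("CompartmentTrack: %d bins @ %d bp (A: %d, B: %d, NA: %d)\n",
              n_bins(x$bins), x$bins$resolution, tab["A"], tab["B"],
              sum(is.na(x$label))))
  invisible(x)
}

#' Classify per-bin compartment switches between two conditions
#'
#' @param track1,track2 `CompartmentTrack`s on identical bin tables.
#' @return A `SwitchTable`: list with per-bin `category` (`A->A`, `B->B`,
#'   `A->B`, `B->A`, NA) and `percent`, the share of each category among
#'   non-NA bins.
#' @export
compartment_switch <- function(track1, track2) {
  if (!identical(track1$bins$bins[, c("chrom", "start", "end")],
                 track2$bins$bins[, c("chrom", "start", "end")]))
    stop("compartment tracks are on different bin tables")
  l1 <- track1$label; l2 <- track2$label
  category <- rep(NA_character_, length(l1))
  ok <- !is.na(l1) & !is.na(l2)
  category[ok] <- paste0(l1[ok], "->", l2[ok])
  lev <- c("A->A", "B->B", "A->B", "B->A")
  counts <- table(factor(category, lev))
  n_ok <- sum(ok)
  percent <- if (n_ok > 0) 100 * as.numeric(counts) / n_ok else rep(0, 4)
  names(percent) <- lev
  structure(list(bins = track1$bins, category = category,
                 counts = as.numeric(counts), percent = percent,
                 n_na = sum(!ok)),
            class = "SwitchTable")
}

#' @export
print.SwitchTable <- function(x, ...) {
  cat("SwitchTable:\n")
  print(round(x$percent, 2))
  cat(sprintf("(switched total: %.1f%%; NA bins: %d)\n",
              sum(x$percent[c("A->B", "B->A")]), x$n_na))
  invisible(x)
}

#' Assign each TAD the majority compartment of its fine bins
#'
#' Exact A/B ties are broken by the sign of the mean eigenvector over the
#' TAD's bins; a zero mean (or all-NA bins) yields NA.
#'
#' @param tads A `TADSet`.
#' @param track A `CompartmentTrack` at a finer resolution than the TADs.
#' @return The `TADSet` with its `label` column filled.
#' @export
majority_compartment <- function(tads, track) {
  bins <- track$bins$bins
  tads$label <- NA_character_
  for (k in seq_len(nrow(tads))) {
    sel <- bins$chrom == tads$chrom[k] & bins$start < tads$end[k] &
      bins$end > tads$start[k]
    if (!any(sel)) {
      warning(sprintf("TAD %s outside track coverage", tads$id[k]))
      next
    }
    lab <- track$label[sel]
    nA <- sum(lab == "A", na.rm = TRUE)
    nB <- sum(lab == "B", na.rm = TRUE)
    if (nA + nB == 0) next
    if (nA > nB) tads$label[k] <- "A"
    else if (nB > nA) tads$label[k] <- "B"
    else {
      mu <- mean(track$value[sel], na.rm = TRUE)
      if (is.finite(mu) && mu > 0) tads$label[k] <- "A"
      else if (is.finite(mu) && mu < 0) tads$label[k] <- "B"
    }
  }
  tads
}

#' Export a compartment track
#'
#' @param track A `CompartmentTrack`.
#' @param bedgraph_path Eigenvector values as bedGraph (NA bins skipped).
#' @param bed_path Labels as BED with name column A/B.
#' @export
write_compartment_track <- function(track, bedgraph_path = NULL,
                                    bed_path = NULL) {
  b <- track$bins$bins
  if (!is.null(bedgraph_path)) {
    ok <- !is.na(track$value)
    write.table(data.frame(b$chrom[ok], b$start[ok], b$end[ok],
                           track$value[ok]),
                bedgraph_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(bed_path)) {
    ok <- !is.na(track$label)
    write.table(data.frame(b$chrom[ok], b$start[ok], b$end[ok],
                           track$label[ok]),
                bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(track)
}

#' Export a switch table as TSV
#' @param sw A `SwitchTable`.
#' @param path Output path.
#' @export
write_switch_table <- function(sw, path) {
  b <- sw$bins$bins
  write.table(data.frame(chrom = b$chrom, start = b$start, end = b$end,
                         category = ifelse(is.na(sw$category), "NA",
                                           sw$category)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sw)
}
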