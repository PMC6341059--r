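# Small in-code fixtures shared across test files.

# two-chromosome bin table: n_bins per chromosome at `res`
tiny_bins <- function(n_per_chrom = 20, res = 5000, chroms = c("c1", "c2")) {
  asm <- genome_assembly(chroms, rep(n_per_chrom * res, length(chroms)))
  bin_table(asm, res)
}

# contact map from an explicit triplet data frame
tiny_map <- function(bins, i, j, count) {
  contact_map(bins, data.frame(i = i, j = j, count = count))
}

# interaction set built directly from bin pairs (for analyses that consume
# calls without running the caller)
make_iset <- function(bins, bin1, bin2, kind = "cis", count = 10,
                      p = 1e-6, q = 1e-4) {
  n <- length(bin1)
  rec <- data.frame(bin1 = bin1, bin2 = bin2,
                    chrom1 = bins$bins$chrom[bin1 + 1L],
                    chrom2 = bins$bins$chrom[bin2 + 1L],
                    count = rep_len(count, n), p_exp = rep(NA_real_, n),
                    p = rep_len(p, n), q = rep_len(q, n))
  chromarch:::new_interaction_set(kind, rec, bins$resolution, bins)
}

# gene table from a compact spec data frame (tss/tes already strand-aware)
make_genes <- function(df, exons = NULL) {
  if (is.null(exons))
    exons <- data.frame(id = character(), chrom = character(),
                        start = numeric(), end = numeric())
  chromarch:::new_gene_table(df, exons)
}

# compartment track with explicit labels/values on a bin table
make_track <- function(bins, label, value = NULL) {
  if (is.null(value))
    value <- ifelse(is.na(label), NA_real_, ifelse(label == "A", 1, -1))
  structure(list(bins = bins, value = value, label = label),
            class = "CompartmentTrack")
}

# structure population from a T x 3 coordinate matrix replicated S times
make_pop <- function(coords, tads, R_nuc = 5000, S = 1) {
  arr <- array(NA_real_, c(S, nrow(coords), 3))
  for (s in seq_len(S)) arr[s, , ] <- coords
  structure_population(arr, tads, R_nuc)
}

make_tads <- function(chrom, start, end, label = NA_character_) {
  df <- data.frame(chrom = chrom, start = start, end = end,
                   id = sprintf("TAD_%04d", seq_along(chrom)),
                   label = rep_len(label, length(chrom)),
                   stringsAsFactors = FALSE)
  class(df) <- c("TADSet", "data.frame")
  df
}

# a random 3D rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}
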