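#' @importFrom stats median quantile rnorm rpois rgamma runif sd cor
#' @importFrom utils read.table write.table head tail
NULL

# All internal coordinates are 0-based half-open [start, end); bin indices are
# global, dense and 0-based. 1-based inputs (GTF, HiC-Pro _abs.bed) are shifted
# on ingest and shifted back on export.

SEX_CHROMS <- c("chrX", "chrY", "chrM", "X", "Y", "M", "MT", "chrMT")

#' Describe a genome assembly
#'
#' @param chroms Ordered chromosome names (unique).
#' @param lengths Chromosome lengths in bp, same order.
#' @param autosome Logical per chromosome; defaults to a name-based guess
#'   (chrX/chrY/chrM and bare X/Y/MT are flagged non-autosomal).
#' @return A `GenomeAssembly` data frame with columns `chrom`, `length`,
#'   `autosome`.
#' @export
genome_assembly <- function(chroms, lengths, autosome = NULL) {
  chroms <- as.character(chroms)
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (length(lengths) != length(chroms)) stop("lengths must match chroms")
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (is.null(autosome)) autosome <- !(chroms %in% SEX_CHROMS)
  out <- data.frame(chrom = chroms, length = as.numeric(lengths),
                    autosome = autosome, stringsAsFactors = FALSE)
  class(out) <- c("GenomeAssembly", "data.frame")
  out
}

#' Restrict an assembly to autosomes
#' @param assembly A `GenomeAssembly`.
#' @return The autosomal subset, same class.
#' @export
autosomes <- function(assembly) {
  out <- assembly[assembly$autosome, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(assembly)
  out
}

#' Tile an assembly into fixed-width bins
#'
#' Bins are half-open `[start, end)`, tile each chromosome from 0, and carry a
#' dense global 0-based index in assembly order. The last bin of a chromosome
#' may be shorter than the resolution.
#'
#' @param assembly A `GenomeAssembly`.
#' @param resolution Bin width in bp.
#' @return A `BinTable`: list with `resolution` and a `bins` data frame
#'   (`chrom`, `start`, `end`, `index`).
#' @export
bin_table <- function(assembly, resolution) {
  stopifnot(resolution >= 1)
  pieces <- lapply(seq_len(nrow(assembly)), function(k) {
    len <- assembly$length[k]
    starts <- seq(0, len - 1, by = resolution)
    data.frame(chrom = assembly$chrom[k], start = starts,
               end = pmin(starts + resolution, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, pieces)
  bins$index <- seq_len(nrow(bins)) - 1L
  structure(list(resolution = resolution, bins = bins,
                 assembly = assembly),
            class = "BinTable")
}

n_bins <- function(bt) nrow(bt$bins)

#' Global bin index of a genomic position
#' @param bt A `BinTable`.
#' @param chrom Chromosome name.
#' @param pos Position in bp (0-based).
#' @return 0-based global bin index (NA if outside the assembly).
#' @export
bin_of <- function(bt, chrom, pos) {
  res <- bt$resolution
  idx <- rep(NA_integer_, length(pos))
  for (cm in unique(chrom)) {
    sel <- chrom == cm
    rows <- bt$bins$chrom == cm
    if (!any(rows)) next
    first <- bt$bins$index[which(rows)[1]]
    nloc <- sum(rows)
    loc <- pos[sel] %/% res
    ok <- loc >= 0 & loc < nloc
    idx[sel][ok] <- as.integer(first + loc[ok])
  }
  idx
}

bin_span <- function(bt, chrom) {
  rows <- which(bt$bins$chrom == chrom)
  if (!length(rows)) return(NULL)
  c(first = bt$bins$index[rows[1]], n = length(rows))
}

#' Construct a sparse symmetric contact map
#'
#' Entries are stored upper-triangular (`i <= j`, 0-based global bin indices);
#' duplicates (including transposed duplicates) are summed.
#'
#' @param bins A `BinTable`.
#' @param entries Data frame with columns `i`, `j`, `count`.
#' @param biases Optional per-bin positive balancing factor (NA = masked).
#' @return A `ContactMap`.
#' @export
contact_map <- function(bins, entries, biases = NULL) {
  if (nrow(entries)) {
    if (any(entries$count < 0)) stop("negative contact values are not allowed")
    bad <- entries$i < 0 | entries$i >= n_bins(bins) |
      entries$j < 0 | entries$j >= n_bins(bins)
    if (any(bad)) {
      k <- which(bad)[1]
      stop(sprintf("contact entry references unknown bin index (line %d: %s %s)",
                   k, entries$i[k], entries$j[k]))
    }
    ii <- pmin(entries$i, entries$j)
    jj <- pmax(entries$i, entries$j)
    key <- paste(ii, jj)
    agg <- rowsum(entries$count, key)
    parts <- matrix(as.integer(unlist(strsplit(rownames(agg), " "))),
                    ncol = 2, byrow = TRUE)
    entries <- data.frame(i = parts[, 1], j = parts[, 2], count = agg[, 1])
    entries <- entries[order(entries$i, entries$j), , drop = FALSE]
    rownames(entries) <- NULL
  } else {
    entries <- data.frame(i = integer(), j = integer(), count = numeric())
  }
  if (!is.null(biases) && length(biases) != n_bins(bins))
    stop("biases must have one value per bin")
  structure(list(bins = bins, entries = entries, biases = biases,
                 total = sum(entries$count)),
            class = "ContactMap")
}

#' @export
print.ContactMap <- function(x, ...) {
  cat(sprintf("ContactMap: %d bins @ %d bp, %d entries, total %.0f, %s\n",
              n_bins(x$bins), x$bins$resolution, nrow(x$entries), x$total,
              if (is.null(x$biases)) "raw" else "balanced"))
  invisible(x)
}

chrom_of_bin <- function(bt, idx) bt$bins$chrom[idx + 1L]

# Dense symmetric matrix for one chromosome; balanced = divide by B_i B_j.
dense_chrom_matrix <- function(map, chrom, balanced = FALSE) {
  sp <- bin_span(map$bins, chrom)
  if (is.null(sp)) stop("unknown chromosome: ", chrom)
  first <- sp["first"]; n <- sp["n"]
  e <- map$entries
  sel <- e$i >= first & e$i < first + n & e$j >= first & e$j < first + n
  e <- e[sel, , drop = FALSE]
  m <- matrix(0, n, n)
  if (nrow(e)) {
    li <- e$i - first + 1L; lj <- e$j - first + 1L
    v <- e$count
    if (balanced) {
      if (is.null(map$biases)) stop("map has no biases; run ice_normalize first")
      b <- map$biases[e$i + 1L] * map$biases[e$j + 1L]
      v <- v / b
    }
    m[cbind(li, lj)] <- v
    m[cbind(lj, li)] <- v
  }
  m
}

#' Read a contact map in the HiC-Pro sparse triplet dialect
#'
#' The bins file is BED-like (`chrom start end index`) with 1-based dense
#' indices; the matrix file holds whitespace-separated `index_i index_j value`
#' triplets. Indices are re-based to 0 and duplicate pairs summed.
#'
#' @param matrix_path Path to the `.matrix` triplet file.
#' @param bins_path Path to the `_abs.bed` bin file.
#' @param autosomes_only Drop sex/mitochondrial chromosomes on ingest
#'   (default TRUE).
#' @return A `ContactMap`.
#' @export
read_contact_map <- function(matrix_path, bins_path, autosomes_only = TRUE) {
  bed <- read.table(bins_path, header = FALSE, stringsAsFactors = FALSE)
  names(bed)[1:4] <- c("chrom", "start", "end", "index")
  bed <- bed[order(bed$index), , drop = FALSE]
  if (autosomes_only) {
    keep_chrom <- setdiff(unique(bed$chrom), SEX_CHROMS)
  } else keep_chrom <- unique(bed$chrom)
  lens <- tapply(bed$end, bed$chrom, max)
  assembly <- genome_assembly(keep_chrom, as.numeric(lens[keep_chrom]))
  res <- max(bed$end - bed$start)
  bt <- bin_table(assembly, res)
  # map original 1-based indices to new dense 0-based indices
  bed$new <- NA_integer_
  keep <- bed$chrom %in% keep_chrom
  lookup <- bin_of(bt, bed$chrom[keep], bed$start[keep])
  if (anyNA(lookup)) stop("bins file does not tile its chromosomes evenly")
  bed$new[keep] <- lookup
  trip <- read.table(matrix_path, header = FALSE, stringsAsFactors = FALSE)
  names(trip)[1:3] <- c("i", "j", "value")
  if (any(trip$value < 0)) {
    k <- which(trip$value < 0)[1]
    stop(sprintf("negative value in matrix file at line %d", k))
  }
  idx_max <- max(bed$index)
  bad <- trip$i < 1 | trip$i > idx_max | trip$j < 1 | trip$j > idx_max
  if (any(bad)) {
    k <- which(bad)[1]
    stop(sprintf("matrix line %d references index %s absent from bins file",
                 k, max(trip$i[k], trip$j[k])))
  }
  remap <- rep(NA_integer_, idx_max)
  remap[bed$index] <- bed$new
  ni <- remap[trip$i]; nj <- remap[trip$j]
  drop <- is.na(ni) | is.na(nj)  # filtered chromosomes
  entries <- data.frame(i = ni[!drop], j = nj[!drop], count = trip$value[!drop])
  contact_map(bt, entries)
}

#' Write a contact map in the HiC-Pro triplet dialect
#'
#' @param map A `ContactMap`.
#' @param matrix_path,bins_path Output paths; indices are written 1-based.
#' @param bias_path Optional TSV of per-bin biases.
#' @export
write_contact_map <- function(map, matrix_path, bins_path, bias_path = NULL) {
  b <- map$bins$bins
  write.table(data.frame(b$chrom, b$start, b$end, b$index + 1L),
              bins_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  e <- map$entries
  write.table(data.frame(e$i + 1L, e$j + 1L, e$count),
              matrix_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(bias_path)) {
    write.table(data.frame(b$chrom, b$start, b$end,
                           ifelse(is.na(map$biases), "NA", map$biases)),
                bias_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(map)
}

#' Aggregate a contact map to a coarser resolution
#'
#' Raw counts of fine bin pairs are summed into their parent coarse bins;
#' biases are dropped (re-balance at the new resolution).
#'
#' @param map A `ContactMap`.
#' @param new_resolution Target resolution; multiple of the current one.
#' @return A `ContactMap` at `new_resolution`.
#' @export
aggregate_contact_map <- function(map, new_resolution) {
  res <- map$bins$resolution
  if (new_resolution %% res != 0) stop("new resolution must be a multiple")
  if (new_resolution == res) return(contact_map(map$bins, map$entries))
  bt2 <- bin_table(map$bins$assembly, new_resolution)
  b <- map$bins$bins
  parent <- bin_of(bt2, b$chrom, b$start)
  e <- map$entries
  contact_map(bt2, data.frame(i = parent[e$i + 1L], j = parent[e$j + 1L],
                              count = e$count))
}

## ---------------------------------------------------------------- genes ----

new_gene_table <- function(genes, exons) {
  if (anyDuplicated(genes$id)) stop("duplicate gene ids")
  genes$start <- pmin(genes$tss, genes$tes)
  genes$end <- pmax(genes$tss, genes$tes)
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons), class = "GeneTable")
}

#' @export
print.GeneTable <- function(x, ...) {
  cat(sprintf("GeneTable: %d genes, %d exons on %d chromosomes\n",
              nrow(x$genes), nrow(x$exons), length(unique(x$genes$chrom))))
  invisible(x)
}

#' Read a gene table
#'
#' Two dialects: `gtf` (gene/exon features, 1-based closed coordinates,
#' converted to 0-based half-open on ingest, strand-aware TSS/TES derived) and
#' `tsv` (explicit 0-based columns `id chrom strand tss tes`).
#'
#' @param path Annotation file.
#' @param dialect `"gtf"` or `"tsv"`.
#' @param autosomes_only Drop sex/mitochondrial chromosomes (default TRUE).
#' @return A `GeneTable`.
#' @export
read_gene_table <- function(path, dialect = c("gtf", "tsv"),
                            autosomes_only = TRUE) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    tab <- read.table(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    need <- c("id", "chrom", "strand", "tss", "tes")
    if (!all(need %in% names(tab))) stop("tsv gene table needs columns: ",
                                         paste(need, collapse = " "))
    if (any(!tab$strand %in% c("+", "-"))) stop("gene without strand")
    if (autosomes_only) tab <- tab[!tab$chrom %in% SEX_CHROMS, , drop = FALSE]
    exons <- data.frame(id = character(), chrom = character(),
                        start = numeric(), end = numeric())
    return(new_gene_table(tab[, need], exons))
  }
  gr <- rtracklayer::import(path)
  df <- as.data.frame(gr)
  if (!"type" %in% names(df)) stop("GTF has no feature type column")
  g <- df[df$type == "gene", , drop = FALSE]
  if (!nrow(g)) stop("GTF contains no gene features")
  if (any(!as.character(g$strand) %in% c("+", "-")))
    stop("gene without strand in GTF")
  # GTF 1-based closed -> 0-based half-open: start-1, end unchanged
  start0 <- g$start - 1
  end0 <- g$end
  plus <- as.character(g$strand) == "+"
  genes <- data.frame(id = as.character(g$gene_id),
                      chrom = as.character(g$seqnames),
                      strand = as.character(g$strand),
                      tss = ifelse(plus, start0, end0),
                      tes = ifelse(plus, end0, start0),
                      stringsAsFactors = FALSE)
  ex <- df[df$type == "exon", , drop = FALSE]
  exons <- data.frame(id = as.character(ex$gene_id),
                      chrom = as.character(ex$seqnames),
                      start = ex$start - 1, end = ex$end,
                      stringsAsFactors = FALSE)
  if (autosomes_only) {
    genes <- genes[!genes$chrom %in% SEX_CHROMS, , drop = FALSE]
    exons <- exons[!exons$chrom %in% SEX_CHROMS, , drop = FALSE]
  }
  new_gene_table(genes, exons)
}

#' Write a gene table in the TSV dialect (0-based)
#' @param gt A `GeneTable`.
#' @param path Output path.
#' @export
write_gene_table <- function(gt, path) {
  write.table(gt$genes[, c("id", "chrom", "strand", "tss", "tes")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(gt)
}

#' Promoter windows of all genes
#'
#' The promoter is `upstream` bp before to `downstream` bp after the TSS in
#' transcription direction, clipped at 0.
#'
#' @param gt A `GeneTable`.
#' @param upstream,downstream Window extent in bp.
#' @return Data frame `id chrom start end` (half-open).
#' @export
promoter_windows <- function(gt, upstream = 2000, downstream = 200) {
  g <- gt$genes
  plus <- g$strand == "+"
  start <- ifelse(plus, g$tss - upstream, g$tss - downstream)
  end <- ifelse(plus, g$tss + downstream, g$tss + upstream)
  data.frame(id = g$id, chrom = g$chrom, start = pmax(start, 0), end = end,
             stringsAsFactors = FALSE)
}

## ------------------------------------------------------------- overlaps ----

#' All overlapping pairs between two interval sets
#'
#' Half-open, 0-based, chromosome-tagged intervals; a pair overlaps when
#' `a.start < b.end && b.start < a.end` on the same chromosome.
#'
#' @param a,b Data frames with columns `chrom`, `start`, `end`.
#' @return Data frame with row indices `a_idx`, `b_idx` of overlapping pairs.
#' @export
overlap_features <- function(a, b) {
  if (!nrow(a) || !nrow(b))
    return(data.frame(a_idx = integer(), b_idx = integer()))
  gra <- GenomicRanges::GRanges(a$chrom,
                                IRanges::IRanges(a$start + 1, a$end))
  grb <- GenomicRanges::GRanges(b$chrom,
                                IRanges::IRanges(b$start + 1, b$end))
  hits <- GenomicRanges::findOverlaps(gra, grb)
  data.frame(a_idx = S4Vectors::queryHits(hits),
             b_idx = S4Vectors::subjectHits(hits))
}

## ------------------------------------------------------------ gene sets ----

#' Read / write GMT gene-set collections
#'
#' @param path GMT file (name, description, then member ids, tab-separated).
#' @return Named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    out[[f[1]]] <- f[-(1:2)]
  }
  out
}

#' @rdname read_gmt
#' @param sets Named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, nm, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(sets)
}

## ----------------------------------------------------------- structures ----

#' Read a 3D structure population
#'
#' @param path TSV with columns `structure_id domain_id x y z` (nm).
#' @param tads `TADSet` giving the domains (ids must resolve).
#' @param R_nuc Nuclear radius in nm.
#' @return A `StructurePopulation`: list `S`, `domains`, `coords`
#'   (array S x T x 3), `R_nuc`.
#' @export
read_structure_population <- function(path, tads, R_nuc) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("structure_id", "domain_id", "x", "y", "z")
  if (!all(need %in% names(tab))) stop("structure table needs columns: ",
                                       paste(need, collapse = " "))
  unknown <- setdiff(unique(tab$domain_id), tads$id)
  if (length(unknown)) stop("unknown domain_id: ", unknown[1])
  structs <- sort(unique(tab$structure_id))
  S <- length(structs); T <- nrow(tads)
  coords <- array(NA_real_, c(S, T, 3))
  si <- match(tab$structure_id, structs)
  di <- match(tab$domain_id, tads$id)
  coords[cbind(si, di, 1)] <- tab$x
  coords[cbind(si, di, 2)] <- tab$y
  coords[cbind(si, di, 3)] <- tab$z
  if (anyNA(coords)) {
    gap <- which(is.na(coords[, , 1]), arr.ind = TRUE)[1, ]
    stop(sprintf("structure %s is missing domain %s",
                 structs[gap[1]], tads$id[gap[2]]))
  }
  r <- sqrt(tab$x^2 + tab$y^2 + tab$z^2)
  if (any(r > R_nuc + 1e-9)) {
    k <- which(r > R_nuc + 1e-9)[1]
    stop(sprintf("point outside nucleus (structure %s domain %s radius %.1f > R_nuc %.1f)",
                 tab$structure_id[k], tab$domain_id[k], r[k], R_nuc))
  }
  structure_population(coords, tads, R_nuc)
}

#' Construct a structure population from a coordinate array
#' @param coords Array S x T x 3 (nm).
#' @param tads `TADSet` of the T domains.
#' @param R_nuc Nuclear radius (nm).
#' @export
structure_population <- function(coords, tads, R_nuc) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[2] == nrow(tads), dim(coords)[1] >= 1)
  structure(list(S = dim(coords)[1], domains = tads, coords = coords,
                 R_nuc = R_nuc),
            class = "StructurePopulation")
}

#' @export
print.StructurePopulation <- function(x, ...) {
  cat(sprintf("StructurePopulation: %d structures x %d domains, R_nuc %.0f nm\n",
              x$S, nrow(x$domains), x$R_nuc))
  invisible(x)
}

#' Write a structure population as TSV
#' @param pop A `StructurePopulation`.
#' @param path Output path.
#' @export
write_structure_population <- function(pop, path) {
  T <- nrow(pop$domains)
  df <- data.frame(
    structure_id = rep(seq_len(pop$S), each = T),
    domain_id = rep(pop$domains$id, pop$S),
    x = as.vector(t(pop$coords[, , 1])),
    y = as.vector(t(pop$coords[, , 2])),
    z = as.vector(t(pop$coords[, , 3])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(pop)
}

#' Export one structure as a PDB-like file for visualization
#'
#' Each domain becomes one CA atom; coordinates are scaled from nm to the PDB
#' Angstrom-ish field width by `scale`.
#'
#' @param pop A `StructurePopulation`.
#' @param structure Index of the structure to export.
#' @param path Output path.
#' @param scale Coordinate scaling factor (default 0.01).
#' @export
write_structure_pdb <- function(pop, structure, path, scale = 0.01) {
  xyz <- pop$coords[structure, , , drop = TRUE] * scale
  lines <- vapply(seq_len(nrow(xyz)), function(k) {
    sprintf("ATOM  %5d  CA  TAD %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            k, substr(pop$domains$chrom[k], nchar(pop$domains$chrom[k]), 1000),
            k %% 10000, xyz[k, 1], xyz[k, 2], xyz[k, 3])
  }, character(1))
  writeLines(c(lines, "END"), path)
  invisible(pop)
}

## ----------------------------------------------- interaction sets (I/O) ----

new_interaction_set <- function(kind, records, resolution, bins) {
  kind <- match.arg(kind, c("cis", "trans"))
  if (nrow(records)) {
    ord <- order(records$chrom1, records$bin1, records$chrom2, records$bin2)
    records <- records[ord, , drop = FALSE]
    rownames(records) <- NULL
  }
  structure(list(kind = kind, records = records, resolution = resolution,
                 bins = bins),
            class = "InteractionSet")
}

#' @export
print.InteractionSet <- function(x, ...) {
  cat(sprintf("InteractionSet (%s): %d records @ %d bp\n",
              x$kind, nrow(x$records), x$resolution))
  invisible(x)
}

#' Export significant interactions as BEDPE
#'
#' Columns: chrom1 start1 end1 chrom2 start2 end2 name(".") score(=count)
#' p q.
#'
#' @param iset An `InteractionSet`.
#' @param path Output path.
#' @export
write_bedpe <- function(iset, path) {
  r <- iset$records
  b <- iset$bins$bins
  df <- data.frame(r$chrom1, b$start[r$bin1 + 1L], b$end[r$bin1 + 1L],
                   r$chrom2, b$start[r$bin2 + 1L], b$end[r$bin2 + 1L],
                   rep(".", nrow(r)), r$count, r$p, r$q)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(iset)
}

#' Import Fit-Hi-C output as an InteractionSet
#'
#' Accepts the published tool's TSV (`chr1 fragmentMid1 chr2 fragmentMid2
#' contactCount p.value q.value`, header optional), so externally produced
#' calls can be fed to the downstream analyses.
#'
#' @param path Fit-Hi-C output table.
#' @param bins `BinTable` the fragment midpoints are resolved against.
#' @param q_max Retain records with q below this threshold (default keep all).
#' @return An `InteractionSet` (kind inferred from the chromosome columns).
#' @export
read_fithic <- function(path, bins, q_max = 1) {
  first <- readLines(path, n = 1)
  has_header <- grepl("chr1|fragmentMid", first)
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  names(tab)[1:7] <- c("chrom1", "mid1", "chrom2", "mid2", "count", "p", "q")
  tab <- tab[tab$q < q_max, , drop = FALSE]
  bin1 <- bin_of(bins, tab$chrom1, tab$mid1)
  bin2 <- bin_of(bins, tab$chrom2, tab$mid2)
  keep <- !is.na(bin1) & !is.na(bin2)
  tab <- tab[keep, , drop = FALSE]
  bin1 <- bin1[keep]; bin2 <- bin2[keep]
  swap <- bin1 > bin2
  tmp <- bin1[swap]; bin1[swap] <- bin2[swap]; bin2[swap] <- tmp
  rec <- data.frame(bin1 = bin1, bin2 = bin2,
                    chrom1 = chrom_of_bin(bins, bin1),
                    chrom2 = chrom_of_bin(bins, bin2),
                    count = tab$count, p_exp = NA_real_,
                    p = tab$p, q = tab$q)
  kind <- if (all(rec$chrom1 == rec$chrom2)) "cis" else "trans"
  new_interaction_set(kind, rec, bins$resolution, bins)
}

## ------------------------------------------------------------ TAD (I/O) ----

#' Read / write TAD sets as TSV
#'
#' Native columns `chrom start end id label`; TopDom-style output with
#' `chr from.coord to.coord` (plus optional `tag`) is also accepted.
#'
#' @param path TSV path.
#' @return A `TADSet` data frame.
#' @export
read_tads <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (all(c("chr", "from.coord", "to.coord") %in% names(tab))) {
    tab <- data.frame(chrom = tab$chr, start = tab$from.coord,
                      end = tab$to.coord,
                      id = sprintf("TAD_%04d", seq_len(nrow(tab))),
                      label = if ("tag" %in% names(tab)) tab$tag else NA,
                      stringsAsFactors = FALSE)
  }
  need <- c("chrom", "start", "end", "id")
  if (!all(need %in% names(tab))) stop("TAD table needs columns: ",
                                       paste(need, collapse = " "))
  if (!"label" %in% names(tab)) tab$label <- NA_character_
  class(tab) <- c("TADSet", "data.frame")
  tab
}

#' @rdname read_tads
#' @param tads A `TADSet`.
#' @export
write_tads <- function(tads, path) {
  write.table(as.data.frame(tads)[, c("chrom", "start", "end", "id", "label")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tads)
}
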