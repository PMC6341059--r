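#' TAD caller parameters
#' @param w Diamond half-width in bins (default 3).
#' @param working_res Working resolution in bp (default 1e5).
#' @export
tad_params <- function(w = 3, working_res = 1e5) {
  stopifnot(w >= 1)
  list(w = w, working_res = working_res)
}

#' Per-bin diamond contact signal
#'
#' For bin i, the mean balanced contact over the diamond
#' `{(u, v): i-w+1 <= u <= i < v <= i+w}`, clipped to available bins at
#' chromosome ends. Chromosomes shorter than `2w` bins get all-NA signal.
#'
#' @param map Balanced `ContactMap` at the working resolution.
#' @param w Diamond half-width in bins.
#' @return Data frame `chrom start end signal` (one row per bin; the last bin
#'   of each chromosome has no downstream diamond and is NA).
#' @export
binsignal <- function(map, w = 3) {
  bt <- map$bins
  out <- list()
  for (cm in unique(bt$bins$chrom)) {
    sp <- bin_span(bt, cm)
    nloc <- sp["n"]
    rows <- bt$bins[bt$bins$chrom == cm, , drop = FALSE]
    sig <- rep(NA_real_, nloc)
    if (nloc >= 2 * w) {
      W <- dense_chrom_matrix(map, cm, balanced = TRUE)
      for (i in seq_len(nloc - 1)) {
        us <- max(1, i - w + 1):i
        vs <- (i + 1):min(nloc, i + w)
        sig[i] <- mean(W[us, vs, drop = FALSE])
      }
    }
    out[[cm]] <- data.frame(chrom = cm, start = rows$start, end = rows$end,
                            signal = sig, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# leftmost bins of strict local minima (plateaus take their leftmost bin)
local_minima <- function(sig) {
  ok <- which(!is.na(sig))
  if (length(ok) < 3) return(integer(0))
  x <- sig[ok]
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mins <- integer(0)
  if (length(r$values) >= 3) {
    for (k in 2:(length(r$values) - 1)) {
      if (r$values[k] < r$values[k - 1] && r$values[k] < r$values[k + 1])
        mins <- c(mins, starts[k])
    }
  }
  ok[mins]
}

#' Call TADs from the diamond signal
#'
#' Boundaries are placed at strict local minima of the signal (plateau minima
#' take the leftmost bin); domains are the intervals between consecutive
#' boundaries plus the chromosome ends. Domains shorter than 2 bins are merged
#' into the neighbor with the higher junction signal.
#'
#' @param signal Output of [binsignal()].
#' @param params `tad_params()`.
#' @return A `TADSet` data frame (`chrom start end id label`).
#' @export
call_tads <- function(signal, params = tad_params()) {
  res_bp <- max(signal$end - signal$start)
  out <- list()
  for (cm in unique(signal$chrom)) {
    sub <- signal[signal$chrom == cm, , drop = FALSE]
    n <- nrow(sub)
    if (all(is.na(sub$signal))) next
    mins <- local_minima(sub$signal)
    # domain cut after each boundary bin
    cuts <- sort(unique(mins[mins < n]))
    starts <- c(1, cuts + 1)
    ends <- c(cuts, n)
    # merge domains shorter than 2 bins
    repeat {
      len <- ends - starts + 1
      shorts <- which(len < 2)
      if (!length(shorts) || length(starts) == 1) break
      k <- shorts[1]
      left_sig <- if (k > 1) sub$signal[starts[k] - 1] else -Inf
      right_sig <- if (k < length(starts)) sub$signal[ends[k]] else -Inf
      left_sig[is.na(left_sig)] <- -Inf
      right_sig[is.na(right_sig)] <- -Inf
      if (k > 1 && (k == length(starts) || left_sig >= right_sig)) {
        ends[k - 1] <- ends[k]
        starts <- starts[-k]; ends <- ends[-k]
      } else {
        starts[k + 1] <- starts[k]
        starts <- starts[-k]; ends <- ends[-k]
      }
    }
    out[[cm]] <- data.frame(chrom = cm,
                            start = sub$start[starts],
                            end = sub$end[ends],
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    tads <- data.frame(chrom = character(), start = numeric(),
                       end = numeric(), id = character(),
                       label = character())
  } else {
    tads <- do.call(rbind, out)
    tads$id <- sprintf("TAD_%04d", seq_len(nrow(tads)))
    tads$label <- NA_character_
    rownames(tads) <- NULL
  }
  class(tads) <- c("TADSet", "data.frame")
  tads
}
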