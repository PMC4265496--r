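#' Filter MNase fragments by insert length
#'
#' Mononucleosomal size selection: keeps fragments whose length lies in the
#' inclusive range `[min_len, max_len]` (default 100-160 bp, the
#' mononucleosome band).
#'
#' @param fragments data.frame with `chrom`, `start`, `end`.
#' @param min_len,max_len inclusive insert-length bounds in bp.
#' @return the kept fragments, with attribute `report` = list(n_in, n_kept,
#'   n_dropped).
#' @export
filter_fragments <- function(fragments, min_len = 100, max_len = 160) {
  if (min_len > max_len)
    stop("min_len must be <= max_len", call. = FALSE)
  validate_intervals(fragments, "fragment")
  len <- fragments$end - fragments$start
  keep <- len >= min_len & len <= max_len
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- list(n_in = nrow(fragments), n_kept = sum(keep),
                              n_dropped = sum(!keep))
  out
}

#' Count fragment midpoints per base pair
#'
#' Each fragment contributes one count at `floor((start + end - 1) / 2)`,
#' the dyad position of a nucleosome-sized fragment (even lengths break the
#' tie leftward).
#'
#' @param fragments data.frame of fragments on one chromosome.
#' @param chrom_length optional chromosome length; the returned array then
#'   covers positions `0 .. chrom_length - 1`.
#' @return integer vector of per-bp counts; element `i` is position `i - 1`
#'   (attribute `offset` = 0).
#' @export
midpoint_counts <- function(fragments, chrom_length = NULL) {
  validate_intervals(fragments, "fragment")
  if (length(unique(fragments$chrom)) > 1L)
    stop("fragments must be on a single chromosome", call. = FALSE)
  mids <- floor((fragments$start + fragments$end - 1) / 2)
  n <- if (is.null(chrom_length)) max(mids) + 1L else as.integer(chrom_length)
  if (any(mids >= n))
    stop("fragment midpoint beyond chrom_length", call. = FALSE)
  counts <- tabulate(mids + 1L, nbins = n)
  attr(counts, "offset") <- 0L
  counts
}

gaussian_kernel <- function(sigma) {
  w <- ceiling(4 * sigma)
  k <- dnorm(seq.int(-w, w), mean = 0, sd = sigma)
  k / sum(k)
}

#' Gaussian-smooth a midpoint count array into an occupancy track
#'
#' Discrete convolution with a Gaussian kernel of bandwidth `sigma`,
#' truncated at +/- 4 sigma and renormalized to unit mass, so interior
#' impulses conserve mass. Kernel mass falling off the chromosome ends is
#' dropped (no reflection). `sigma = 0` returns the counts unchanged.
#'
#' @param counts per-bp integer counts (from [midpoint_counts()]).
#' @param sigma smoothing bandwidth in bp (>= 0).
#' @param chrom chromosome name stored in the track.
#' @return an `occupancy_track`: list with `chrom`, `offset`, `values`,
#'   `sigma`, `n_fragments`.
#' @export
smooth_track <- function(counts, sigma = 20, chrom = "chr1") {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  offset <- attr(counts, "offset") %||% 0L
  x <- as.numeric(counts)
  if (sigma == 0) {
    values <- x
  } else {
    k <- gaussian_kernel(sigma)
    w <- (length(k) - 1L) / 2L
    full <- convolve(x, rev(k), type = "open")
    values <- pmax(full[(w + 1L):(w + length(x))], 0)
  }
  structure(list(chrom = chrom, offset = offset, values = values,
                 sigma = sigma, n_fragments = sum(counts)),
            class = "occupancy_track")
}

#' @export
print.occupancy_track <- function(x, ...) {
  cat(sprintf(
    "occupancy_track: %s:%d-%d  sigma=%g  n_fragments=%g  mean=%.4g\n",
    x$chrom, x$offset, x$offset + length(x$values), x$sigma,
    x$n_fragments, mean(x$values)))
  invisible(x)
}

#' Normalize an occupancy track to mean 1
#'
#' @param track an `occupancy_track`.
#' @param mode only `"mean_one"` is supported.
#' @return the rescaled track.
#' @export
normalize_track <- function(track, mode = c("mean_one")) {
  mode <- match.arg(mode)
  stopifnot(inherits(track, "occupancy_track"))
  m <- mean(track$values)
  if (m <= 0) stop("track has no positive mass", call. = FALSE)
  track$values <- track$values / m
  track
}

#' Extract track values at absolute genomic positions
#'
#' @param track an `occupancy_track`.
#' @param pos 0-based positions; out-of-range positions give `NA`.
#' @return numeric vector of values at `pos`.
#' @export
track_values_at <- function(track, pos) {
  idx <- pos - track$offset + 1L
  ok <- idx >= 1L & idx <= length(track$values)
  out <- rep(NA_real_, length(pos))
  out[ok] <- track$values[idx[ok]]
  out
}
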