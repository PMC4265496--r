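# Anchor-aligned occupancy averaging, length-sorted heatmap matrices and
# phasing-period estimation.

#' Anchor-aligned average signal (metaprofile)
#'
#' Averages track signal over a fixed offset range around a set of anchor
#' positions. When `orient = TRUE`, anchors labelled `"3prime"` are
#' mirrored (offset o reads the track at `pos - o`), so that for boundary
#' anchors positive offsets consistently point out of the HMR into the
#' methylated flank. Offsets falling off the track are masked: they reduce
#' that offset's contributing count `n` rather than contributing zeros.
#'
#' @param track an `occupancy_track`.
#' @param anchors data.frame with column `pos` (0-based) and optionally
#'   `side` (`"5prime"`/`"3prime"`, default all 5prime).
#' @param flank half-width of the offset range in bp.
#' @param orient mirror 3prime anchors (default `TRUE`).
#' @return a `meta_profile`: list with `offsets` (-flank..flank), `mean`
#'   (NA where no anchor contributes), `n` (per-offset count), and
#'   `anchor_mode`.
#' @export
metaprofile <- function(track, anchors, flank = 2000, orient = TRUE) {
  stopifnot(inherits(track, "occupancy_track"))
  if (NROW(anchors) == 0L) stop("empty anchor set", call. = FALSE)
  if (is.numeric(anchors)) anchors <- data.frame(pos = anchors)
  side <- anchors$side %||% rep("5prime", nrow(anchors))
  offsets <- seq.int(-flank, flank)
  sgn <- ifelse(orient & side == "3prime", -1, 1)
  # n_anchor x n_offset matrix of absolute positions
  posm <- outer(anchors$pos * 1, rep(1, length(offsets))) +
    outer(sgn, offsets)
  vals <- matrix(track_values_at(track, as.vector(posm)), nrow(posm))
  n <- colSums(!is.na(vals))
  total <- colSums(vals, na.rm = TRUE)
  structure(list(
    offsets = offsets,
    mean = ifelse(n > 0, total / pmax(n, 1L), NA_real_),
    n = n,
    anchor_mode = attr(anchors, "anchor_mode") %||% "custom"
  ), class = "meta_profile")
}

#' @export
print.meta_profile <- function(x, ...) {
  cat(sprintf("meta_profile: offsets %d..%d, %d anchors max, peak at %+d\n",
              min(x$offsets), max(x$offsets), max(x$n),
              x$offsets[which.max(x$mean)]))
  invisible(x)
}

#' Anchored occupancy heatmap matrix sorted by interval length
#'
#' One row per interval, anchored at the chosen boundary; rows ordered by
#' increasing interval length. Off-track cells are `NA`.
#'
#' @param track an `occupancy_track`.
#' @param intervals interval data.frame; if it carries `boundary_5` /
#'   `boundary_3` columns those are used as anchors, else `start` / the
#'   last covered base.
#' @param anchor_side `"5prime"` or `"3prime"`.
#' @param flank half-width in bp.
#' @param sort_key only `"length"`.
#' @param decreasing sort direction flag.
#' @return list with `matrix` (rows = intervals in sorted order, columns
#'   named by offset), `lengths` (sorted), `order` (row indices into the
#'   input), `offsets`.
#' @export
heatmap_matrix <- function(track, intervals, anchor_side = c("5prime",
                                                             "3prime"),
                           flank = 2000, sort_key = c("length"),
                           decreasing = FALSE) {
  anchor_side <- match.arg(anchor_side)
  sort_key <- match.arg(sort_key)
  offsets <- seq.int(-flank, flank)
  if (nrow(intervals) == 0L) {
    return(list(matrix = matrix(numeric(0), 0L, length(offsets),
                                dimnames = list(NULL, offsets)),
                lengths = numeric(0), order = integer(0),
                offsets = offsets))
  }
  anchors <- if (anchor_side == "5prime") {
    intervals$boundary_5 %||% intervals$start
  } else {
    intervals$boundary_3 %||% (intervals$end - 1)
  }
  len <- intervals$end - intervals$start
  ord <- order(len, decreasing = decreasing)
  posm <- outer(anchors[ord], rep(1, length(offsets))) +
    outer(rep(1, length(ord)), offsets)
  m <- matrix(track_values_at(track, as.vector(posm)), length(ord),
              dimnames = list(NULL, offsets))
  list(matrix = m, lengths = len[ord], order = ord, offsets = offsets)
}

#' Estimate nucleosome phasing period from a metaprofile
#'
#' The period is the lag of the maximum of the mean-subtracted
#' autocorrelation of the profile within `search_range`; the prominence is
#' that autocorrelation value (1 = perfectly periodic, ~0 = none).
#'
#' @param profile a `meta_profile` (or plain numeric signal).
#' @param search_range two-element bp range of candidate periods.
#' @return list with `period` (bp) and `prominence`.
#' @export
estimate_periodicity <- function(profile, search_range = c(120, 260)) {
  x <- if (inherits(profile, "meta_profile")) profile$mean else
    as.numeric(profile)
  x <- x[!is.na(x)]
  lags <- seq.int(search_range[1L], search_range[2L])
  if (length(x) < max(lags) + 3L)
    stop("profile shorter than the period search range", call. = FALSE)
  ac <- drop(acf(x, lag.max = max(lags), plot = FALSE,
                 demean = TRUE)$acf)
  vals <- ac[lags + 1L]
  best <- which.max(vals)
  list(period = lags[best], prominence = vals[best])
}

#' Permutation null for periodicity prominence
#'
#' Shuffles the profile values and returns the prominence distribution of
#' the best in-range period, for judging whether an observed prominence
#' exceeds chance.
#'
#' @inheritParams estimate_periodicity
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return numeric vector of null prominences (length `n_perm`).
#' @export
periodicity_null <- function(profile, search_range = c(120, 260),
                             n_perm = 1000, seed = 1) {
  x <- if (inherits(profile, "meta_profile")) profile$mean else
    as.numeric(profile)
  x <- x[!is.na(x)]
  set.seed(check_seed(seed))
  vapply(seq_len(n_perm), function(i) {
    estimate_periodicity(sample(x), search_range)$prominence
  }, 0)
}
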