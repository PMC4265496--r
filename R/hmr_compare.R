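# Cross-tissue HMR taxonomy: common vs tissue-specific labels, CGI and TSS
# overlap, and extended HMR pairs with boundaries 1/2/3.

#' Classify HMRs across two cell types
#'
#' A pair of HMRs (one per set) is "common" when their reciprocal overlap
#' is at least `overlap_frac` of each interval. Matching is one-to-one:
#' candidate pairs are taken in order of greatest reciprocal overlap
#' (the smaller of the two overlap fractions), ties broken by leftmost
#' partner. Unmatched HMRs are tissue-specific.
#'
#' @param hmrs_a,hmrs_b interval data.frames (sorted, disjoint within set).
#' @param overlap_frac required reciprocal overlap fraction.
#' @return list with `labels_a` and `labels_b`, each a data.frame with
#'   `label` (`common` / `a_specific` / `b_specific`) and `partner`
#'   (row index in the other set, `NA` unless common).
#' @export
classify_hmrs <- function(hmrs_a, hmrs_b, overlap_frac = 0.5) {
  validate_intervals(hmrs_a, "hmrs_a")
  validate_intervals(hmrs_b, "hmrs_b")
  la <- data.frame(label = rep("a_specific", nrow(hmrs_a)),
                   partner = NA_integer_, stringsAsFactors = FALSE)
  lb <- data.frame(label = rep("b_specific", nrow(hmrs_b)),
                   partner = NA_integer_, stringsAsFactors = FALSE)
  if (nrow(hmrs_a) && nrow(hmrs_b)) {
    hits <- GenomicRanges::findOverlaps(as_gr(hmrs_a), as_gr(hmrs_b))
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    if (length(qi)) {
      ov <- pmin(hmrs_a$end[qi], hmrs_b$end[si]) -
        pmax(hmrs_a$start[qi], hmrs_b$start[si])
      fa <- ov / (hmrs_a$end[qi] - hmrs_a$start[qi])
      fb <- ov / (hmrs_b$end[si] - hmrs_b$start[si])
      recip <- pmin(fa, fb)
      keep <- recip >= overlap_frac
      qi <- qi[keep]; si <- si[keep]; recip <- recip[keep]
      ord <- order(-recip, hmrs_b$start[si], hmrs_a$start[qi])
      for (h in ord) {
        i <- qi[h]; j <- si[h]
        if (la$label[i] == "common" || lb$label[j] == "common") next
        la$label[i] <- "common"; la$partner[i] <- j
        lb$label[j] <- "common"; lb$partner[j] <- i
      }
    }
  }
  list(labels_a = la, labels_b = lb)
}

#' Fraction of HMRs overlapping CpG islands
#'
#' An HMR overlaps a CGI when they share at least one bp.
#'
#' @param hmrs,cgis interval data.frames.
#' @return list with `n_total`, `n_overlap`, `n_non_overlap`, `fraction`
#'   (overlapping / total).
#' @export
cgi_overlap_fraction <- function(hmrs, cgis) {
  validate_intervals(hmrs, "hmrs")
  validate_intervals(cgis, "cgis")
  if (nrow(hmrs) == 0L) stop("empty HMR set", call. = FALSE)
  n_ov <- if (nrow(cgis) == 0L) 0L else
    sum(GenomicRanges::countOverlaps(as_gr(hmrs), as_gr(cgis)) > 0L)
  list(n_total = nrow(hmrs), n_overlap = n_ov,
       n_non_overlap = nrow(hmrs) - n_ov, fraction = n_ov / nrow(hmrs))
}

#' Find extended HMR pairs across two cell types
#'
#' Scans overlapping HMR pairs for those sharing exactly one boundary
#' (within `identical_tol` bp of the first unmethylated CG) while the other
#' boundary differs by more than `identical_tol`. The shared position is
#' boundary 1, the inner non-shared boundary (end of the shorter HMR) is
#' boundary 2, the outer one (end of the longer HMR) boundary 3. Pairs
#' identical at both ends are excluded.
#'
#' @param hmrs_a,hmrs_b HMR data.frames carrying `boundary_5` and
#'   `boundary_3` columns (see [hmr_boundaries()]).
#' @param identical_tol bp tolerance for boundary identity.
#' @return data.frame with `shared_boundary`, `short_boundary`,
#'   `long_boundary`, `extension_length`, `extended_in` (`"a"`/`"b"`),
#'   `shared_side`, `a_idx`, `b_idx`; attribute `summary` holds the mean
#'   and median extension length.
#' @export
find_extended_pairs <- function(hmrs_a, hmrs_b, identical_tol = 0) {
  stopifnot(all(c("boundary_5", "boundary_3") %in% names(hmrs_a)),
            all(c("boundary_5", "boundary_3") %in% names(hmrs_b)))
  empty <- data.frame(shared_boundary = numeric(), short_boundary =
                        numeric(), long_boundary = numeric(),
                      extension_length = numeric(),
                      extended_in = character(), shared_side = character(),
                      a_idx = integer(), b_idx = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(hmrs_a) == 0L || nrow(hmrs_b) == 0L) {
    attr(empty, "summary") <- list(mean = NA_real_, median = NA_real_)
    return(empty)
  }
  hits <- GenomicRanges::findOverlaps(as_gr(hmrs_a), as_gr(hmrs_b))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  rows <- list()
  for (h in seq_along(qi)) {
    i <- qi[h]; j <- si[h]
    same5 <- abs(hmrs_a$boundary_5[i] - hmrs_b$boundary_5[j]) <=
      identical_tol
    same3 <- abs(hmrs_a$boundary_3[i] - hmrs_b$boundary_3[j]) <=
      identical_tol
    if (is.na(same5) || is.na(same3)) next
    if (same5 == same3) next  # both identical or both different
    if (same5) {
      shared <- hmrs_a$boundary_5[i]
      pa <- hmrs_a$boundary_3[i]; pb <- hmrs_b$boundary_3[j]
      side <- "5prime"
    } else {
      shared <- hmrs_a$boundary_3[i]
      pa <- hmrs_a$boundary_5[i]; pb <- hmrs_b$boundary_5[j]
      side <- "3prime"
    }
    # the longer HMR's free boundary is farther from the shared one
    a_longer <- abs(pa - shared) > abs(pb - shared)
    rows[[length(rows) + 1L]] <- data.frame(
      shared_boundary = shared,
      short_boundary = if (a_longer) pb else pa,
      long_boundary = if (a_longer) pa else pb,
      extension_length = abs(pa - pb),
      extended_in = if (a_longer) "a" else "b",
      shared_side = side, a_idx = i, b_idx = j,
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  rownames(out) <- NULL
  attr(out, "summary") <- list(
    mean = if (nrow(out)) mean(out$extension_length) else NA_real_,
    median = if (nrow(out)) median(out$extension_length) else NA_real_)
  out
}

#' Classify HMRs by proximity to transcription start sites
#'
#' `contains_tss` when a TSS lies inside the interval; `within_2kb` when
#' the nearest TSS is within `within` bp of the interval; else `distal`.
#'
#' @param hmrs interval data.frame.
#' @param tss data.frame with `chrom`, `pos` (0-based TSS positions) or a
#'   numeric position vector (single chromosome).
#' @param within proximity threshold in bp.
#' @return character vector of classes (one per HMR) with attribute
#'   `fractions` (named class fractions).
#' @export
tss_proximity <- function(hmrs, tss, within = 2000) {
  validate_intervals(hmrs, "hmrs")
  if (is.numeric(tss))
    tss <- data.frame(chrom = unique(hmrs$chrom)[1L], pos = tss)
  cls <- rep("distal", nrow(hmrs))
  by_chrom <- lapply(split(tss$pos, tss$chrom), sort)
  for (i in seq_len(nrow(hmrs))) {
    p <- by_chrom[[hmrs$chrom[i]]]
    if (is.null(p) || !length(p)) next
    s <- hmrs$start[i]; e <- hmrs$end[i]
    if (any(p >= s & p < e)) {
      cls[i] <- "contains_tss"
    } else {
      d <- min(abs(p - s), abs(p - (e - 1)))
      if (d <= within) cls[i] <- "within_2kb"
    }
  }
  frac <- table(factor(cls, levels = c("contains_tss", "within_2kb",
                                       "distal"))) / length(cls)
  attr(cls, "fractions") <- c(frac)
  cls
}
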