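# Boundary nucleosome peak scoring/stratification, boundary-CG 6-mer
# enrichment, CACGTG observed/expected positional ratios, and ROC/AUC.

#' Score nucleosome occupancy at boundary CGs and stratify
#'
#' The score of a boundary is the mean track value over
#' `[b - halfwidth, b + halfwidth]` (one nucleosome footprint by default);
#' positions off the track are masked from the mean. Boundaries are then
#' cut into bottom 20% / middle / top 20% strata by score, ties resolved
#' deterministically by position order.
#'
#' @param track an `occupancy_track`.
#' @param boundaries 0-based boundary positions (numeric vector or
#'   data.frame with `pos`).
#' @param halfwidth window half-width in bp.
#' @return data.frame with `pos`, `score`, `stratum` (`bottom20` / `mid` /
#'   `top20`).
#' @export
boundary_peak_scores <- function(track, boundaries, halfwidth = 73) {
  pos <- if (is.data.frame(boundaries)) boundaries$pos else
    as.numeric(boundaries)
  offs <- seq.int(-halfwidth, halfwidth)
  posm <- outer(pos, rep(1, length(offs))) +
    outer(rep(1, length(pos)), offs)
  vals <- matrix(track_values_at(track, as.vector(posm)), length(pos))
  score <- rowMeans(vals, na.rm = TRUE)
  n <- length(pos)
  nb <- round(0.2 * n)
  nt <- round(0.2 * n)
  ord <- order(score, seq_len(n))  # position order breaks ties
  stratum <- rep("mid", n)
  if (nb > 0L) stratum[ord[seq_len(nb)]] <- "bottom20"
  if (nt > 0L) stratum[ord[seq.int(n - nt + 1L, n)]] <- "top20"
  data.frame(pos = pos, score = score, stratum = stratum,
             stringsAsFactors = FALSE)
}

#' Central k-mers at boundary CGs
#'
#' For each boundary with a CG dinucleotide at (b, b+1), returns the k-bp
#' window placing the CG centrally (for k = 6: `b-2 .. b+3`). k-mers at
#' `3prime`-side boundaries are reverse-complemented so the CG orientation
#' relative to the HMR is consistent across sides. Boundaries without a CG
#' or with windows off the sequence end are skipped and counted in the
#' `report` attribute.
#'
#' @param genome a single sequence string.
#' @param boundaries numeric positions or data.frame with `pos` and
#'   optional `side`.
#' @param k even k-mer length.
#' @return character vector of k-mers; attribute `report` = list(n_in,
#'   n_used, n_not_cg, n_off_end).
#' @export
boundary_kmer_table <- function(genome, boundaries, k = 6) {
  if (k %% 2 != 0) stop("k must be even (central CG)", call. = FALSE)
  genome <- as.character(genome[[1L]])
  L <- nchar(genome)
  if (is.data.frame(boundaries)) {
    pos <- boundaries$pos
    side <- boundaries$side %||% rep("5prime", length(pos))
  } else {
    pos <- as.numeric(boundaries)
    side <- rep("5prime", length(pos))
  }
  left <- k / 2 - 1
  lo <- pos - left          # 0-based window start
  hi <- pos + k / 2 + 1     # 0-based exclusive end
  off_end <- lo < 0 | hi > L
  kmers <- rep(NA_character_, length(pos))
  ok <- !off_end
  kmers[ok] <- substring(genome, lo[ok] + 1L, hi[ok])
  is_cg <- !is.na(kmers) &
    substr(kmers, left + 1L, left + 2L) == "CG"
  use <- ok & is_cg
  out <- kmers[use]
  flip <- side[use] == "3prime"
  if (any(flip)) out[flip] <- revcomp(out[flip])
  attr(out, "report") <- list(n_in = length(pos), n_used = sum(use),
                              n_not_cg = sum(ok & !is_cg),
                              n_off_end = sum(off_end))
  out
}

#' 6-mer enrichment between two boundary strata
#'
#' Tabulates k-mer counts and raw frequencies per stratum (frequencies sum
#' to 1 within each set) and the enrichment
#' `log2((f_top + pseudocount) / (f_bottom + pseudocount))`, sorted
#' decreasing. The pseudocount is added to the frequencies; with the
#' default of 1 the ordering is driven by the frequency difference, so a
#' k-mer seen a handful of times in one stratum and never in the other
#' cannot outrank a strong planted enrichment.
#'
#' @param kmers_top,kmers_bottom character vectors of central k-mers (from
#'   [boundary_kmer_table()]).
#' @param pseudocount added to each frequency before the ratio.
#' @return data.frame with `kmer`, `count_top`, `count_bottom`,
#'   `freq_top`, `freq_bottom`, `log2_ratio`, sorted by `log2_ratio`
#'   decreasing.
#' @export
kmer_enrichment <- function(kmers_top, kmers_bottom, pseudocount = 1) {
  if (!length(kmers_top) || !length(kmers_bottom))
    stop("both k-mer sets must be non-empty", call. = FALSE)
  kk <- sort(unique(c(kmers_top, kmers_bottom)))
  ct <- as.numeric(table(factor(kmers_top, levels = kk)))
  cb <- as.numeric(table(factor(kmers_bottom, levels = kk)))
  nt <- length(kmers_top); nb <- length(kmers_bottom)
  ft_pc <- ct / nt + pseudocount
  fb_pc <- cb / nb + pseudocount
  out <- data.frame(kmer = kk, count_top = ct, count_bottom = cb,
                    freq_top = ct / nt, freq_bottom = cb / nb,
                    log2_ratio = log2(ft_pc / fb_pc),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$log2_ratio, out$kmer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# all CG dinucleotide positions (0-based position of the C) in a sequence
cg_positions <- function(genome) {
  genome <- as.character(genome[[1L]])
  m <- gregexpr("CG", genome, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer(0))
  as.integer(m) - 1L
}

#' Observed/expected motif frequency at CGs indexed from HMR boundaries
#'
#' CG sites are indexed from each boundary CG (index 0 = the first
#' unmethylated CG): positive indices step inward (into the HMR), negative
#' indices outward (into the methylated flank). Observed(i) is the
#' fraction of index-i CGs whose centered 6-mer equals `pattern`
#' (reverse-complemented at 3prime boundaries); expected is the fraction
#' over all CG sites genome-wide. The ratio observed/expected is reported
#' per index.
#'
#' @param genome a single sequence string.
#' @param boundaries data.frame with `pos` and `side` (both-side boundary
#'   CGs of the HMR set; see [hmr_boundaries()]).
#' @param pattern even-length motif with a central CG.
#' @param cg_offsets integer CG indices to evaluate.
#' @return data.frame with `index`, `n`, `observed`, `expected`, `ratio`.
#' @export
obs_exp_positional <- function(genome, boundaries, pattern = "CACGTG",
                               cg_offsets = -5:5) {
  k <- nchar(pattern)
  if (k %% 2 != 0 ||
      substr(pattern, k / 2, k / 2 + 1) != "CG")
    stop("pattern must have even length and a central CG", call. = FALSE)
  genome <- as.character(genome[[1L]])
  cgs <- cg_positions(genome)
  if (!length(cgs)) stop("no CG sites in genome", call. = FALSE)
  all_kmers <- boundary_kmer_table(genome, cgs, k = k)
  expected <- mean(all_kmers == pattern)
  pos <- boundaries$pos
  side <- boundaries$side %||% rep("5prime", length(pos))
  bidx <- match(pos, cgs)
  res <- lapply(cg_offsets, function(i) {
    # inward is rightward for 5prime boundaries, leftward for 3prime
    step <- ifelse(side == "5prime", i, -i)
    at <- bidx + step
    ok <- !is.na(at) & at >= 1L & at <= length(cgs)
    if (!any(ok))
      return(data.frame(index = i, n = 0L, observed = NA_real_,
                        expected = expected, ratio = NA_real_))
    km <- boundary_kmer_table(
      genome, data.frame(pos = cgs[at[ok]], side = side[ok]), k = k)
    obs <- mean(km == pattern)
    data.frame(index = i, n = length(km), observed = obs,
               expected = expected, ratio = obs / expected)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' ROC curve and AUC by the rank (Mann-Whitney) formulation
#'
#' AUC uses midranks, so ties count one half; ROC points are emitted at
#' every distinct score threshold.
#'
#' @param scores numeric predictor values.
#' @param labels logical (or 0/1) class labels; both classes must be
#'   present.
#' @return list with `auc` and `roc` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (anyNA(scores) || anyNA(labels))
    stop("NA in scores or labels", call. = FALSE)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present", call. = FALSE)
  r <- rank(scores)  # midranks
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  keep <- c(diff(s) != 0, TRUE)  # last duplicate of each threshold run
  tp <- cumsum(l)[keep]
  fp <- cumsum(!l)[keep]
  roc <- rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
               data.frame(threshold = s[keep], fpr = fp / n0,
                          tpr = tp / n1))
  rownames(roc) <- NULL
  list(auc = auc, roc = roc)
}
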