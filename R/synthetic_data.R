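# Seeded generators for genomes, methylomes, MNase fragment sets and
# planted motifs, with complete ground truth, so every pipeline stage has a
# recoverable planted signal.

#' Simulate a genome with CpG islands and a CpG-depleted background
#'
#' Background bases are i.i.d. at the target GC fraction, then CG
#' dinucleotides outside islands are depleted (the G mutated to A with
#' probability `cpg_depletion`) to emulate the CpG depletion of mammalian
#' genomes. Islands are elevated-GC, undepteted (hence CpG-enriched)
#' intervals placed non-overlapping on an even grid with random jitter.
#'
#' @param length genome length in bp.
#' @param gc background GC fraction.
#' @param cgi list with `count`, `length`, `gc` for the islands.
#' @param cpg_depletion probability a background CG is destroyed.
#' @param seed RNG seed.
#' @return list with `genome` (named character vector, one chromosome
#'   `chr1`) and `truth` (list with `cgis` interval data.frame, `seed`).
#' @export
simulate_genome <- function(length, gc = 0.42,
                            cgi = list(count = 20, length = 1000,
                                       gc = 0.65),
                            cpg_depletion = 0.75, seed = 1) {
  seed <- check_seed(seed)
  if (length < 10 * cgi$count * cgi$length)
    stop("infeasible packing: genome too short for the CGI spec",
         call. = FALSE)
  set.seed(seed)
  base_probs <- function(g) c(A = (1 - g) / 2, C = g / 2, G = g / 2,
                              T = (1 - g) / 2)
  chars <- sample(DNA_BASES, length, replace = TRUE,
                  prob = base_probs(gc))
  # islands on an even grid with jitter
  step <- floor(length / cgi$count)
  starts <- (seq_len(cgi$count) - 1L) * step +
    floor(runif(cgi$count, 0.1, 0.9) * (step - cgi$length))
  cgis <- new_intervals("chr1", starts, starts + cgi$length,
                        name = paste0("cgi_", seq_len(cgi$count)))
  for (i in seq_len(cgi$count)) {
    idx <- (starts[i] + 1L):(starts[i] + cgi$length)
    chars[idx] <- sample(DNA_BASES, cgi$length, replace = TRUE,
                         prob = base_probs(cgi$gc))
  }
  # CpG depletion outside islands
  is_cgi <- rep(FALSE, length)
  for (i in seq_len(cgi$count))
    is_cgi[(starts[i] + 1L):(starts[i] + cgi$length)] <- TRUE
  cg_at <- which(chars[-length] == "C" & chars[-1L] == "G")  # 1-based C
  cg_at <- cg_at[!is_cgi[cg_at]]
  kill <- cg_at[runif(length(cg_at)) < cpg_depletion]
  chars[kill + 1L] <- "A"
  genome <- c(chr1 = paste(chars, collapse = ""))
  list(genome = genome,
       truth = list(cgis = cgis, gc = gc, cgi_spec = cgi, seed = seed))
}

default_hmr_plan <- function() {
  list(n_common = 30, n_specific_a = 15, n_specific_b = 15,
       n_extended = 15, frac_common_cgi = 0.35,
       span_range = c(500, 1500),
       extension = function(n) pmin(pmax(round(rlnorm(n, log(170), 1)),
                                         100), 2000),
       min_cpgs = 6)
}

set_chars <- function(chars, pos0, s) {
  # write string s at 0-based position pos0
  chars[(pos0 + 1L):(pos0 + nchar(s))] <- strsplit(s, "")[[1L]]
  chars
}

clear_cgs <- function(chars, from0, to0) {
  # destroy CG dinucleotides whose C lies in 0-based [from0, to0]
  if (to0 < from0) return(chars)
  i <- (from0 + 1L):(to0 + 1L)
  i <- i[i >= 1L & i < length(chars)]
  hit <- i[chars[i] == "C" & chars[i + 1L] == "G"]
  chars[hit + 1L] <- "A"
  chars
}

#' Simulate two-cell methylomes with planted HMR structure
#'
#' Plants common, tissue-specific and extended HMRs on the genome. Each
#' HMR's first and last CpGs are written into the sequence at exact
#' positions; a CpG-free "moat" is carved outside each outer boundary and
#' the adjacent methylated CG planted at a gap drawn uniform from
#' `boundary_gap` (default 100-200 bp, mean 150). Extended pairs share one
#' boundary CG exactly, the other end extended in one cell by a draw from
#' the plan's extension distribution (default lognormal, median 170 bp /
#' mean ~280 bp). Every CpG of the (modified) genome then receives
#' beta-binomial counts from its per-cell state. Because boundary CpGs are
#' planted, the returned `genome` differs from the input and must be used
#' downstream.
#'
#' @param genome single-chromosome genome (named character vector).
#' @param hmr_plan list; see `default_hmr_plan` in the package source:
#'   counts `n_common`, `n_specific_a`, `n_specific_b`, `n_extended`,
#'   `frac_common_cgi`, `span_range`, `extension` (function of n),
#'   `min_cpgs`.
#' @param coverage mean Poisson read coverage per CpG.
#' @param levels list with `hypo`, `meth` mean methylation levels and
#'   `dispersion` (beta-binomial rho, both states).
#' @param boundary_gap range of the first-unmethylated-to-adjacent-
#'   methylated CG gap in bp.
#' @param cgis optional CGI intervals (from [simulate_genome()] truth);
#'   a `frac_common_cgi` share of common HMRs is then placed inside CGIs.
#' @param seed RNG seed.
#' @return list with `methylomes` (`$a`, `$b` CpG record data.frames),
#'   `truth` (planted HMR tables with labels and boundaries, extended
#'   pairs, planted gaps, seed) and `genome` (modified).
#' @export
simulate_methylome <- function(genome, hmr_plan = NULL, coverage = 20,
                               levels = list(hypo = 0.05, meth = 0.85,
                                             dispersion = 0.1),
                               boundary_gap = c(100, 200), cgis = NULL,
                               seed = 1) {
  seed <- check_seed(seed)
  plan <- utils::modifyList(default_hmr_plan(), hmr_plan %||% list())
  gname <- names(genome)[1L] %||% "chr1"
  chars <- strsplit(as.character(genome[[1L]]), "")[[1L]]
  L <- length(chars)
  set.seed(seed)
  n_tot <- plan$n_common + plan$n_specific_a + plan$n_specific_b +
    plan$n_extended
  margin <- 2600  # room for flanks, moats and extensions
  slot_w <- max(plan$span_range) + 2L * margin + 200L
  n_slots <- floor(L / slot_w)
  if (n_slots < n_tot)
    stop("plan infeasible: genome too short for the HMR plan",
         call. = FALSE)
  types <- sample(c(rep("common", plan$n_common),
                    rep("a_specific", plan$n_specific_a),
                    rep("b_specific", plan$n_specific_b),
                    rep("extended", plan$n_extended)))
  n_cgi_common <- if (!is.null(cgis))
    min(round(plan$frac_common_cgi * plan$n_common), nrow(cgis)) else 0L
  cgi_pick <- if (n_cgi_common > 0L)
    sample(nrow(cgis), n_cgi_common) else integer(0)
  cgi_assigned <- 0L
  placed <- matrix(numeric(0), ncol = 2L)  # occupied spans incl. margin
  if (!is.null(cgis) && nrow(cgis))
    placed <- cbind(cgis$start - 1000, cgis$end + 1000)
  hmrs <- list()
  slot <- 0L
  for (ti in seq_along(types)) {
    ty <- types[ti]
    span <- round(runif(1L, plan$span_range[1L], plan$span_range[2L]))
    in_cgi <- FALSE
    if (ty == "common" && cgi_assigned < n_cgi_common) {
      cgi_assigned <- cgi_assigned + 1L
      ci <- cgi_pick[cgi_assigned]
      span <- min(span, cgis$end[ci] - cgis$start[ci] - 100)
      s <- cgis$start[ci] + floor((cgis$end[ci] - cgis$start[ci] -
                                     span) / 2)
      in_cgi <- TRUE
    } else {
      s <- NA_real_
      for (try in 1:80) {
        slot <- slot + 1L
        base <- (slot %% n_slots) * slot_w
        cand <- base + margin +
          floor(runif(1L, 0, max(slot_w - span - 2 * margin, 1)))
        if (cand + span + margin > L) next
        lo <- cand - margin; hi <- cand + span + margin
        if (nrow(placed) == 0L ||
            all(hi <= placed[, 1L] | lo >= placed[, 2L])) {
          s <- cand
          break
        }
      }
      if (is.na(s)) stop("plan infeasible: could not place all HMRs",
                         call. = FALSE)
    }
    hmrs[[ti]] <- list(type = ty, s = s, span = span, in_cgi = in_cgi)
    placed <- rbind(placed, c(s - margin, s + span + margin))
  }
  # write boundary and interior CpGs, moats, extensions
  gaps <- list()
  ext_rows <- list()
  rows_a <- list(); rows_b <- list()
  pair_id <- 0L
  for (h in hmrs) {
    b5 <- h$s
    b3 <- h$s + h$span - 2
    chars <- set_chars(chars, b5, "CG")
    chars <- set_chars(chars, b3, "CG")
    n_int <- max(plan$min_cpgs - 2L, 4L)
    for (q in seq_len(n_int)) {
      p <- b5 + round(h$span * q / (n_int + 1L))
      if (p > b5 + 2 && p < b3 - 2) chars <- set_chars(chars, p, "CG")
    }
    lo_b <- b5; hi_b <- b3  # outermost boundaries of the union
    ext <- NA_real_; ext_side <- NA_character_; ext_in <- NA_character_
    if (h$type == "extended") {
      ext <- plan$extension(1L)
      ext_side <- sample(c("5prime", "3prime"), 1L)
      ext_in <- sample(c("a", "b"), 1L)
      g2 <- round(runif(1L, boundary_gap[1L], boundary_gap[2L]))
      if (ext_side == "3prime") {
        bL <- b3 + ext
        # the short cell's boundary gap is planted too: no natural CpG
        # between its last CpG and the first extension-zone CpG
        chars <- clear_cgs(chars, b3 + 2, b3 + g2 - 1)
        zone <- if (b3 + g2 <= bL - 10)
          seq(b3 + g2, bL - 10, by = 120) else numeric(0)
        for (p in zone) chars <- set_chars(chars, p, "CG")
        chars <- set_chars(chars, bL, "CG")
        hi_b <- bL
      } else {
        bL <- b5 - ext
        chars <- clear_cgs(chars, b5 - g2 + 1, b5 - 2)
        zone <- if (b5 - g2 >= bL + 10)
          seq(b5 - g2, bL + 10, by = -120) else numeric(0)
        for (p in zone) chars <- set_chars(chars, p, "CG")
        chars <- set_chars(chars, bL, "CG")
        lo_b <- bL
      }
    }
    # moats + adjacent methylated CG outside the outermost boundaries
    g5 <- round(runif(1L, boundary_gap[1L], boundary_gap[2L]))
    g3 <- round(runif(1L, boundary_gap[1L], boundary_gap[2L]))
    chars <- clear_cgs(chars, lo_b - g5, lo_b - 1)
    chars <- clear_cgs(chars, hi_b + 2, hi_b + g3 + 1)
    chars <- set_chars(chars, lo_b - g5, "CG")
    chars <- set_chars(chars, hi_b + g3, "CG")
    gaps[[length(gaps) + 1L]] <- data.frame(gap5 = g5, gap3 = g3)
    # per-cell intervals (end = last CpG position + 1)
    mk <- function(s0, e_cpg, label, pid) data.frame(
      chrom = gname, start = s0, end = e_cpg + 1, label = label,
      pair_id = pid, in_cgi = h$in_cgi, stringsAsFactors = FALSE)
    if (h$type == "common") {
      rows_a[[length(rows_a) + 1L]] <- mk(b5, b3, "common", NA)
      rows_b[[length(rows_b) + 1L]] <- mk(b5, b3, "common", NA)
    } else if (h$type == "a_specific") {
      rows_a[[length(rows_a) + 1L]] <- mk(b5, b3, "a_specific", NA)
    } else if (h$type == "b_specific") {
      rows_b[[length(rows_b) + 1L]] <- mk(b5, b3, "b_specific", NA)
    } else {
      pair_id <- pair_id + 1L
      short <- mk(b5, b3, "extended_short", pair_id)
      long <- mk(lo_b, hi_b, "extended_long", pair_id)
      if (ext_in == "a") {
        rows_a[[length(rows_a) + 1L]] <- long
        rows_b[[length(rows_b) + 1L]] <- short
      } else {
        rows_a[[length(rows_a) + 1L]] <- short
        rows_b[[length(rows_b) + 1L]] <- long
      }
      b1 <- if (ext_side == "3prime") b5 else b3
      b2 <- if (ext_side == "3prime") b3 else b5
      b3x <- if (ext_side == "3prime") hi_b else lo_b
      ext_rows[[length(ext_rows) + 1L]] <- data.frame(
        pair_id = pair_id, boundary1 = b1, boundary2 = b2,
        boundary3 = b3x, extension_length = abs(b3x - b2),
        extended_in = ext_in, shared_side = if (ext_side == "3prime")
          "5prime" else "3prime", stringsAsFactors = FALSE)
    }
  }
  genome_mod <- paste(chars, collapse = "")
  names(genome_mod) <- gname
  finish <- function(rows) {
    df <- do.call(rbind, rows)
    df <- df[order(df$start), , drop = FALSE]
    rownames(df) <- NULL
    df$boundary_5 <- df$start
    df$boundary_3 <- df$end - 1
    df
  }
  truth_a <- finish(rows_a)
  truth_b <- finish(rows_b)
  # emissions over the final CpG set
  cgs <- cg_positions(genome_mod)
  rho <- levels$dispersion
  emit <- function(truth_df, cell_seed) {
    set.seed(cell_seed)
    st <- findInterval(cgs, truth_df$start)
    hypo <- st >= 1L & cgs < truth_df$end[pmax(st, 1L)]
    mu <- ifelse(hypo, levels$hypo, levels$meth)
    n <- rpois(length(cgs), coverage)
    keep <- n > 0L
    p <- rbeta(length(cgs), mu * (1 - rho) / rho,
               (1 - mu) * (1 - rho) / rho)
    m <- rbinom(length(cgs), n, p)
    data.frame(chrom = gname, pos = cgs[keep], meth_count = m[keep],
               total_count = n[keep], level = m[keep] / n[keep],
               stringsAsFactors = FALSE)
  }
  truth <- list(
    hmrs_a = truth_a, hmrs_b = truth_b,
    extended_pairs = if (length(ext_rows)) do.call(rbind, ext_rows) else
      NULL,
    boundary_gaps = do.call(rbind, gaps),
    cgis = cgis, levels = levels, coverage = coverage, seed = seed
  )
  list(
    methylomes = list(a = emit(truth_a, seed + 101L),
                      b = emit(truth_b, seed + 202L)),
    truth = truth,
    genome = genome_mod
  )
}

#' Simulate MNase fragments with boundary-phased nucleosomes
#'
#' Fragment midpoints are drawn from a mixture of a uniform background and
#' Gaussian-positioned nucleosomes placed at `boundary + k * period`
#' (k = 0..n_phased-1) propagating outward into the methylated flank of
#' every HMR boundary of the chosen cell, with amplitude decaying
#' geometrically per nucleosome. `fold` is the peak midpoint density of
#' the k = 0 nucleosome in background units (0 = uniform background only).
#' Insert lengths are rounded normal draws truncated to [50, 300]; with
#' `clip = TRUE` only fragments in [100, 160] survive.
#'
#' @param genome single-chromosome genome.
#' @param truth truth list from [simulate_methylome()].
#' @param cell `"a"` or `"b"`: whose HMR boundaries anchor the nucleosomes.
#' @param phasing list with `fold`, `period` (bp), `n_phased`, `decay`,
#'   `pos_sd` (midpoint jitter sd, bp).
#' @param insert list with `mean`, `sd`, `clip`.
#' @param n_fragments number of fragments drawn (before end/clip losses).
#' @param seed RNG seed.
#' @return fragment data.frame (`chrom`, `start`, `end`).
#' @export
simulate_fragments <- function(genome, truth, cell = c("a", "b"),
                               phasing = list(fold = 8, period = 165,
                                              n_phased = 3, decay = 0.7,
                                              pos_sd = 20),
                               insert = list(mean = 147, sd = 10,
                                             clip = FALSE),
                               n_fragments = 2e5, seed = 1) {
  cell <- match.arg(cell)
  seed <- check_seed(seed)
  if (n_fragments <= 0) stop("n_fragments must be > 0", call. = FALSE)
  ph <- utils::modifyList(list(fold = 8, period = 165, n_phased = 3,
                               decay = 0.7, pos_sd = 20), phasing)
  ins <- utils::modifyList(list(mean = 147, sd = 10, clip = FALSE),
                           insert)
  gname <- names(genome)[1L] %||% "chr1"
  L <- nchar(as.character(genome[[1L]]))
  hm <- if (cell == "a") truth$hmrs_a else truth$hmrs_b
  centers <- numeric(0); weights <- numeric(0)
  if (ph$fold > 0 && nrow(hm)) {
    for (k in seq_len(ph$n_phased) - 1L) {
      amp <- ph$fold * ph$decay^k * sqrt(2 * pi) * ph$pos_sd / L
      centers <- c(centers, hm$boundary_5 - k * ph$period,
                   hm$boundary_3 + k * ph$period)
      weights <- c(weights, rep(amp, 2L * nrow(hm)))
    }
  }
  set.seed(seed)
  masses <- c(1, weights)  # background mass 1
  comp <- sample.int(length(masses), n_fragments, replace = TRUE,
                     prob = masses)
  mids <- numeric(n_fragments)
  bg <- comp == 1L
  mids[bg] <- floor(runif(sum(bg), 0, L))
  if (any(!bg))
    mids[!bg] <- round(rnorm(sum(!bg), centers[comp[!bg] - 1L],
                             ph$pos_sd))
  len <- pmin(pmax(round(rnorm(n_fragments, ins$mean, ins$sd)), 50), 300)
  if (isTRUE(ins$clip)) {
    keep <- len >= 100 & len <= 160
    mids <- mids[keep]; len <- len[keep]
  }
  start <- mids - floor((len - 1) / 2)
  end <- start + len
  ok <- start >= 0 & end <= L
  data.frame(chrom = gname, start = start[ok], end = end[ok],
             stringsAsFactors = FALSE)
}

#' Plant a motif at boundary CGs and at background CG sites
#'
#' Writes `pattern` centered on the CG of a seeded random subset of the
#' chosen cell's HMR boundary CGs (target share `boundary_fraction`) and
#' of background CG sites (target share `background_rate` of all CG
#' sites). A site is only planted when the surrounding context contains no
#' CG other than the central one, before and after writing, so the genome's
#' CpG set (and hence any methylome generated from it) is unchanged.
#' Ineligible or overlapping sites are skipped and counted in the report.
#'
#' @param genome single-chromosome genome.
#' @param truth truth list from [simulate_methylome()].
#' @param pattern even-length motif with central CG.
#' @param boundary_fraction target fraction of boundary CGs carrying the
#'   motif.
#' @param background_rate target fraction of non-boundary CG sites
#'   carrying it.
#' @param cell whose boundaries to plant at.
#' @param seed RNG seed.
#' @return list with `genome` (modified), `truth` (with
#'   `motif_positions`), `report` (planted/skipped counts).
#' @export
plant_motifs <- function(genome, truth, pattern = "CACGTG",
                         boundary_fraction = 0.2, background_rate = 0.1,
                         cell = c("a", "b"), seed = 1) {
  cell <- match.arg(cell)
  seed <- check_seed(seed)
  k <- nchar(pattern)
  if (k %% 2 != 0 || substr(pattern, k / 2, k / 2 + 1) != "CG")
    stop("pattern must have even length and a central CG", call. = FALSE)
  gname <- names(genome)[1L] %||% "chr1"
  chars <- strsplit(as.character(genome[[1L]]), "")[[1L]]
  L <- length(chars)
  left <- as.integer(k / 2 - 1)
  hm <- if (cell == "a") truth$hmrs_a else truth$hmrs_b
  bpos <- sort(unique(c(hm$boundary_5, hm$boundary_3)))
  cgs <- cg_positions(paste(chars, collapse = ""))
  bgpos <- setdiff(cgs, bpos)
  set.seed(seed)
  pat_chars <- strsplit(pattern, "")[[1L]]
  planted <- numeric(0)
  n_skipped <- 0L
  try_plant <- function(b) {
    lo <- b - left; hi <- b + k / 2 + 1  # 0-based window [lo, hi)
    if (lo - 1 < 0 || hi + 1 > L) return(FALSE)
    if (length(planted) && any(abs(planted - b) < k + 2)) return(FALSE)
    ctx <- chars[(lo - 1 + 1):(hi + 1)]  # context incl. 1 bp each side
    cg_in_ctx <- which(ctx[-length(ctx)] == "C" & ctx[-1L] == "G")
    # only the central CG may be present (at context offset left + 2)
    if (!identical(cg_in_ctx, left + 2L)) return(FALSE)
    new_ctx <- ctx
    new_ctx[2:(k + 1)] <- pat_chars
    cg_new <- which(new_ctx[-length(new_ctx)] == "C" &
                      new_ctx[-1L] == "G")
    if (!identical(cg_new, left + 2L)) return(FALSE)
    chars[(lo + 1):(hi)] <<- pat_chars
    planted <<- c(planted, b)
    TRUE
  }
  has_pattern <- function(b) {
    lo <- b - left
    lo >= 0 && lo + k <= L &&
      identical(chars[(lo + 1):(lo + k)], pat_chars)
  }
  plant_set <- function(cand, target) {
    # discount natural occurrences so the realized rate matches the target
    done <- sum(vapply(cand, has_pattern, TRUE))
    cand <- sample(cand[!vapply(cand, has_pattern, TRUE)])
    for (b in cand) {
      if (done >= target) break
      if (try_plant(b)) done <- done + 1L else
        n_skipped <<- n_skipped + 1L
    }
    done
  }
  n_b <- plant_set(bpos, round(boundary_fraction * length(bpos)))
  boundary_planted <- planted
  n_g <- plant_set(bgpos, round(background_rate * length(bgpos)))
  genome_mod <- paste(chars, collapse = "")
  names(genome_mod) <- gname
  truth$motif_positions <- data.frame(
    pos = planted,
    at_boundary = planted %in% boundary_planted,
    stringsAsFactors = FALSE)
  list(genome = genome_mod, truth = truth,
       report = list(n_boundary = n_b, n_background = n_g,
                     n_skipped = n_skipped,
                     n_boundaries_total = length(bpos)))
}

#' Simulate a complete two-cell dataset
#'
#' Orchestrates [simulate_genome()], [simulate_methylome()],
#' [plant_motifs()] and [simulate_fragments()] at a common scale. The
#' default full-scale preset is a 5 Mb genome with 150 CGIs, 500 planted
#' HMRs and 500k fragments per cell; `scale` shrinks everything
#' proportionally.
#'
#' @param seed master RNG seed (sub-generators are seeded from it).
#' @param scale scale multiplier on genome length, HMR counts, CGI count
#'   and fragment counts.
#' @param phasing,insert passed to [simulate_fragments()].
#' @param boundary_fraction,background_rate,pattern passed to
#'   [plant_motifs()] (`boundary_fraction = 0` skips motif planting).
#' @param coverage,levels passed to [simulate_methylome()].
#' @return list with `genome`, `methylomes`, `fragments` (`$a`, `$b`),
#'   `truth`.
#' @export
simulate_dataset <- function(seed = 1, scale = 0.1,
                             phasing = list(fold = 8, period = 165,
                                            n_phased = 3, decay = 0.7,
                                            pos_sd = 20),
                             insert = list(mean = 147, sd = 10,
                                           clip = FALSE),
                             pattern = "CACGTG", boundary_fraction = 0.2,
                             background_rate = 0.1, coverage = 20,
                             levels = list(hypo = 0.05, meth = 0.85,
                                           dispersion = 0.1)) {
  seed <- check_seed(seed)
  g <- simulate_genome(
    length = round(5e6 * scale),
    cgi = list(count = max(3L, round(150 * scale)), length = 1000,
               gc = 0.65),
    seed = seed)
  plan <- list(n_common = max(4L, round(200 * scale)),
               n_specific_a = max(2L, round(100 * scale)),
               n_specific_b = max(2L, round(100 * scale)),
               n_extended = max(2L, round(100 * scale)))
  me <- simulate_methylome(g$genome, hmr_plan = plan, coverage = coverage,
                           levels = levels, cgis = g$truth$cgis,
                           seed = seed + 1L)
  genome <- me$genome
  truth <- me$truth
  if (boundary_fraction > 0 || background_rate > 0) {
    pm <- plant_motifs(genome, truth, pattern = pattern,
                       boundary_fraction = boundary_fraction,
                       background_rate = background_rate, cell = "a",
                       seed = seed + 2L)
    genome <- pm$genome
    truth <- pm$truth
    truth$motif_report <- pm$report
  }
  nf <- max(1000L, round(5e5 * scale))
  frags <- list(
    a = simulate_fragments(genome, truth, cell = "a", phasing = phasing,
                           insert = insert, n_fragments = nf,
                           seed = seed + 3L),
    b = simulate_fragments(genome, truth, cell = "b", phasing = phasing,
                           insert = insert, n_fragments = nf,
                           seed = seed + 4L))
  list(genome = genome, methylomes = me$methylomes, fragments = frags,
       truth = truth)
}
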