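#' Read a per-CpG methylome table
#'
#' Reads a tab-separated methylome in the methpipe-style dialect
#' `chrom  pos  strand  context  level  coverage`. Positions are taken as
#' 0-based positions of the C of a CG on the + strand unless
#' `one_based = TRUE`. Records on the `-` strand are mapped to the + strand
#' C position (one base to the left) and merged with any + strand record at
#' that site by summing counts. Records with zero coverage are dropped; the
#' drop count is attached as attribute `n_dropped`.
#'
#' Methylated read counts are reconstructed as `round(level * coverage)`
#' using round-half-away-from-zero.
#'
#' @param path path to the TSV file.
#' @param one_based set `TRUE` for 1-based position dialects.
#' @return a data.frame with columns `chrom`, `pos`, `meth_count`,
#'   `total_count`, `level`, sorted by (chrom, pos), with attribute
#'   `n_dropped` (records removed for zero coverage).
#' @export
read_methylome <- function(path, one_based = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L) {
    out <- data.frame(chrom = character(), pos = numeric(),
                      meth_count = numeric(), total_count = numeric(),
                      level = numeric(), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  fields <- strsplit(raw, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 6L)
  if (length(bad))
    stop("malformed methylome line ", bad[1L], ": fewer than 6 fields",
         call. = FALSE)
  chrom <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  strand <- vapply(fields, `[[`, "", 3L)
  level <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  cov <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 6L)))
  bad <- which(is.na(pos) | pos != floor(pos) | is.na(cov))
  if (length(bad))
    stop("malformed methylome line ", bad[1L], ": non-integer position ",
         "or coverage", call. = FALSE)
  bad <- which(is.na(level) | level < 0 | level > 1)
  if (length(bad))
    stop("methylome line ", bad[1L], ": level outside [0, 1]", call. = FALSE)
  if (one_based) pos <- pos - 1
  pos[strand == "-"] <- pos[strand == "-"] - 1
  n_dropped <- sum(cov == 0)
  keep <- cov > 0
  chrom <- chrom[keep]; pos <- pos[keep]; level <- level[keep]
  cov <- cov[keep]
  meth <- round_half_away(level * cov)
  key <- paste(chrom, pos)
  if (anyDuplicated(key)) {
    meth <- as.numeric(tapply(meth, key, sum)[unique(key)])
    cov <- as.numeric(tapply(cov, key, sum)[unique(key)])
    first <- !duplicated(key)
    chrom <- chrom[first]; pos <- pos[first]
  }
  out <- data.frame(chrom = chrom, pos = pos, meth_count = meth,
                    total_count = cov, level = meth / cov,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Write a per-CpG methylome table
#'
#' Inverse of [read_methylome()]: writes `chrom pos + CpG level coverage`
#' with 0-based + strand positions.
#'
#' @param cpgs data.frame as returned by [read_methylome()].
#' @param path output path.
#' @export
write_methylome <- function(cpgs, path) {
  df <- data.frame(cpgs$chrom, cpgs$pos, "+", "CpG",
                   cpgs$meth_count / cpgs$total_count, cpgs$total_count)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genomic intervals from BED
#'
#' BED3+ parser returning 0-based half-open intervals sorted by
#' (chrom, start). Column 4 becomes `name` and column 6 `strand` when
#' present.
#'
#' @param path path to a BED file.
#' @param format only `"BED"` is supported.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `strand`.
#' @export
read_intervals <- function(path, format = c("BED")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readLines(path)
  raw <- raw[nzchar(raw) & !startsWith(raw, "track") &
               !startsWith(raw, "#")]
  if (length(raw) == 0L) return(new_intervals())
  fields <- strsplit(raw, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("BED line ", which(lengths(fields) < 3L)[1L],
         ": fewer than 3 fields", call. = FALSE)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad))
    stop("BED line ", bad[1L], ": non-integer coordinates", call. = FALSE)
  df <- new_intervals(
    chrom = vapply(fields, `[[`, "", 1L), start = start, end = end,
    name = vapply(fields, function(f) if (length(f) >= 4L) f[[4L]]
                  else NA_character_, ""),
    strand = vapply(fields, function(f) if (length(f) >= 6L) f[[6L]]
                    else ".", "")
  )
  validate_intervals(df, "BED")
  out <- sort_intervals(df)
  rownames(out) <- NULL
  out
}

#' Write genomic intervals as BED
#'
#' @param intervals data.frame with `chrom`, `start`, `end` and optionally
#'   `name`, `strand`.
#' @param path output path.
#' @export
write_intervals <- function(intervals, path) {
  validate_intervals(intervals, "interval")
  name <- intervals$name %||% rep(NA_character_, nrow(intervals))
  strand <- intervals$strand %||% rep(".", nrow(intervals))
  has_meta <- !all(is.na(name))
  df <- if (has_meta) {
    data.frame(intervals$chrom, intervals$start, intervals$end,
               ifelse(is.na(name), ".", name), 0L, strand)
  } else {
    data.frame(intervals$chrom, intervals$start, intervals$end)
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read genome sequences from FASTA
#'
#' Sequences are uppercased, names truncated at the first whitespace, and
#' the alphabet restricted to A/C/G/T/N.
#'
#' @param path path to a FASTA file.
#' @return named character vector, one uppercase sequence per record.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(nm))
    stop("duplicate sequence name: ", nm[duplicated(nm)][1L], call. = FALSE)
  seqs <- toupper(as.character(ss))
  names(seqs) <- nm
  if (any(grepl("[^ACGTN]", seqs)))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA", call. = FALSE)
  seqs
}

#' Write genome sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read paired-end fragments from BED or BEDPE
#'
#' BED rows are taken as whole-fragment intervals. BEDPE rows (>= 6 columns
#' with a second chrom in column 4) are collapsed to the outer span of the
#' two mates, which must lie on one chromosome.
#'
#' @param path path to the file.
#' @param format `"BED"` or `"BEDPE"`.
#' @return data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_fragments <- function(path, format = c("BED", "BEDPE")) {
  format <- match.arg(format)
  if (format == "BED") {
    iv <- read_intervals(path)
    return(data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                      stringsAsFactors = FALSE))
  }
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 6L) stop("BEDPE requires >= 6 columns", call. = FALSE)
  if (any(tab[[1L]] != tab[[4L]]))
    stop("BEDPE mates on different chromosomes are not supported",
         call. = FALSE)
  df <- data.frame(chrom = as.character(tab[[1L]]),
                   start = pmin(tab[[2L]], tab[[5L]]),
                   end = pmax(tab[[3L]], tab[[6L]]),
                   stringsAsFactors = FALSE)
  validate_intervals(df, "BEDPE")
  sort_intervals(df)
}

#' Export an occupancy track as bedGraph
#'
#' Adjacent equal values are run-length collapsed.
#'
#' @param track an `occupancy_track` (see [smooth_track()]).
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "occupancy_track"))
  v <- track$values
  r <- rle(v)
  end <- track$offset + cumsum(r$lengths)
  start <- end - r$lengths
  df <- data.frame(track$chrom, start, end, signif(r$values, 8))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
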