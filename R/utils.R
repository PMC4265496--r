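# Internal helpers shared across modules. Intervals live in data.frames with
# 0-based half-open start/end; GRanges (1-based closed) only inside helpers.

new_intervals <- function(chrom = character(), start = integer(),
                          end = integer(), name = NA_character_,
                          strand = ".") {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  df$name <- rep_len(as.character(name), nrow(df))
  df$strand <- rep_len(as.character(strand), nrow(df))
  df
}

validate_intervals <- function(df, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop(what, ": non-numeric coordinates", call. = FALSE)
  if (any(df$start < 0))
    stop(what, ": negative start coordinate", call. = FALSE)
  if (any(df$end <= df$start))
    stop(what, ": end must be greater than start (0-based half-open)",
         call. = FALSE)
  if (any(!nzchar(df$chrom)))
    stop(what, ": empty chromosome name", call. = FALSE)
  invisible(df)
}

sort_intervals <- function(df) {
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

# 0-based half-open data.frame -> GRanges (1-based closed)
as_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# round half away from zero (deterministic across platforms)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer", call. = FALSE)
  as.integer(seed)
}
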