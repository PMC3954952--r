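#' Construct a genomic interval table
#'
#' Intervals are kept as plain data frames with 0-based, half-open
#' coordinates (`start` inclusive, `end` exclusive), the convention of the
#' BED format. All interval algebra in the package goes through
#' [GenomicRanges::GRanges] after a 1-based conversion at the boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end` per row.
#' @param strand strand per row, one of `"+"`, `"-"`, `"*"`.
#' @param ... further equal-length columns (e.g. `name`) kept as-is.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`
#'   plus any extra columns.
#' @export
genomic_intervals <- function(chrom = character(), start = integer(),
                              end = integer(), strand = "*", ...) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   strand = rep_len(as.character(strand), n),
                   ...,
                   stringsAsFactors = FALSE)
  validate_intervals(df)
  df
}

validate_intervals <- function(df, chrom_lengths = NULL) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$start < 0) || any(df$start >= df$end))
    stop("invalid interval: need 0 <= start < end")
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[df$chrom]
    if (anyNA(len)) stop("interval on unknown chromosome")
    if (any(df$end > len)) stop("interval exceeds chromosome length")
  }
  invisible(df)
}

empty_intervals <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             strand = character(), stringsAsFactors = FALSE)
}

# 0-based half-open data.frame -> 1-based closed GRanges
gi_to_gr <- function(df) {
  if (nrow(df) == 0)
    return(GenomicRanges::GRanges())
  strand <- if ("strand" %in% names(df)) df$strand else "*"
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "*"
  GenomicRanges::GRanges(seqnames = df$chrom,
                         ranges = IRanges::IRanges(start = df$start + 1,
                                                   end = df$end),
                         strand = strand)
}

gr_to_gi <- function(gr) {
  if (length(gr) == 0) return(empty_intervals())
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# Merge overlapping/adjacent-by-overlap intervals, ignoring strand.
gi_merge <- function(df) {
  if (nrow(df) == 0) return(empty_intervals())
  gr_to_gi(GenomicRanges::reduce(gi_to_gr(df), ignore.strand = TRUE))
}

gi_intersect <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_intervals())
  gr_to_gi(GenomicRanges::intersect(gi_to_gr(a), gi_to_gr(b),
                                    ignore.strand = TRUE))
}

gi_subtract <- function(a, b) {
  if (nrow(a) == 0) return(empty_intervals())
  if (nrow(b) == 0) return(gi_merge(a))
  gr_to_gi(GenomicRanges::setdiff(gi_to_gr(a), gi_to_gr(b),
                                  ignore.strand = TRUE))
}

# Complement within [0, chrom_length) for every named chromosome.
gi_complement <- function(df, chrom_lengths) {
  full <- data.frame(chrom = names(chrom_lengths), start = 0,
                     end = as.numeric(chrom_lengths), strand = "*",
                     stringsAsFactors = FALSE)
  gi_subtract(full, df)
}

gi_clip <- function(df, chrom_lengths) {
  if (nrow(df) == 0) return(df)
  len <- chrom_lengths[df$chrom]
  df$start <- pmax(df$start, 0)
  df$end <- pmin(df$end, as.numeric(len))
  df[df$start < df$end, , drop = FALSE]
}

gi_total_width <- function(df) {
  if (nrow(df) == 0) return(0)
  sum(df$end - df$start)
}

# GRanges of single-base probe positions (manifest is 0-based)
probes_to_gr <- function(manifest) {
  GenomicRanges::GRanges(seqnames = manifest$chrom,
                         ranges = IRanges::IRanges(start = manifest$pos + 1,
                                                   width = 1))
}

# For each probe, TRUE if its position falls inside any interval of df.
probes_in_intervals <- function(manifest, df) {
  if (nrow(df) == 0 || nrow(manifest) == 0)
    return(rep(FALSE, nrow(manifest)))
  IRanges::overlapsAny(probes_to_gr(manifest), gi_to_gr(df),
                       ignore.strand = TRUE)
}
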