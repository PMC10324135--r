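# Internal helpers: interval validation, coordinate conversion, seeding.
#
# All internal coordinates are 0-based half-open [start, end); GTF I/O
# converts at the boundary (GTF is 1-based inclusive), BED/bedGraph are
# natively 0-based half-open.

#' Construct a genomic interval
#'
#' A genomic interval is a plain one-row `data.frame` with columns `chrom`,
#' `start`, `end`, `strand`, using 0-based half-open coordinates.
#'
#' @param chrom Chromosome name.
#' @param start 0-based inclusive start (nt).
#' @param end 0-based exclusive end (nt).
#' @param strand `"+"` or `"-"`.
#' @return A one-row `data.frame` with columns `chrom`, `start`, `end`,
#'   `strand`.
#' @examples
#' genomic_interval("chr1", 100, 200, "+")
#' @export
genomic_interval <- function(chrom, start, end, strand = "+") {
  iv <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), strand = as.character(strand),
                   stringsAsFactors = FALSE)
  validate_intervals(iv)
  iv
}

# Check interval invariants: start < end, start >= 0, strand in {+,-}.
validate_intervals <- function(iv, what = "interval") {
  stopifnot(is.data.frame(iv))
  need <- c("chrom", "start", "end", "strand")
  missing_cols <- setdiff(need, names(iv))
  if (length(missing_cols) > 0) {
    stop(what, " is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!(iv$start < iv$end) | iv$start < 0 |
                 !(iv$strand %in% c("+", "-")))
  if (length(bad) > 0) {
    stop(what, " invariant violated (need 0 <= start < end, strand in {+,-}) ",
         "at row(s): ", paste(head(bad, 5), collapse = ", "))
  }
  invisible(iv)
}

interval_width <- function(iv) iv$end - iv$start

# data.frame (0-based half-open) -> GRanges (1-based inclusive)
df_to_gr <- function(df, chrom = "chrom", start = "start", end = "end",
                     strand = "strand") {
  GenomicRanges::GRanges(
    seqnames = df[[chrom]],
    ranges = IRanges::IRanges(start = df[[start]] + 1L, end = df[[end]]),
    strand = if (is.null(strand) || !strand %in% names(df)) "*" else df[[strand]]
  )
}

gr_to_df <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

# TRUE where [s1,e1) overlaps [s2,e2) by >= 1 nt (vectorised).
spans_overlap <- function(s1, e1, s2, e2) pmin(e1, e2) - pmax(s1, s2) > 0

overlap_width <- function(s1, e1, s2, e2) pmax(0L, pmin(e1, e2) - pmax(s1, s2))

contains <- function(outer_start, outer_end, inner_start, inner_end) {
  outer_start <= inner_start & inner_end <= outer_end
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. seed = NULL uses the current RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  code
}

# Named substream: derive a child seed from a root seed and a stream label so
# regenerating one synthetic file type never perturbs the others. Kept below
# 2^31 - 1 (R integers are 32 bit).
substream_seed <- function(root, name) {
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 1000003
  as.integer((as.numeric(root) * 7919 + h) %% 2147483647)
}
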