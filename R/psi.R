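# splicing quantification: PSI for cassette exons from inclusion/skip
# evidence, depth normalisation, and per-sample correlations.

#' Percent spliced in
#'
#' `inclusion / (inclusion + skip)`; `NA` when both counts are zero.
#'
#' @param inclusion_reads Count of reads fully or partially overlapping the
#'   alternative exon.
#' @param skip_junction_reads Count of reads containing the junction joining
#'   the exon's upstream and downstream exons.
#' @return PSI in \[0,1\], or `NA`.
#' @export
compute_psi <- function(inclusion_reads, skip_junction_reads) {
  if (any(inclusion_reads < 0) || any(skip_junction_reads < 0)) {
    stop("read counts must be non-negative")
  }
  total <- inclusion_reads + skip_junction_reads
  ifelse(total > 0, inclusion_reads / total, NA_real_)
}

#' Count inclusion and skip evidence for a cassette exon
#'
#' Inclusion evidence: rows of the exon-overlap table overlapping the exon by
#' >= 1 nt. Skip evidence: junction rows whose donor equals the upstream
#' exon's end and whose acceptor equals the downstream exon's start (genomic
#' coordinates, half-open boundaries). A junction row matching the skip
#' junction is never also counted as inclusion.
#'
#' @param junctions Data frame with columns `chrom`, `donor`, `acceptor`,
#'   `count` (and optionally `sample_id`, `strand`).
#' @param overlaps Data frame with columns `chrom`, `start`, `end`, `count`
#'   (and optionally `sample_id`).
#' @param exon One-row interval data frame (the cassette exon).
#' @param up_end Genomic end (half-open) of the flanking exon on the lower
#'   coordinate side.
#' @param down_start Genomic start of the flanking exon on the higher
#'   coordinate side.
#' @param sample_id Optional sample to restrict to.
#' @return Named numeric vector `c(inclusion, skip)`.
#' @export
count_exon_evidence <- function(junctions, overlaps, exon, up_end, down_start,
                                sample_id = NULL) {
  if (is.null(up_end) || is.null(down_start) || is.na(up_end) ||
      is.na(down_start)) {
    stop("flanking exon boundaries are required")
  }
  if (!is.null(sample_id)) {
    if ("sample_id" %in% names(junctions)) {
      junctions <- junctions[junctions$sample_id == sample_id, , drop = FALSE]
    }
    if ("sample_id" %in% names(overlaps)) {
      overlaps <- overlaps[overlaps$sample_id == sample_id, , drop = FALSE]
    }
  }
  inc <- 0
  if (nrow(overlaps) > 0) {
    hit <- overlaps$chrom == exon$chrom &
      spans_overlap(overlaps$start, overlaps$end, exon$start, exon$end)
    inc <- sum(overlaps$count[hit])
  }
  skip <- 0
  if (nrow(junctions) > 0) {
    hit <- junctions$chrom == exon$chrom & junctions$donor == up_end &
      junctions$acceptor == down_start
    skip <- sum(junctions$count[hit])
  }
  c(inclusion = inc, skip = skip)
}

#' Per-sample PSI table for a cassette exon
#'
#' @param junctions,overlaps Evidence tables with a `sample_id` column.
#' @param exon One-row interval data frame.
#' @param up_end,down_start Flanking exon boundaries (see
#'   [count_exon_evidence()]).
#' @return Data frame with `sample_id`, `inclusion`, `skip`, `psi`.
#' @export
psi_table <- function(junctions, overlaps, exon, up_end, down_start) {
  samples <- sort(unique(c(junctions$sample_id, overlaps$sample_id)))
  rows <- lapply(samples, function(s) {
    ev <- count_exon_evidence(junctions, overlaps, exon, up_end, down_start,
                              sample_id = s)
    data.frame(sample_id = s, inclusion = ev[["inclusion"]],
               skip = ev[["skip"]],
               psi = compute_psi(ev[["inclusion"]], ev[["skip"]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Depth-normalised abundance
#'
#' @param raw_count Read count of the region of interest.
#' @param depth Total mapped reads of the sequencing run (> 0).
#' @return `raw_count / depth`.
#' @export
normalize_abundance <- function(raw_count, depth) {
  if (any(depth <= 0)) stop("depth must be > 0")
  raw_count / depth
}

#' Pearson correlation across samples
#'
#' Values are aligned by name when both vectors are named (sample ids), not by
#' position; pairs with a missing value are dropped. Constant input yields an
#' undefined correlation, flagged rather than raised as an error.
#'
#' @param x,y Numeric vectors (optionally named by sample id).
#' @return A list: `r`, `p_value`, `n`, `constant` (logical flag).
#' @export
correlate <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    common <- intersect(names(x), names(y))
    x <- x[common]; y <- y[common]
  }
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 paired samples")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                constant = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       constant = FALSE)
}
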