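# evidence features: per-base tracks, conservation with matched negatives and
# bootstrap, snoRNA extension coverage ratio, branch-point overlap, and the
# five-flag evidence classifier.

#' Read a per-base track from a bedGraph file
#'
#' Used both for conservation scores (values in \[0,1\]) and read-coverage
#' depth. Positions not covered by any interval are "missing" and contribute
#' 0 to means.
#'
#' @param path bedGraph file (0-based half-open).
#' @return An object of class `snohost_track` holding run-length encoded
#'   per-base values and a covered mask.
#' @export
read_track <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  track_from_granges(gr)
}

track_from_granges <- function(gr) {
  structure(list(score = GenomicRanges::coverage(gr, weight = gr$score),
                 covered = GenomicRanges::coverage(gr)),
            class = "snohost_track")
}

# sum of track values over [start, end) on chrom; positions beyond the track
# contribute 0. Also returns the number of covered positions.
track_window_sum <- function(track, chrom, start, end) {
  rle <- track$score[[chrom]]
  cov <- track$covered[[chrom]]
  if (is.null(rle) || start + 1 > length(rle)) {
    return(c(sum = 0, covered = 0))
  }
  hi <- min(end, length(rle))
  w <- S4Vectors::window(rle, start + 1, hi)
  wc <- S4Vectors::window(cov, start + 1, hi)
  c(sum = sum(as.numeric(w)), covered = sum(as.numeric(wc) > 0))
}

#' Mean track value over a region, missing positions scoring 0
#'
#' The arithmetic mean over all positions of the region; positions outside
#' the track's declared intervals contribute 0 (the count of missing bases is
#' attached as an attribute).
#'
#' @param region One-row interval data frame (`chrom`, `start`, `end`).
#' @param track A `snohost_track`.
#' @return Mean value; for conservation tracks this lies in \[0,1\].
#' @export
mean_conservation <- function(region, track) {
  stopifnot(region$end > region$start)
  s <- track_window_sum(track, region$chrom, region$start, region$end)
  width <- region$end - region$start
  out <- s[["sum"]] / width
  attr(out, "missing_bases") <- width - s[["covered"]]
  out
}

#' Matched negative region for a target
#'
#' An interval of the target's length mirrored to the opposite side of the
#' snoRNA, at the same distance from the snoRNA boundary as the target; `NULL`
#' if the mirrored interval would leave the host intron.
#'
#' @param target One-row interval data frame (within the host intron, not
#'   overlapping the snoRNA).
#' @param sno One-row interval data frame (the snoRNA).
#' @param intron One-row interval data frame (the host intron).
#' @return A one-row interval data frame, or `NULL`.
#' @export
matched_negative <- function(target, sno, intron) {
  if (spans_overlap(target$start, target$end, sno$start, sno$end)) {
    stop("target region overlaps the snoRNA")
  }
  if (!contains(intron$start, intron$end, target$start, target$end)) {
    stop("target region is not inside the host intron")
  }
  len <- target$end - target$start
  if (target$start >= sno$end) {            # target downstream in coordinates
    gap <- target$start - sno$end
    neg_end <- sno$start - gap
    neg_start <- neg_end - len
  } else {                                  # target upstream in coordinates
    gap <- sno$start - target$end
    neg_start <- sno$end + gap
    neg_end <- neg_start + len
  }
  if (neg_start < intron$start || neg_end > intron$end) return(NULL)
  genomic_interval(target$chrom, neg_start, neg_end, target$strand)
}

#' Sample negative intronic regions near non-interacting snoRNAs
#'
#' Draws `n` intervals with replacement: a snoRNA uniformly from the supplied
#' (non-interacting) set, a side (upstream/downstream flank of the snoRNA
#' within its host intron) uniformly, a length by resampling the positive
#' target-length distribution, and a start uniform within the flank. Draws
#' whose flank cannot host the length are retried a bounded number of times.
#'
#' @param snos Data frame of non-interacting snoRNAs (rows of a registry).
#' @param introns [host_introns()] rows for those snoRNAs.
#' @param lengths Positive-region length sample to resample from (nt).
#' @param n Number of regions to draw.
#' @param seed Optional integer seed (deterministic output).
#' @param max_retries Bounded retries per draw.
#' @return A data frame of intervals (possibly fewer than `n` rows if flanks
#'   are persistently too short).
#' @export
sample_negative_regions <- function(snos, introns, lengths, n, seed = NULL,
                                    max_retries = 20L) {
  stopifnot(length(lengths) > 0)
  if (n == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sno_id = character(0)))
  }
  with_seed(seed, {
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      for (try in seq_len(max_retries)) {
        i <- sample.int(nrow(snos), 1)
        s <- snos[i, ]
        hi <- introns[introns$sno_id == s$sno_id, , drop = FALSE]
        if (nrow(hi) != 1) next
        len <- lengths[sample.int(length(lengths), 1)]
        upstream <- stats::runif(1) < 0.5
        flank <- if (upstream) c(hi$start, s$start) else c(s$end, hi$end)
        avail <- flank[2] - flank[1] - len
        if (avail < 0) next
        start <- flank[1] + sample.int(avail + 1, 1) - 1L
        rows[[k]] <- data.frame(chrom = s$chrom, start = start,
                                end = start + len, strand = s$strand,
                                sno_id = s$sno_id, stringsAsFactors = FALSE)
        break
      }
    }
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(out)) {
      out <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        sno_id = character(0))
    }
    row.names(out) <- NULL
    out
  })
}

#' Bootstrap test for the proportion of highly conserved regions
#'
#' The statistic is the proportion of region scores greater or equal to
#' `threshold`. The null is built by resampling the negative scores (sample
#' size equal to the number of targets, with replacement) `n_boot` times; the
#' p-value uses the add-one convention `p = (1 + #(null >= observed)) /
#' (n_boot + 1)` so it can never be exactly 0.
#'
#' @param target_scores Per-region mean scores of target regions.
#' @param negative_scores Per-region mean scores of negative regions.
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param threshold High-conservation cutoff (default 0.5).
#' @param seed Optional integer seed.
#' @return A list: `proportion_target`, `proportion_negative`, `p_value`,
#'   `n_boot`.
#' @export
conservation_bootstrap <- function(target_scores, negative_scores,
                                   n_boot = 1000L, threshold = 0.5,
                                   seed = NULL) {
  if (length(target_scores) == 0 || length(negative_scores) == 0) {
    stop("both score collections must be non-empty")
  }
  obs_t <- mean(target_scores >= threshold)
  obs_n <- mean(negative_scores >= threshold)
  with_seed(seed, {
    nt <- length(target_scores)
    draws <- matrix(sample(negative_scores, n_boot * nt, replace = TRUE),
                    nrow = nt)
    null_prop <- colMeans(draws >= threshold)
    p <- (1 + sum(null_prop >= obs_t)) / (n_boot + 1)
    list(proportion_target = obs_t, proportion_negative = obs_n,
         p_value = p, n_boot = n_boot)
  })
}

#' snoRNA extension coverage ratio
#'
#' Ratio of the mean coverage of the extension window -- from the snoRNA
#' boundary facing the interaction, shifted `pad` nt away from the snoRNA to
#' avoid counting mature snoRNA reads, up to the interaction end -- to the
#' mean coverage of the rest of the intron (intron minus snoRNA minus the
#' window).
#'
#' @param track A `snohost_track` of read coverage.
#' @param sno One-row interval data frame (the snoRNA).
#' @param interaction One-row interval data frame (the interaction target
#'   region, on one side of the snoRNA within the intron).
#' @param intron One-row interval data frame (the host intron).
#' @param pad Offset from the snoRNA boundary in nt (default 2).
#' @return The ratio (non-negative); `Inf` when the rest of the intron has
#'   zero coverage but the window does not; `NA` when both are zero or the
#'   window is empty (with a warning).
#' @export
extension_ratio <- function(track, sno, interaction, intron, pad = 2L) {
  if (interaction$start >= sno$end) {
    win_start <- sno$end + pad
    win_end <- interaction$end
  } else if (interaction$end <= sno$start) {
    win_start <- interaction$start
    win_end <- sno$start - pad
  } else {
    # interaction overlapping the snoRNA: use the part extending past it
    if (interaction$end > sno$end) {
      win_start <- sno$end + pad; win_end <- interaction$end
    } else {
      win_start <- interaction$start; win_end <- sno$start - pad
    }
  }
  win_start <- max(win_start, intron$start)
  win_end <- min(win_end, intron$end)
  if (win_end <= win_start) {
    warning("empty extension window (interaction ends within ", pad,
            " nt of the snoRNA boundary)")
    return(NA_real_)
  }
  sum_win <- track_window_sum(track, intron$chrom, win_start, win_end)[["sum"]]
  w_win <- win_end - win_start
  sum_intron <- track_window_sum(track, intron$chrom, intron$start,
                                 intron$end)[["sum"]]
  sum_sno <- track_window_sum(track, intron$chrom, sno$start, sno$end)[["sum"]]
  w_rest <- (intron$end - intron$start) - (sno$end - sno$start) - w_win
  num <- sum_win / w_win
  den <- if (w_rest > 0) (sum_intron - sum_sno - sum_win) / w_rest else 0
  if (den == 0 && num > 0) return(Inf)
  if (den == 0 && num == 0) return(NA_real_)
  num / den
}

#' Read branch points from a TSV, keeping the best per intron
#'
#' Expected columns: `intron_id`, `chrom`, `position` (0-based), `score`.
#' Only the top-scoring row per intron is kept.
#'
#' @param path TSV path (with header).
#' @return A data frame with one row per intron.
#' @export
read_branch_points <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("intron_id", "chrom", "position", "score")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("branch-point TSV missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[order(df$intron_id, -df$score), , drop = FALSE]
  out <- df[!duplicated(df$intron_id), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Does a target region overlap a branch point?
#'
#' @param target One-row interval data frame.
#' @param bp A one-row branch-point data frame (`chrom`, `position`), or
#'   `NULL`.
#' @return `TRUE` iff the branch-point position lies in `[start, end)`.
#' @export
bp_overlap <- function(target, bp) {
  if (is.null(bp) || nrow(bp) == 0) return(FALSE)
  bp$chrom == target$chrom && bp$position >= target$start &&
    bp$position < target$end
}

#' Default evidence thresholds
#'
#' The five evidence criteria, all strict inequalities: chimeric-read support
#' > 3, duplex MFE < 0 kcal/mol, mean conservation > 0.2, distance to the
#' closest alternative splice site < 150 nt, and extension ratio > 2.
#'
#' @return A named list of thresholds.
#' @export
evidence_thresholds <- function() {
  list(support = 3, duplex_mfe = 0, conservation = 0.2,
       splice_distance = 150, extension_ratio = 2)
}

#' Classify interactions into the evidence matrix
#'
#' Applies the five strict thresholds to a feature table; missing values
#' (`NA`) fail their criterion. `evidence_count` is the number of satisfied
#' flags (0-5).
#'
#' @param features Data frame with columns `support`, `duplex_mfe`,
#'   `mean_conservation`, `splice_distance`, `extension_ratio` (extra columns
#'   are carried through).
#' @param thresholds Named list as returned by [evidence_thresholds()].
#' @return `features` with added logical columns `pls_support`,
#'   `stable_structure`, `conservation`, `ase_proximity`, `extension` and an
#'   integer `evidence_count`.
#' @export
classify_evidence <- function(features, thresholds = evidence_thresholds()) {
  flag <- function(x) !is.na(x) & x
  features$pls_support <- flag(features$support > thresholds$support)
  features$stable_structure <- flag(features$duplex_mfe < thresholds$duplex_mfe)
  features$conservation <- flag(features$mean_conservation > thresholds$conservation)
  features$ase_proximity <- flag(features$splice_distance < thresholds$splice_distance)
  features$extension <- flag(features$extension_ratio > thresholds$extension_ratio)
  features$evidence_count <- features$pls_support + features$stable_structure +
    features$conservation + features$ase_proximity + features$extension
  features
}

#' Conservation contrast of target regions against sampled negatives
#'
#' Computes per-region mean conservation for the supplied target regions,
#' samples negative intronic regions near non-interacting snoRNAs (length
#' distribution resampled from the targets; `n_sets` independent draws give
#' the spread of the negative statistic), and runs the proportion bootstrap.
#'
#' @param targets Interval data frame of target regions (one per interacting
#'   snoRNA; a `sno_id` column marks their snoRNAs as interacting).
#' @param ann A `snohost_annotation`.
#' @param track A `snohost_track` of conservation scores.
#' @param introns Precomputed [host_introns()] table.
#' @param n_sets Independent negative-set draws used for the spread (default
#'   10).
#' @param n_boot,threshold Bootstrap settings, see [conservation_bootstrap()].
#' @param seed Optional integer seed.
#' @return A list: `target_scores`, `negative_scores` (first draw),
#'   `proportion_target`, `proportion_negative`, `negative_proportion_sd`
#'   (across the `n_sets` draws), `p_value`.
#' @export
conservation_contrast <- function(targets, ann, track,
                                  introns = host_introns(ann),
                                  n_sets = 10L, n_boot = 1000L,
                                  threshold = 0.5, seed = NULL) {
  stopifnot(nrow(targets) > 0)
  target_scores <- vapply(seq_len(nrow(targets)), function(i) {
    as.numeric(mean_conservation(targets[i, ], track))
  }, numeric(1))
  interacting <- unique(targets$sno_id)
  noninteracting <- ann$snornas[
    ann$snornas$sno_id %in% introns$sno_id &
      !(ann$snornas$sno_id %in% interacting), , drop = FALSE]
  if (nrow(noninteracting) == 0) {
    stop("no non-interacting snoRNAs available to sample negatives from")
  }
  lengths <- targets$end - targets$start
  with_seed(seed, {
    neg_sets <- lapply(seq_len(n_sets), function(k) {
      regs <- sample_negative_regions(noninteracting, introns, lengths,
                                      n = length(target_scores))
      vapply(seq_len(nrow(regs)), function(i) {
        as.numeric(mean_conservation(regs[i, ], track))
      }, numeric(1))
    })
    neg_props <- vapply(neg_sets, function(x) mean(x >= threshold), numeric(1))
    boot <- conservation_bootstrap(target_scores, neg_sets[[1]],
                                   n_boot = n_boot, threshold = threshold)
    list(target_scores = target_scores, negative_scores = neg_sets[[1]],
         proportion_target = boot$proportion_target,
         proportion_negative = boot$proportion_negative,
         negative_proportion_sd = stats::sd(neg_props),
         p_value = boot$p_value)
  })
}
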