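# interaction screen: chimeric-read loading, filtering, single-linkage
# merging with support accumulation, and categorisation of snoRNA-target
# interactions.

#' Load chimeric duplex reads from a TSV
#'
#' Expected columns: `chrom1, start1, end1, strand1, chrom2, start2, end2,
#' strand2, dataset_id` and optionally `support` (defaults to 1). Coordinates
#' are 0-based half-open. Arms are normalised so the left arm precedes the
#' right arm (by chromosome, then start).
#'
#' @param tsv_path Path to the chimera TSV (with header).
#' @return A data frame of validated chimeric reads.
#' @export
load_chimeras <- function(tsv_path) {
  df <- read.delim(tsv_path, stringsAsFactors = FALSE)
  need <- c("chrom1", "start1", "end1", "strand1",
            "chrom2", "start2", "end2", "strand2", "dataset_id")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    stop("chimera TSV missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!"support" %in% names(df)) df$support <- 1L
  if (nrow(df) == 0) return(df)
  for (arm in 1:2) {
    s <- df[[paste0("start", arm)]]; e <- df[[paste0("end", arm)]]
    st <- df[[paste0("strand", arm)]]
    bad <- which(!(s < e) | s < 0 | !(st %in% c("+", "-")))
    if (length(bad) > 0) {
      stop("invalid arm ", arm, " (need 0 <= start < end, strand in {+,-}) ",
           "at row(s): ", paste(head(bad, 5), collapse = ", "))
    }
  }
  if (any(df$support < 1)) stop("support must be a positive integer")
  swap <- df$chrom2 < df$chrom1 |
    (df$chrom2 == df$chrom1 & df$start2 < df$start1)
  if (any(swap)) {
    cols1 <- c("chrom1", "start1", "end1", "strand1")
    cols2 <- c("chrom2", "start2", "end2", "strand2")
    tmp <- df[swap, cols1]
    df[swap, cols1] <- df[swap, cols2]
    df[swap, cols2] <- tmp
  }
  row.names(df) <- NULL
  df
}

# For each arm, the snoRNA (same chrom and strand, >= 1 nt overlap) with the
# largest overlap; NA when none. Returns character vector.
arm_sno_hits <- function(chrom, start, end, strand, snornas) {
  vapply(seq_along(chrom), function(i) {
    hit <- snornas$chrom == chrom[i] & snornas$strand == strand[i] &
      spans_overlap(snornas$start, snornas$end, start[i], end[i])
    if (!any(hit)) return(NA_character_)
    cand <- snornas[hit, , drop = FALSE]
    ov <- overlap_width(cand$start, cand$end, start[i], end[i])
    cand$sno_id[which.max(ov)]
  }, character(1))
}

#' Filter chimeric reads
#'
#' Retained reads satisfy all of:
#' * both arm lengths >= `min_arm_len` nt (default 9; short duplex arms of
#'   <= 8 nt are discarded);
#' * at least one arm overlaps a snoRNA (same strand);
#' * neither arm lies entirely in intergenic space (no same-strand overlap
#'   with any annotated gene span);
#' * for snoRNA self-reads (both arms overlapping the same snoRNA), at least
#'   one arm extends >= `self_extension` nt beyond a boundary of that snoRNA.
#'
#' @param reads Data frame from [load_chimeras()].
#' @param ann A `snohost_annotation`.
#' @param min_arm_len Minimum arm length in nt (default 9).
#' @param self_extension Minimum extension beyond the snoRNA boundary for
#'   self-reads, in nt (default 10).
#' @return The retained subset of `reads`.
#' @export
filter_chimeras <- function(reads, ann, min_arm_len = 9L, self_extension = 10L) {
  if (nrow(reads) == 0) return(reads)
  len1 <- reads$end1 - reads$start1
  len2 <- reads$end2 - reads$start2
  keep <- len1 >= min_arm_len & len2 >= min_arm_len

  sno1 <- arm_sno_hits(reads$chrom1, reads$start1, reads$end1, reads$strand1,
                       ann$snornas)
  sno2 <- arm_sno_hits(reads$chrom2, reads$start2, reads$end2, reads$strand2,
                       ann$snornas)
  keep <- keep & (!is.na(sno1) | !is.na(sno2))

  # genic space: annotated gene spans (snoRNA genes included), same strand
  genic <- function(chrom, start, end, strand) {
    vapply(seq_along(chrom), function(i) {
      any(ann$genes$chrom == chrom[i] & ann$genes$strand == strand[i] &
            spans_overlap(ann$genes$start, ann$genes$end, start[i], end[i]))
    }, logical(1))
  }
  keep <- keep & genic(reads$chrom1, reads$start1, reads$end1, reads$strand1) &
    genic(reads$chrom2, reads$start2, reads$end2, reads$strand2)

  is_self <- !is.na(sno1) & !is.na(sno2) & sno1 == sno2
  if (any(is_self & keep)) {
    idx <- which(is_self & keep)
    sno <- ann$snornas[match(sno1[idx], ann$snornas$sno_id), , drop = FALSE]
    overhang <- function(s, e) pmax(pmax(0L, sno$start - s), pmax(0L, e - sno$end))
    ext <- pmax(overhang(reads$start1[idx], reads$end1[idx]),
                overhang(reads$start2[idx], reads$end2[idx]))
    keep[idx] <- ext >= self_extension
  }
  out <- reads[keep, , drop = FALSE]
  row.names(out) <- NULL
  out
}

# Union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

#' Merge overlapping chimeric reads into interactions
#'
#' Reads are clustered by single linkage, the link predicate being ">= 1 nt
#' overlap of the left arms AND >= 1 nt overlap of the right arms" (same
#' chromosome and strand per arm). Per cluster the support is the sum of the
#' member supports and the dataset set is the union. The representative arms
#' are those of the member whose total pairwise arm overlap with the rest of
#' the cluster is largest (ties: larger total arm length, then smaller left
#' start); the cluster-wide arm-span union is kept in `left_span_*` /
#' `right_span_*` columns. Merging is order independent and idempotent.
#'
#' @param reads Data frame of (filtered) chimeric reads.
#' @return A data frame of merged interactions with columns `chrom1, start1,
#'   end1, strand1, chrom2, start2, end2, strand2, support, n_reads,
#'   datasets, members` (input row indices of the cluster),
#'   `left_span_start, left_span_end, right_span_start, right_span_end`.
#' @export
merge_interactions <- function(reads) {
  empty <- data.frame(chrom1 = character(0), start1 = integer(0),
                      end1 = integer(0), strand1 = character(0),
                      chrom2 = character(0), start2 = integer(0),
                      end2 = integer(0), strand2 = character(0),
                      support = integer(0), n_reads = integer(0),
                      datasets = character(0), members = character(0),
                      left_span_start = integer(0), left_span_end = integer(0),
                      right_span_start = integer(0), right_span_end = integer(0))
  n <- nrow(reads)
  if (n == 0) return(empty)
  if (!"support" %in% names(reads)) reads$support <- 1L
  if (!"dataset_id" %in% names(reads)) reads$dataset_id <- "NA"

  left <- df_to_gr(reads, "chrom1", "start1", "end1", "strand1")
  right <- df_to_gr(reads, "chrom2", "start2", "end2", "strand2")
  hl <- GenomicRanges::findOverlaps(left, left)
  hr <- GenomicRanges::findOverlaps(right, right)
  key_l <- paste(S4Vectors::queryHits(hl), S4Vectors::subjectHits(hl))
  key_r <- paste(S4Vectors::queryHits(hr), S4Vectors::subjectHits(hr))
  both <- hl[key_l %in% key_r]
  qi <- S4Vectors::queryHits(both); si <- S4Vectors::subjectHits(both)

  parent <- uf_new(n)
  for (k in seq_along(qi)) {
    if (qi[k] < si[k]) parent <- uf_union(parent, qi[k], si[k])
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))

  out <- lapply(unique(comp), function(cid) {
    idx <- which(comp == cid)
    m <- reads[idx, , drop = FALSE]
    k <- length(idx)
    if (k == 1) {
      rep_row <- m[1, , drop = FALSE]
    } else {
      ov_tot <- vapply(seq_len(k), function(i) {
        others <- setdiff(seq_len(k), i)
        sum(overlap_width(m$start1[i], m$end1[i], m$start1[others], m$end1[others])) +
          sum(overlap_width(m$start2[i], m$end2[i], m$start2[others], m$end2[others]))
      }, numeric(1))
      total_len <- (m$end1 - m$start1) + (m$end2 - m$start2)
      ord <- order(-ov_tot, -total_len, m$start1)
      rep_row <- m[ord[1], , drop = FALSE]
    }
    data.frame(rep_row[, c("chrom1", "start1", "end1", "strand1",
                           "chrom2", "start2", "end2", "strand2")],
               support = sum(m$support),
               n_reads = k,
               datasets = paste(sort(unique(m$dataset_id)), collapse = ","),
               members = paste(sort(idx), collapse = ","),
               left_span_start = min(m$start1), left_span_end = max(m$end1),
               right_span_start = min(m$start2), right_span_end = max(m$end2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$chrom1, out$start1, out$start2), , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Categorise merged interactions relative to the snoRNA's host gene
#'
#' For each merged interaction the snoRNA arm is the arm overlapping a snoRNA
#' (if both arms overlap the same snoRNA, the arm with the larger overlap; if
#' they overlap two distinct snoRNAs, one interaction is emitted per snoRNA).
#' The target arm is categorised as `host_same_intron` when contained in the
#' snoRNA's host intron, `host_other` when overlapping the host gene span
#' elsewhere, and `other_gene` otherwise (including target arms on another
#' chromosome or strand). Orientation compares the target-arm midpoint with
#' the snoRNA span, strand-aware (`upstream`/`downstream`/`overlapping`).
#'
#' @param merged Data frame from [merge_interactions()].
#' @param ann A `snohost_annotation`.
#' @param introns Optional precomputed [host_introns()] table.
#' @return A data frame with one row per (interaction, snoRNA): snoRNA and
#'   target arm coordinates, support, datasets, `category` and `orientation`.
#' @export
categorize_interactions <- function(merged, ann, introns = host_introns(ann)) {
  empty <- data.frame(sno_id = character(0), chrom = character(0),
                      sno_arm_start = integer(0), sno_arm_end = integer(0),
                      target_chrom = character(0), target_start = integer(0),
                      target_end = integer(0), target_strand = character(0),
                      strand = character(0), support = integer(0),
                      n_reads = integer(0), datasets = character(0),
                      category = character(0), orientation = character(0))
  if (nrow(merged) == 0) return(empty)
  sno1 <- arm_sno_hits(merged$chrom1, merged$start1, merged$end1,
                       merged$strand1, ann$snornas)
  sno2 <- arm_sno_hits(merged$chrom2, merged$start2, merged$end2,
                       merged$strand2, ann$snornas)
  rows <- list()
  for (i in seq_len(nrow(merged))) {
    m <- merged[i, , drop = FALSE]
    hits <- list()
    if (!is.na(sno1[i]) && !is.na(sno2[i]) && sno1[i] == sno2[i]) {
      s <- ann$snornas[ann$snornas$sno_id == sno1[i], ]
      ov1 <- overlap_width(s$start, s$end, m$start1, m$end1)
      ov2 <- overlap_width(s$start, s$end, m$start2, m$end2)
      hits[[1]] <- list(sno = sno1[i], sno_arm = if (ov1 >= ov2) 1L else 2L)
    } else {
      if (!is.na(sno1[i])) hits[[length(hits) + 1]] <- list(sno = sno1[i], sno_arm = 1L)
      if (!is.na(sno2[i])) hits[[length(hits) + 1]] <- list(sno = sno2[i], sno_arm = 2L)
    }
    if (length(hits) == 0) {
      stop("interaction without a snoRNA arm at row ", i,
           " (reads must be filtered first)")
    }
    for (h in hits) {
      sa <- h$sno_arm; ta <- 3L - sa
      sno <- ann$snornas[ann$snornas$sno_id == h$sno, ]
      t_chrom <- m[[paste0("chrom", ta)]]
      t_start <- m[[paste0("start", ta)]]
      t_end <- m[[paste0("end", ta)]]
      t_strand <- m[[paste0("strand", ta)]]

      category <- "other_gene"
      if (t_chrom == sno$chrom && t_strand == sno$strand) {
        hi <- introns[introns$sno_id == h$sno, , drop = FALSE]
        if (nrow(hi) == 1 &&
            contains(hi$start, hi$end, t_start, t_end)) {
          category <- "host_same_intron"
        } else if (!is.na(sno$host_gene_id)) {
          g <- ann$genes[ann$genes$gene_id == sno$host_gene_id, ]
          if (nrow(g) == 1 && spans_overlap(g$start, g$end, t_start, t_end)) {
            category <- "host_other"
          }
        }
      }
      mid <- (t_start + t_end) / 2
      side <- if (t_chrom != sno$chrom) NA_character_
      else if (mid < sno$start) "left"
      else if (mid >= sno$end) "right"
      else "overlapping"
      orientation <- if (is.na(side)) "trans"
      else if (side == "overlapping") "overlapping"
      else if ((side == "right") == (sno$strand == "+")) "downstream"
      else "upstream"

      span_cols <- c("left_span_start", "left_span_end",
                     "right_span_start", "right_span_end")
      have_spans <- all(span_cols %in% names(m))
      t_span_start <- if (have_spans && ta == 1L) m$left_span_start
      else if (have_spans) m$right_span_start else t_start
      t_span_end <- if (have_spans && ta == 1L) m$left_span_end
      else if (have_spans) m$right_span_end else t_end
      rows[[length(rows) + 1]] <- data.frame(
        sno_id = h$sno, chrom = m[[paste0("chrom", sa)]],
        sno_arm_start = m[[paste0("start", sa)]],
        sno_arm_end = m[[paste0("end", sa)]],
        target_chrom = t_chrom, target_start = t_start, target_end = t_end,
        target_strand = t_strand, strand = sno$strand,
        target_span_start = t_span_start, target_span_end = t_span_end,
        support = m$support, n_reads = m$n_reads, datasets = m$datasets,
        category = category, orientation = orientation,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  row.names(out) <- NULL
  out
}

#' Screen chimeric reads against an annotation
#'
#' Convenience wrapper: [load_chimeras()] (if given a path), then
#' [filter_chimeras()], [merge_interactions()] and
#' [categorize_interactions()].
#'
#' @param ann A `snohost_annotation`.
#' @param chimeras Path to a chimera TSV, or a data frame of reads.
#' @param min_arm_len,self_extension Filter thresholds, see
#'   [filter_chimeras()].
#' @return Categorised interaction table (see [categorize_interactions()]).
#' @export
screen_interactions <- function(ann, chimeras, min_arm_len = 9L,
                                self_extension = 10L) {
  reads <- if (is.character(chimeras)) load_chimeras(chimeras) else chimeras
  kept <- filter_chimeras(reads, ann, min_arm_len = min_arm_len,
                          self_extension = self_extension)
  categorize_interactions(merge_interactions(kept), ann)
}
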