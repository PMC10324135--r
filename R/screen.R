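# top-level driver: compute per-interaction evidence features, classify them,
# quantify PSI and correlate extension abundance with splicing.

# strand-aware RNA sequence of a genomic interval from a DNAStringSet genome
extract_rna <- function(genome, chrom, start, end, strand) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  s <- Biostrings::subseq(genome[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  chartr("T", "U", as.character(s))
}

#' Compute the five evidence features for host-intron interactions
#'
#' For each `host_same_intron` interaction: chimeric-read support, distance to
#' the closest alternative splice site of the host gene, mean conservation of
#' the target region, duplex MFE of the snoRNA against the target region
#' (reduced nearest-neighbour model), the per-nucleotide fold MFE of the
#' snoRNA-to-splice-site span, the extension coverage ratio (maximum over
#' samples when several coverage tracks are supplied), and branch-point
#' overlap.
#'
#' @param interactions Categorised interactions (rows with category
#'   `host_same_intron` are scored; other rows are ignored).
#' @param ann A `snohost_annotation`.
#' @param genome A `DNAStringSet` (or FASTA path).
#' @param conservation A `snohost_track` (or bedGraph path), or `NULL`.
#' @param coverage Named list of `snohost_track`s (or named vector of bedGraph
#'   paths), or `NULL`.
#' @param introns Precomputed [host_introns()] table.
#' @param branch_points Branch-point data frame from [read_branch_points()],
#'   or `NULL`.
#' @param table A `snohost_scoring` table.
#' @param use_span Use the merged cluster's target-arm span union (rather than
#'   the representative arm) as the interaction region; default `TRUE`.
#' @return A feature data frame, one row per host-intron interaction, with a
#'   `per_sample_ratio` attribute (matrix of extension ratios, interactions x
#'   samples) when coverage is supplied.
#' @export
compute_features <- function(interactions, ann, genome, conservation = NULL,
                             coverage = NULL, introns = host_introns(ann),
                             branch_points = NULL, table = scoring_table(),
                             use_span = TRUE) {
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  if (is.character(conservation)) conservation <- read_track(conservation)
  if (!is.null(coverage) && !inherits(coverage[[1]], "snohost_track")) {
    coverage <- lapply(coverage, read_track)
  }
  hi_rows <- interactions[interactions$category == "host_same_intron", ,
                          drop = FALSE]
  empty <- data.frame(sno_id = character(0), gene_id = character(0),
                      target_chrom = character(0), target_start = integer(0),
                      target_end = integer(0), support = integer(0),
                      splice_distance = integer(0),
                      mean_conservation = numeric(0), duplex_mfe = numeric(0),
                      mfe_per_nt = numeric(0), extension_ratio = numeric(0),
                      bp_overlap = logical(0))
  if (nrow(hi_rows) == 0) return(empty)

  site_cache <- list()
  out <- vector("list", nrow(hi_rows))
  ratio_mat <- if (!is.null(coverage)) {
    matrix(NA_real_, nrow(hi_rows), length(coverage),
           dimnames = list(NULL, names(coverage)))
  } else NULL

  for (i in seq_len(nrow(hi_rows))) {
    x <- hi_rows[i, ]
    sno <- ann$snornas[ann$snornas$sno_id == x$sno_id, ]
    hi <- introns[introns$sno_id == x$sno_id, , drop = FALSE]
    gene_id <- sno$host_gene_id
    region <- data.frame(
      chrom = x$target_chrom,
      start = if (use_span && "target_span_start" %in% names(x))
        x$target_span_start else x$target_start,
      end = if (use_span && "target_span_end" %in% names(x))
        x$target_span_end else x$target_end,
      strand = x$target_strand, stringsAsFactors = FALSE)
    # clip the interaction region to the intron, outside the snoRNA
    region$start <- max(region$start, hi$start)
    region$end <- min(region$end, hi$end)

    if (is.null(site_cache[[gene_id]])) {
      site_cache[[gene_id]] <- alternative_splice_sites(ann, gene_id)
    }
    dist <- splice_distance(sno, site_cache[[gene_id]])

    cons <- if (!is.null(conservation)) {
      as.numeric(mean_conservation(region, conservation))
    } else NA_real_

    sno_seq <- extract_rna(genome, sno$chrom, sno$start, sno$end, sno$strand)
    tgt_seq <- extract_rna(genome, region$chrom, region$start, region$end,
                           region$strand)
    dmfe <- duplex_mfe(sno_seq, tgt_seq, table)$mfe

    # intramolecular span: snoRNA through the interaction side of the intron
    span_start <- if (region$start >= sno$end) sno$start else hi$start
    span_end <- if (region$start >= sno$end) hi$end else sno$end
    span_seq <- extract_rna(genome, sno$chrom, span_start, span_end,
                            sno$strand)
    fold_len <- min(nchar(span_seq), 1000L)
    fmfe <- fold_mfe(span_seq, table)
    fpn <- mfe_per_nt(fmfe, fold_len)

    ratio <- NA_real_
    if (!is.null(coverage)) {
      rs <- vapply(coverage, function(tr) {
        suppressWarnings(extension_ratio(tr, sno, region, hi))
      }, numeric(1))
      ratio_mat[i, ] <- rs
      if (any(!is.na(rs))) ratio <- max(rs, na.rm = TRUE)
    }

    bp <- NULL
    if (!is.null(branch_points)) {
      in_intron <- branch_points$chrom == hi$chrom &
        branch_points$position >= hi$start & branch_points$position < hi$end
      if (any(in_intron)) {
        cand <- branch_points[in_intron, , drop = FALSE]
        bp <- cand[which.max(cand$score), , drop = FALSE]
      }
    }

    out[[i]] <- data.frame(
      sno_id = x$sno_id, gene_id = gene_id, target_chrom = region$chrom,
      target_start = region$start, target_end = region$end,
      support = x$support, splice_distance = dist, mean_conservation = cons,
      duplex_mfe = dmfe, mfe_per_nt = fpn, extension_ratio = ratio,
      bp_overlap = bp_overlap(region, bp), stringsAsFactors = FALSE)
  }
  features <- do.call(rbind, out)
  row.names(features) <- NULL
  if (!is.null(ratio_mat)) attr(features, "per_sample_ratio") <- ratio_mat
  features
}

#' Run the full snoRNA-host interaction screen
#'
#' End-to-end driver: parses annotation and genome, screens chimeric reads
#' (filter, merge, categorise), computes and classifies the evidence features
#' of host-intron interactions, quantifies cassette-exon PSI per sample when
#' junction evidence is supplied, and correlates extension abundance with PSI
#' across samples.
#'
#' @param gtf Path to the GTF annotation.
#' @param genome Path to the genome FASTA (or a `DNAStringSet`).
#' @param chimeras Path to the chimera TSV (or a data frame).
#' @param conservation Optional conservation bedGraph path (or
#'   `snohost_track`).
#' @param coverage Optional named vector of per-sample coverage bedGraph paths
#'   (or list of tracks).
#' @param depths Optional depth TSV path (`sample_id`, `mapped_reads`) or data
#'   frame.
#' @param junctions,exon_overlaps Optional evidence TSV paths (or data
#'   frames) for PSI quantification.
#' @param branch_points Optional branch-point TSV path (or data frame).
#' @param thresholds Evidence thresholds, see [evidence_thresholds()].
#' @param min_arm_len,self_extension Chimera filter settings.
#' @param table A `snohost_scoring` table.
#' @return An object of class `snohost_screen`: a list with `interactions`,
#'   `features`, `evidence`, `evidence_by_sno` (best-supported host-intron
#'   interaction per snoRNA), `psi`, `correlations`, `host_introns`,
#'   `n_snornas`, `params`.
#' @export
snohost_screen <- function(gtf, genome, chimeras, conservation = NULL,
                           coverage = NULL, depths = NULL, junctions = NULL,
                           exon_overlaps = NULL, branch_points = NULL,
                           thresholds = evidence_thresholds(),
                           min_arm_len = 9L, self_extension = 10L,
                           table = scoring_table()) {
  ann <- if (inherits(gtf, "snohost_annotation")) gtf else parse_annotation(gtf)
  if (is.character(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  introns <- host_introns(ann)
  interactions <- screen_interactions(ann, chimeras,
                                      min_arm_len = min_arm_len,
                                      self_extension = self_extension)
  if (is.character(conservation)) conservation <- read_track(conservation)
  cov_tracks <- NULL
  if (!is.null(coverage)) {
    cov_tracks <- if (is.character(coverage)) lapply(coverage, read_track)
    else coverage
    if (is.null(names(cov_tracks)) && is.character(coverage)) {
      names(cov_tracks) <- names(coverage)
    }
  }
  bp_df <- if (is.character(branch_points)) read_branch_points(branch_points)
  else branch_points

  features <- compute_features(interactions, ann, genome,
                               conservation = conservation,
                               coverage = cov_tracks, introns = introns,
                               branch_points = bp_df, table = table)
  evidence <- classify_evidence(features, thresholds)
  attr(evidence, "per_sample_ratio") <- attr(features, "per_sample_ratio")

  # best-supported host-intron interaction per snoRNA
  evidence_by_sno <- evidence[0, , drop = FALSE]
  if (nrow(evidence) > 0) {
    ord <- order(-evidence$support, -evidence$evidence_count)
    e2 <- evidence[ord, , drop = FALSE]
    evidence_by_sno <- e2[!duplicated(e2$sno_id), , drop = FALSE]
    row.names(evidence_by_sno) <- NULL
  }

  depth_df <- NULL
  if (!is.null(depths)) {
    depth_df <- if (is.character(depths)) read.delim(depths) else depths
  }
  junc_df <- if (is.character(junctions)) read.delim(junctions) else junctions
  over_df <- if (is.character(exon_overlaps)) read.delim(exon_overlaps)
  else exon_overlaps

  psi <- NULL
  correlations <- NULL
  if (!is.null(junc_df) && !is.null(over_df) && nrow(evidence_by_sno) > 0) {
    psi_rows <- list(); cor_rows <- list()
    for (i in seq_len(nrow(evidence_by_sno))) {
      e <- evidence_by_sno[i, ]
      cass <- cassette_exons(ann, e$gene_id)
      if (nrow(cass) == 0) next
      sno <- ann$snornas[ann$snornas$sno_id == e$sno_id, ]
      d <- pmin(abs(cass$start - sno$end), abs(cass$end - sno$start))
      cx <- cass[which.min(d), ]
      pt <- psi_table(junc_df, over_df, cx, cx$up_end, cx$down_start)
      if (nrow(pt) == 0 || all(is.na(pt$psi))) next
      pt$sno_id <- e$sno_id; pt$gene_id <- e$gene_id
      psi_rows[[length(psi_rows) + 1]] <- pt
      if (!is.null(cov_tracks) && !is.null(depth_df)) {
        hi <- introns[introns$sno_id == e$sno_id, ]
        win <- extension_window(sno, e, hi)
        abund <- vapply(names(cov_tracks), function(s) {
          raw <- track_window_sum(cov_tracks[[s]], hi$chrom, win[1],
                                  win[2])[["sum"]]
          dep <- depth_df$mapped_reads[depth_df$sample_id == s]
          if (length(dep) != 1) return(NA_real_)
          normalize_abundance(raw, dep)
        }, numeric(1))
        psi_v <- setNames(pt$psi, pt$sample_id)
        common <- intersect(names(abund), names(psi_v))
        if (length(common) >= 3) {
          ct <- correlate(abund[common], psi_v[common])
          cor_rows[[length(cor_rows) + 1]] <- data.frame(
            sno_id = e$sno_id, gene_id = e$gene_id, n = ct$n, r = ct$r,
            p_value = ct$p_value, constant = ct$constant,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(psi_rows) > 0) psi <- do.call(rbind, psi_rows)
    if (length(cor_rows) > 0) correlations <- do.call(rbind, cor_rows)
  }

  structure(list(
    interactions = interactions, features = features, evidence = evidence,
    evidence_by_sno = evidence_by_sno, psi = psi,
    correlations = correlations, host_introns = introns,
    n_snornas = nrow(ann$snornas),
    n_eligible_snornas = length(unique(introns$sno_id)),
    params = list(thresholds = thresholds, min_arm_len = min_arm_len,
                  self_extension = self_extension)),
    class = "snohost_screen")
}

# extension window from the snoRNA boundary to the interaction end, pad 2 nt
extension_window <- function(sno, interaction_row, intron) {
  t_start <- interaction_row$target_start
  t_end <- interaction_row$target_end
  if (t_start >= sno$end) {
    c(min(sno$end + 2L, intron$end), min(t_end, intron$end))
  } else {
    c(max(t_start, intron$start), max(sno$start - 2L, intron$start))
  }
}

#' @export
print.snohost_screen <- function(x, ...) {
  cat("snoRNA-host interaction screen\n")
  cat("  snoRNAs in registry:       ", x$n_snornas, "\n")
  cat("  with resolvable host intron:", x$n_eligible_snornas, "\n")
  cat("  merged interactions:       ", nrow(x$interactions), "\n")
  if (nrow(x$interactions) > 0) {
    tab <- table(x$interactions$category)
    for (nm in names(tab)) cat("    ", nm, ": ", tab[[nm]], "\n", sep = "")
  }
  cat("  host-intron interactions scored:", nrow(x$evidence), "\n")
  if (nrow(x$evidence_by_sno) > 0) {
    cat("  evidence count per snoRNA (best interaction):\n")
    print(table(x$evidence_by_sno$evidence_count))
  }
  invisible(x)
}

#' @exportS3Method base::summary
summary.snohost_screen <- function(object, ...) {
  out <- list(
    categories = if (nrow(object$interactions) > 0)
      table(object$interactions$category) else table(character(0)),
    evidence_counts = if (nrow(object$evidence_by_sno) > 0)
      table(factor(object$evidence_by_sno$evidence_count, levels = 0:5))
    else table(factor(integer(0), levels = 0:5)),
    flags = if (nrow(object$evidence) > 0)
      colSums(object$evidence[, c("pls_support", "stable_structure",
                                  "conservation", "ase_proximity",
                                  "extension")])
    else NULL,
    correlations = object$correlations)
  class(out) <- "summary.snohost_screen"
  out
}

#' @export
print.summary.snohost_screen <- function(x, ...) {
  cat("Interaction categories:\n"); print(x$categories)
  cat("\nEvidence counts (per snoRNA):\n"); print(x$evidence_counts)
  if (!is.null(x$flags)) {
    cat("\nEvidence flags satisfied (per interaction):\n"); print(x$flags)
  }
  if (!is.null(x$correlations)) {
    cat("\nExtension-abundance vs PSI correlations:\n")
    print(x$correlations, row.names = FALSE)
  }
  invisible(x)
}

#' @exportS3Method graphics::plot
plot.snohost_screen <- function(x, ...) {
  if (nrow(x$evidence_by_sno) == 0) {
    warning("nothing to plot: no host-intron interactions")
    return(invisible(x))
  }
  counts <- table(factor(x$evidence_by_sno$evidence_count, levels = 0:5))
  barplot(counts, xlab = "evidence count", ylab = "snoRNAs",
          main = "Evidence supporting snoRNA-host intron interactions", ...)
  invisible(x)
}
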