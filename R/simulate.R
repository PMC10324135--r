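# synthetic-data generator: fully deterministic loci with planted
# snoRNA-intron interactions, conservation contrast, extension-ratio signal,
# and per-sample PSI coupled (or not) to extension abundance.
#
# Geometry per interacting gene mirrors the canonical snoRNA/cassette-exon
# arrangement: the snoRNA sits in an intron whose transcript-downstream
# flanking exon is a cassette exon, with the planted intronic target region
# between the snoRNA's 3' boundary and the 3' splice site. The planted target
# sequence is the reverse complement of the snoRNA's 3'-terminal chunk, so the
# duplex model finds a strongly favourable interaction.

#' Synthetic-cosmos configuration
#'
#' Defaults define the study conditions used throughout the test suite:
#' 20 genes each hosting one snoRNA, half of the snoRNAs interacting with
#' their host intron with 6 supporting chimeric reads each, modest random
#' chimera noise, a conservation contrast of Beta(8,2) target regions over a
#' Beta(2,8) background, a planted extension coverage ratio of 4, and 12
#' samples whose extended-snoRNA abundance is negatively coupled to the
#' cassette-exon PSI.
#'
#' @param seed Mandatory root seed; named substreams are derived per file
#'   type, so regenerating one file type never perturbs the others.
#' @param n_genes Number of host genes (one snoRNA each).
#' @param n_samples Number of samples for coverage/junction tables.
#' @param fraction_interacting Fraction of snoRNAs with a planted host-intron
#'   interaction.
#' @param reads_per_interaction Chimeric-read support planted per interaction.
#' @param noise_chimeras Number of random noise chimeras (including sub-9-nt
#'   and intergenic arms).
#' @param short_arm_rate Fraction of noise arms drawn below 9 nt.
#' @param exons_per_gene,exon_length,intron_length Structural ranges (nt).
#' @param sno_length snoRNA length range (nt).
#' @param target_offset Distance from the snoRNA 3' boundary to the planted
#'   target region (nt).
#' @param target_length Planted target region length range (nt).
#' @param target_tail Distance from the target region to the 3' splice site
#'   (nt).
#' @param upstream_pad Intron space on the snoRNA's 5' side (nt), hosting
#'   matched negatives.
#' @param extra_isoform_prob Probability that a non-interacting gene carries a
#'   skip isoform of a far exon.
#' @param cons_target,cons_background Beta(shape1, shape2) parameters for
#'   per-base conservation in target regions / elsewhere.
#' @param background_coverage Mean intron coverage per base (reads).
#' @param sno_coverage_mult Coverage multiplier inside the mature snoRNA.
#' @param extension_ratio_true Planted extension/background coverage ratio.
#' @param extension_multipliers Per-sample abundance multipliers of the
#'   extended snoRNA species (length `n_samples`).
#' @param depth Nominal mapped reads per sample (jittered +/- 20% per sample).
#' @param junction_evidence_n Nominal splicing evidence reads per sample.
#' @param psi_base Baseline cassette PSI.
#' @param psi_extension_coupling Slope of PSI against the centred extension
#'   multiplier (negative couples high extension to exon skipping; 0 decouples
#'   them).
#' @param dataset_labels Chimera dataset labels to spread reads across.
#' @param self_read_scenarios Also emit, per planted snoRNA, one
#'   snoRNA-self read that survives the self filter (arm extending >= 10 nt
#'   into the intron) and one that it must discard.
#' @param intergenic_gap Gap range between genes (nt).
#' @return An object of class `snohost_config`.
#' @export
synthetic_config <- function(seed,
                             n_genes = 20L,
                             n_samples = 12L,
                             fraction_interacting = 0.5,
                             reads_per_interaction = 6L,
                             noise_chimeras = 60L,
                             short_arm_rate = 0.15,
                             exons_per_gene = c(4L, 6L),
                             exon_length = c(90L, 180L),
                             intron_length = c(250L, 450L),
                             sno_length = c(70L, 110L),
                             target_offset = c(20L, 40L),
                             target_length = c(25L, 40L),
                             target_tail = c(20L, 40L),
                             upstream_pad = c(100L, 250L),
                             extra_isoform_prob = 0.5,
                             cons_target = c(8, 2),
                             cons_background = c(2, 8),
                             background_coverage = 10,
                             sno_coverage_mult = 20,
                             extension_ratio_true = 4,
                             extension_multipliers = seq(0.5, 2,
                                                         length.out = n_samples),
                             depth = 1e5,
                             junction_evidence_n = 200L,
                             psi_base = 0.5,
                             psi_extension_coupling = -0.5,
                             dataset_labels = c("P0", "P1", "P2", "P3", "P4",
                                                "L0", "L1",
                                                "S0", "S1", "S2", "S3"),
                             self_read_scenarios = FALSE,
                             intergenic_gap = c(400L, 900L)) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  stopifnot(n_genes >= 1, n_samples >= 1,
            fraction_interacting >= 0, fraction_interacting <= 1,
            reads_per_interaction >= 1, noise_chimeras >= 0,
            exons_per_gene[1] >= 4,
            length(extension_multipliers) == n_samples,
            all(extension_multipliers > 0),
            background_coverage > 0, extension_ratio_true > 0,
            depth > 0, junction_evidence_n >= 1,
            psi_base >= 0, psi_base <= 1)
  if (target_length[1] < 17) {
    stop("target_length must be >= 17 nt so chimera arms stay >= 9 nt")
  }
  cfg <- as.list(environment())
  structure(cfg, class = "snohost_config")
}

r_range <- function(n, range) {
  if (range[1] == range[2]) rep(as.integer(range[1]), n)
  else sample(seq.int(range[1], range[2]), n, replace = TRUE)
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

revcomp_dna <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

#' Generate the synthetic locus (genome, annotation, ground truth)
#'
#' Builds the gene models, places one snoRNA per gene, plants target regions
#' complementary to the snoRNA 3' end in interacting genes, writes
#' `genome.fa`, `annotation.gtf` and `snornas.tsv` under `dir`, and returns
#' the ground truth. Deterministic given `cfg$seed`.
#'
#' @param cfg A `snohost_config`.
#' @param dir Output directory (created if needed).
#' @return The ground truth: a list with `genes`, `snornas`, `planted`,
#'   `samples`, `chrom`, `chrom_len` and output `paths`.
#' @export
generate_locus <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(substream_seed(cfg$seed, "locus"), {
    chrom <- "chrS"
    n_int <- round(cfg$n_genes * cfg$fraction_interacting)
    gene_rows <- list(); tx_rows <- list(); exon_rows <- list()
    sno_rows <- list(); planted <- list()

    cursor <- r_range(1, cfg$intergenic_gap)
    for (g in seq_len(cfg$n_genes)) {
      gid <- sprintf("GENE%02d", g)
      interacting <- g <= n_int
      strand <- sample(c("+", "-"), 1)
      K <- r_range(1, cfg$exons_per_gene)
      el <- r_range(K, cfg$exon_length)
      il <- r_range(K - 1, cfg$intron_length)

      # the snoRNA-hosting intron: genomic intron index j, composed so the
      # transcript-downstream flank (toward the cassette) holds the target
      j <- if (strand == "+") 2L else K - 2L
      upad <- r_range(1, cfg$upstream_pad)
      slen <- r_range(1, cfg$sno_length)
      off <- r_range(1, cfg$target_offset)
      tlen <- r_range(1, cfg$target_length)
      tail_len <- r_range(1, cfg$target_tail)
      il[j] <- upad + slen + off + tlen + tail_len

      starts <- integer(K); ends <- integer(K)
      p <- cursor
      for (k in seq_len(K)) {
        starts[k] <- p; ends[k] <- p + el[k]
        p <- ends[k] + if (k < K) il[k] else 0L
      }
      gene_start <- starts[1]; gene_end <- ends[K]
      cursor <- gene_end + r_range(1, cfg$intergenic_gap)

      intron_start <- ends[j]; intron_end <- starts[j + 1]
      if (strand == "+") {
        sno_start <- intron_start + upad
        sno_end <- sno_start + slen
        target_start <- sno_end + off
        target_end <- target_start + tlen
        chunk_start <- sno_end - tlen; chunk_end <- sno_end
        ext_start <- sno_end; ext_end <- target_end
        cassette_k <- j + 1L
      } else {
        sno_end <- intron_end - upad
        sno_start <- sno_end - slen
        target_end <- sno_start - off
        target_start <- target_end - tlen
        chunk_start <- sno_start; chunk_end <- sno_start + tlen
        ext_start <- target_start; ext_end <- sno_start
        cassette_k <- j
      }

      sid <- sprintf("SNO%02d", g)
      sno_rows[[g]] <- data.frame(
        sno_id = sid, box_type = sample(c("CD", "HACA"), 1), chrom = chrom,
        start = sno_start, end = sno_end, strand = strand, gene_id = gid,
        interacting = interacting, chunk_start = chunk_start,
        chunk_end = chunk_end, stringsAsFactors = FALSE)

      has_cassette <- interacting
      skip_k <- NA_integer_
      if (interacting) {
        skip_k <- cassette_k
      } else if (stats::runif(1) < cfg$extra_isoform_prob) {
        cand <- setdiff(2:(K - 1), c(j, j + 1L))
        if (length(cand) > 0) {
          skip_k <- cand[sample.int(length(cand), 1)]
          has_cassette <- TRUE
        }
      }

      tx_main <- paste0(gid, "-201")
      tx_rows[[length(tx_rows) + 1]] <- data.frame(
        transcript_id = tx_main, transcript_name = tx_main, gene_id = gid,
        biotype = "protein_coding", chrom = chrom, start = gene_start,
        end = gene_end, strand = strand, stringsAsFactors = FALSE)
      exon_rows[[length(exon_rows) + 1]] <- data.frame(
        transcript_id = tx_main, gene_id = gid, chrom = chrom,
        start = starts, end = ends, strand = strand, stringsAsFactors = FALSE)
      if (has_cassette) {
        tx_skip <- paste0(gid, "-202")
        keep <- setdiff(seq_len(K), skip_k)
        tx_rows[[length(tx_rows) + 1]] <- data.frame(
          transcript_id = tx_skip, transcript_name = tx_skip, gene_id = gid,
          biotype = "protein_coding", chrom = chrom, start = gene_start,
          end = gene_end, strand = strand, stringsAsFactors = FALSE)
        exon_rows[[length(exon_rows) + 1]] <- data.frame(
          transcript_id = tx_skip, gene_id = gid, chrom = chrom,
          start = starts[keep], end = ends[keep], strand = strand,
          stringsAsFactors = FALSE)
      }

      gene_rows[[g]] <- data.frame(
        gene_id = gid, biotype = "protein_coding", chrom = chrom,
        start = gene_start, end = gene_end, strand = strand,
        interacting = interacting, sno_id = sid,
        sno_intron_start = intron_start, sno_intron_end = intron_end,
        cassette_start = if (interacting) starts[cassette_k] else NA_integer_,
        cassette_end = if (interacting) ends[cassette_k] else NA_integer_,
        up_end = if (interacting) ends[cassette_k - 1L] else NA_integer_,
        down_start = if (interacting) starts[cassette_k + 1L] else NA_integer_,
        stringsAsFactors = FALSE)

      if (interacting) {
        planted[[length(planted) + 1]] <- data.frame(
          sno_id = sid, gene_id = gid, chrom = chrom, strand = strand,
          target_start = target_start, target_end = target_end,
          support = cfg$reads_per_interaction,
          ext_start = ext_start, ext_end = ext_end,
          stringsAsFactors = FALSE)
      }
    }

    chrom_len <- cursor + 50L
    bases <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
    seq_chr <- paste(bases, collapse = "")
    # plant complementarity: target genomic sequence is the reverse
    # complement of the snoRNA's duplex-forming chunk (strand independent)
    for (pl in planted) {
      s <- sno_rows[[match(pl$sno_id, vapply(sno_rows, function(x) x$sno_id,
                                             character(1)))]]
      chunk <- substr(seq_chr, s$chunk_start + 1, s$chunk_end)
      substr(seq_chr, pl$target_start + 1, pl$target_end) <- revcomp_dna(chunk)
    }

    genes <- do.call(rbind, gene_rows)
    snornas <- do.call(rbind, sno_rows)
    planted <- if (length(planted) > 0) do.call(rbind, planted) else
      data.frame(sno_id = character(0), gene_id = character(0),
                 chrom = character(0), strand = character(0),
                 target_start = integer(0), target_end = integer(0),
                 support = integer(0), ext_start = integer(0),
                 ext_end = integer(0))

    m <- cfg$extension_multipliers
    samples <- data.frame(
      sample_id = sprintf("S%02d", seq_len(cfg$n_samples)),
      multiplier = m,
      depth = round(cfg$depth * stats::runif(cfg$n_samples, 0.8, 1.2)),
      psi = clamp(cfg$psi_base + cfg$psi_extension_coupling * (m - mean(m)),
                  0.02, 0.98),
      stringsAsFactors = FALSE)

    ann <- structure(list(
      genes = genes[, c("gene_id", "biotype", "chrom", "start", "end", "strand")],
      transcripts = {
        tx <- do.call(rbind, tx_rows)
        tx$name_number <- transcript_name_number(tx$transcript_name)
        tx
      },
      exons = do.call(rbind, exon_rows),
      snornas = data.frame(snornas[, c("sno_id", "box_type", "chrom", "start",
                                       "end", "strand")],
                           host_gene_id = snornas$gene_id)),
      class = "snohost_annotation")

    paths <- list(fasta = file.path(dir, "genome.fa"),
                  gtf = file.path(dir, "annotation.gtf"),
                  snorna_registry = file.path(dir, "snornas.tsv"))
    genome <- Biostrings::DNAStringSet(setNames(seq_chr, chrom))
    Biostrings::writeXStringSet(genome, paths$fasta)
    write_annotation_gtf(ann, paths$gtf)
    write.table(snornas[, c("sno_id", "box_type", "chrom", "start", "end",
                            "strand", "gene_id")],
                paths$snorna_registry, sep = "\t", quote = FALSE,
                row.names = FALSE)

    list(genes = genes, snornas = snornas, planted = planted,
         samples = samples, chrom = chrom, chrom_len = chrom_len,
         paths = paths)
  })
}

#' Generate chimeric duplex reads for a synthetic locus
#'
#' Planted interactions contribute `support`-many reads with one arm jittered
#' inside the snoRNA's duplex-forming chunk and one inside the target region
#' (arm lengths >= 9 nt, jitter small enough that all reads of one
#' interaction mutually overlap), spread across dataset labels. Noise
#' chimeras have uniformly random arms, including sub-9-nt and intergenic
#' arms the filters must remove.
#'
#' @param cfg A `snohost_config`.
#' @param truth Ground truth from [generate_locus()].
#' @param path Output TSV path.
#' @return `path`, invisibly; the file gains a `chimeras` entry in
#'   `truth$paths` when called via [simulate_snohost()].
#' @export
generate_chimeras <- function(cfg, truth, path) {
  with_seed(substream_seed(cfg$seed, "chimeras"), {
    rows <- list()
    for (i in seq_len(nrow(truth$planted))) {
      pl <- truth$planted[i, ]
      s <- truth$snornas[truth$snornas$sno_id == pl$sno_id, ]
      tlen <- pl$target_end - pl$target_start
      armlen <- tlen - 8L
      for (r in seq_len(pl$support)) {
        so <- sample(0:8, 1); to <- sample(0:8, 1)
        a1 <- c(s$chunk_start + so, s$chunk_start + so + armlen)
        a2 <- c(pl$target_start + to, pl$target_start + to + armlen)
        rows[[length(rows) + 1]] <- data.frame(
          chrom1 = pl$chrom, start1 = a1[1], end1 = a1[2], strand1 = s$strand,
          chrom2 = pl$chrom, start2 = a2[1], end2 = a2[2], strand2 = s$strand,
          dataset_id = sample(cfg$dataset_labels, 1), support = 1L,
          stringsAsFactors = FALSE)
      }
      if (isTRUE(cfg$self_read_scenarios)) {
        # survivor: one arm extends 15 nt beyond the snoRNA 3' boundary
        rows[[length(rows) + 1]] <- data.frame(
          chrom1 = pl$chrom, start1 = s$start + 10L, end1 = s$start + 25L,
          strand1 = s$strand,
          chrom2 = pl$chrom, start2 = s$end - 10L, end2 = s$end + 15L,
          strand2 = s$strand,
          dataset_id = sample(cfg$dataset_labels, 1), support = 1L,
          stringsAsFactors = FALSE)
        # victim: both arms stay within the snoRNA boundaries
        rows[[length(rows) + 1]] <- data.frame(
          chrom1 = pl$chrom, start1 = s$start + 5L, end1 = s$start + 17L,
          strand1 = s$strand,
          chrom2 = pl$chrom, start2 = s$end - 14L, end2 = s$end - 2L,
          strand2 = s$strand,
          dataset_id = sample(cfg$dataset_labels, 1), support = 1L,
          stringsAsFactors = FALSE)
      }
    }
    if (cfg$noise_chimeras > 0) {
      arm <- function() {
        len <- if (stats::runif(1) < cfg$short_arm_rate) sample(4:8, 1)
        else sample(15:30, 1)
        start <- sample.int(truth$chrom_len - 35L, 1) - 1L
        c(start, start + len)
      }
      for (r in seq_len(cfg$noise_chimeras)) {
        a1 <- arm(); a2 <- arm()
        rows[[length(rows) + 1]] <- data.frame(
          chrom1 = truth$chrom, start1 = a1[1], end1 = a1[2],
          strand1 = sample(c("+", "-"), 1),
          chrom2 = truth$chrom, start2 = a2[1], end2 = a2[2],
          strand2 = sample(c("+", "-"), 1),
          dataset_id = sample(cfg$dataset_labels, 1), support = 1L,
          stringsAsFactors = FALSE)
      }
    }
    df <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(chrom1 = character(0), start1 = integer(0),
                 end1 = integer(0), strand1 = character(0),
                 chrom2 = character(0), start2 = integer(0),
                 end2 = integer(0), strand2 = character(0),
                 dataset_id = character(0), support = integer(0))
    # normalise arm order as the loader would
    swap <- df$start2 < df$start1
    if (any(swap)) {
      tmp <- df[swap, c("chrom1", "start1", "end1", "strand1")]
      df[swap, c("chrom1", "start1", "end1", "strand1")] <-
        df[swap, c("chrom2", "start2", "end2", "strand2")]
      df[swap, c("chrom2", "start2", "end2", "strand2")] <- tmp
    }
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
  })
}

# per-base values over an interval set, written as single-base bedGraph
write_bedgraph <- function(chrom, positions, values, path) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(positions + 1L, width = 1L),
                               score = values)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

# intron intervals of every gene's main (-201) transcript
main_introns <- function(truth) {
  out <- list()
  for (i in seq_len(nrow(truth$genes))) {
    g <- truth$genes[i, ]
    out[[i]] <- data.frame(gene_id = g$gene_id, start = g$sno_intron_start,
                           end = g$sno_intron_end, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate conservation and per-sample coverage tracks
#'
#' Conservation: per-base Beta draws, target parameters inside planted target
#' regions, background elsewhere, emitted over the snoRNA-hosting introns of
#' all genes. Coverage: per-base Poisson counts per sample; background level
#' over introns, elevated inside mature snoRNAs, and
#' `extension_ratio_true * multiplier[s]` times background inside planted
#' extension windows. Also writes a per-sample depth table.
#'
#' @param cfg A `snohost_config`.
#' @param truth Ground truth from [generate_locus()].
#' @param dir Output directory.
#' @return A list of paths: `conservation`, `coverage` (named by sample),
#'   `depths`.
#' @export
generate_tracks <- function(cfg, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(substream_seed(cfg$seed, "tracks"), {
    introns <- main_introns(truth)
    pos <- unlist(lapply(seq_len(nrow(introns)), function(i) {
      seq.int(introns$start[i], introns$end[i] - 1L)
    }))
    n <- length(pos)

    in_ranges <- function(p, starts, ends) {
      hit <- rep(FALSE, length(p))
      for (k in seq_along(starts)) hit <- hit | (p >= starts[k] & p < ends[k])
      hit
    }
    is_target <- in_ranges(pos, truth$planted$target_start,
                           truth$planted$target_end)
    cons <- numeric(n)
    cons[!is_target] <- stats::rbeta(sum(!is_target), cfg$cons_background[1],
                                     cfg$cons_background[2])
    cons[is_target] <- stats::rbeta(sum(is_target), cfg$cons_target[1],
                                    cfg$cons_target[2])
    cons_path <- file.path(dir, "conservation.bedgraph")
    write_bedgraph(truth$chrom, pos, round(cons, 4), cons_path)

    is_sno <- in_ranges(pos, truth$snornas$start, truth$snornas$end)
    is_ext <- in_ranges(pos, truth$planted$ext_start, truth$planted$ext_end)
    b <- cfg$background_coverage
    cov_paths <- character(0)
    for (si in seq_len(nrow(truth$samples))) {
      s <- truth$samples[si, ]
      lambda <- rep(b, n)
      lambda[is_sno] <- b * cfg$sno_coverage_mult
      lambda[is_ext] <- b * cfg$extension_ratio_true * s$multiplier
      counts <- stats::rpois(n, lambda)
      p <- file.path(dir, paste0("coverage_", s$sample_id, ".bedgraph"))
      write_bedgraph(truth$chrom, pos, counts, p)
      cov_paths[s$sample_id] <- p
    }
    depth_path <- file.path(dir, "depths.tsv")
    write.table(data.frame(sample_id = truth$samples$sample_id,
                           mapped_reads = truth$samples$depth),
                depth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(conservation = cons_path, coverage = cov_paths, depths = depth_path)
  })
}

#' Generate junction and exon-overlap evidence tables
#'
#' For each cassette-carrying gene and sample, inclusion and skip counts are
#' drawn binomially around the sample's PSI with `n` scaled by the sample's
#' sequencing depth. Interacting genes use the ground-truth PSI (coupled to
#' the extension multiplier when `psi_extension_coupling` is non-zero);
#' decoy cassettes use the constant `psi_base`.
#'
#' @param cfg A `snohost_config`.
#' @param truth Ground truth from [generate_locus()].
#' @param dir Output directory.
#' @return A list of paths: `junctions`, `exon_overlaps`.
#' @export
generate_junctions <- function(cfg, truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(substream_seed(cfg$seed, "junctions"), {
    jrows <- list(); orows <- list()
    cass <- truth$genes[!is.na(truth$genes$cassette_start), , drop = FALSE]
    for (gi in seq_len(nrow(cass))) {
      g <- cass[gi, ]
      for (si in seq_len(nrow(truth$samples))) {
        s <- truth$samples[si, ]
        psi <- if (g$interacting) s$psi else cfg$psi_base
        n_ev <- max(1L, round(cfg$junction_evidence_n * s$depth / cfg$depth))
        inc <- stats::rbinom(1, n_ev, psi)
        skip <- n_ev - inc
        jrows[[length(jrows) + 1]] <- data.frame(
          chrom = g$chrom,
          donor = c(g$up_end, g$up_end, g$cassette_end),
          acceptor = c(g$down_start, g$cassette_start, g$down_start),
          strand = g$strand, count = c(skip, inc, inc),
          sample_id = s$sample_id, stringsAsFactors = FALSE)
        orows[[length(orows) + 1]] <- data.frame(
          chrom = g$chrom, start = g$cassette_start, end = g$cassette_end,
          count = inc, sample_id = s$sample_id, stringsAsFactors = FALSE)
      }
    }
    junc_path <- file.path(dir, "junctions.tsv")
    over_path <- file.path(dir, "exon_overlaps.tsv")
    jdf <- if (length(jrows) > 0) do.call(rbind, jrows) else
      data.frame(chrom = character(0), donor = integer(0),
                 acceptor = integer(0), strand = character(0),
                 count = integer(0), sample_id = character(0))
    odf <- if (length(orows) > 0) do.call(rbind, orows) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 count = integer(0), sample_id = character(0))
    write.table(jdf, junc_path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(odf, over_path, sep = "\t", quote = FALSE, row.names = FALSE)
    list(junctions = junc_path, exon_overlaps = over_path)
  })
}

# branch points: the true one near the transcript 3' end of the sno intron
# plus weaker decoy rows, so only the top-scoring row should be used
generate_branch_points <- function(cfg, truth, path) {
  with_seed(substream_seed(cfg$seed, "branchpoints"), {
    rows <- list()
    for (i in seq_len(nrow(truth$genes))) {
      g <- truth$genes[i, ]
      bp <- if (g$strand == "+") g$sno_intron_end - 25L else
        g$sno_intron_start + 24L
      decoy1 <- if (g$strand == "+") g$sno_intron_start + 40L else
        g$sno_intron_end - 40L
      rows[[i]] <- data.frame(
        intron_id = paste0(g$gene_id, "-201-I"),
        chrom = g$chrom, position = c(bp, decoy1),
        score = c(0.9, round(stats::runif(1, 0.2, 0.6), 3)),
        stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
  })
}

#' Generate a complete synthetic cosmos
#'
#' Runs [generate_locus()], [generate_chimeras()], [generate_tracks()] and
#' [generate_junctions()], plus a branch-point table and a ground-truth JSON,
#' all under one directory. Byte-identical for identical `cfg` (including
#' `seed`).
#'
#' @param cfg A `snohost_config`.
#' @param dir Output directory.
#' @return A list with `paths` (all emitted files), `truth` and `config`.
#' @export
simulate_snohost <- function(cfg, dir) {
  stopifnot(inherits(cfg, "snohost_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  truth <- generate_locus(cfg, dir)
  paths <- truth$paths
  paths$chimeras <- file.path(dir, "chimeras.tsv")
  generate_chimeras(cfg, truth, paths$chimeras)
  paths <- c(paths, generate_tracks(cfg, truth, dir))
  paths <- c(paths, generate_junctions(cfg, truth, dir))
  paths$branch_points <- file.path(dir, "branch_points.tsv")
  generate_branch_points(cfg, truth, paths$branch_points)
  paths$ground_truth <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(
    list(chrom = truth$chrom, chrom_len = truth$chrom_len,
         planted = truth$planted, samples = truth$samples,
         snornas = truth$snornas),
    paths$ground_truth, auto_unbox = TRUE, digits = NA)
  truth$paths <- paths
  list(paths = paths, truth = truth, config = cfg)
}
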