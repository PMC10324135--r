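# genome/annotation handling: GTF parsing, snoRNA registry, host-intron
# resolution, alternative splice sites, transcript counts.

#' Parse an Ensembl-style GTF annotation
#'
#' Reads gene, transcript and exon records plus a snoRNA registry from a GTF
#' file (1-based inclusive coordinates; converted internally to 0-based
#' half-open). snoRNAs are gene records whose `gene_biotype` is `"snoRNA"`;
#' each snoRNA is assigned the host gene whose span contains it on the same
#' strand (the smallest such span if several), or none.
#'
#' @param gtf_path Path to a GTF file with Ensembl-style attributes
#'   (`gene_id`, `transcript_id`, `transcript_name`, `gene_biotype`,
#'   `transcript_biotype`; an optional `box_type` attribute on snoRNA genes is
#'   carried through).
#' @return An object of class `snohost_annotation`: a list with data frames
#'   `genes`, `transcripts`, `exons` and `snornas` (all coordinates 0-based
#'   half-open).
#' @examples
#' cfg <- synthetic_config(seed = 1, n_genes = 2)
#' sim <- simulate_snohost(cfg, dir = tempfile())
#' ann <- parse_annotation(sim$paths$gtf)
#' ann$snornas
#' @export
parse_annotation <- function(gtf_path) {
  gr <- tryCatch(
    rtracklayer::import(gtf_path, format = "gtf"),
    error = function(e) {
      stop("GTF parse error in '", gtf_path, "': ", conditionMessage(e))
    }
  )
  md <- S4Vectors::mcols(gr)
  get_col <- function(col) {
    if (col %in% names(md)) as.character(md[[col]]) else rep(NA_character_, length(gr))
  }
  type <- get_col("type")
  gene_id <- get_col("gene_id")
  tx_id <- get_col("transcript_id")
  tx_name <- get_col("transcript_name")
  gene_biotype <- get_col("gene_biotype")
  tx_biotype <- get_col("transcript_biotype")
  box_type <- get_col("box_type")
  pos <- gr_to_df(gr)

  is_gene <- type == "gene"
  genes <- data.frame(
    gene_id = gene_id[is_gene],
    biotype = gene_biotype[is_gene],
    pos[is_gene, , drop = FALSE],
    stringsAsFactors = FALSE, row.names = NULL
  )
  validate_intervals(genes, "gene record")

  is_tx <- type == "transcript"
  transcripts <- data.frame(
    transcript_id = tx_id[is_tx],
    transcript_name = tx_name[is_tx],
    gene_id = gene_id[is_tx],
    biotype = ifelse(is.na(tx_biotype[is_tx]), gene_biotype[is_tx],
                     tx_biotype[is_tx]),
    pos[is_tx, , drop = FALSE],
    stringsAsFactors = FALSE, row.names = NULL
  )
  transcripts$name_number <- transcript_name_number(transcripts$transcript_name)
  validate_intervals(transcripts, "transcript record")

  is_exon <- type == "exon"
  exons <- data.frame(
    transcript_id = tx_id[is_exon],
    gene_id = gene_id[is_exon],
    pos[is_exon, , drop = FALSE],
    stringsAsFactors = FALSE, row.names = NULL
  )
  validate_intervals(exons, "exon record")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  row.names(exons) <- NULL

  # exon within the declared transcript span
  tx_start <- setNames(transcripts$start, transcripts$transcript_id)
  tx_end <- setNames(transcripts$end, transcripts$transcript_id)
  known <- exons$transcript_id %in% transcripts$transcript_id
  bad <- known & (exons$start < tx_start[exons$transcript_id] |
                    exons$end > tx_end[exons$transcript_id])
  if (any(bad)) {
    stop("exon outside its transcript's declared span for transcript(s): ",
         paste(unique(exons$transcript_id[bad]), collapse = ", "))
  }

  is_sno <- is_gene & !is.na(gene_biotype) & gene_biotype == "snoRNA"
  snornas <- data.frame(
    sno_id = gene_id[is_sno],
    box_type = box_type[is_sno],
    pos[is_sno, , drop = FALSE],
    stringsAsFactors = FALSE, row.names = NULL
  )

  host_genes <- genes[genes$biotype != "snoRNA", , drop = FALSE]
  snornas$host_gene_id <- vapply(seq_len(nrow(snornas)), function(i) {
    s <- snornas[i, ]
    hit <- host_genes$chrom == s$chrom & host_genes$strand == s$strand &
      contains(host_genes$start, host_genes$end, s$start, s$end)
    if (!any(hit)) return(NA_character_)
    cand <- host_genes[hit, , drop = FALSE]
    cand$gene_id[which.min(cand$end - cand$start)]
  }, character(1))

  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 snornas = snornas),
            class = "snohost_annotation")
}

# Parse the Ensembl "-NNN" suffix of a transcript name; NA when absent.
transcript_name_number <- function(transcript_name) {
  m <- regmatches(transcript_name, regexpr("-([0-9]+)$", transcript_name))
  out <- rep(NA_integer_, length(transcript_name))
  has <- lengths(regmatches(transcript_name,
                            gregexpr("-([0-9]+)$", transcript_name))) > 0
  out[has] <- as.integer(sub("^-", "", m))
  out
}

#' Write an annotation back to GTF
#'
#' Inverse of [parse_annotation()]; coordinates are converted back to GTF's
#' 1-based inclusive convention. Used for round-trip validation and by the
#' synthetic-data generator.
#'
#' @param ann A `snohost_annotation`.
#' @param path Output GTF path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(ann, path) {
  rows <- list()
  g <- ann$genes
  rows$gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start + 1L, g$end), g$strand,
    type = "gene", gene_id = g$gene_id, gene_biotype = g$biotype
  )
  tx <- ann$transcripts
  rows$tx <- GenomicRanges::GRanges(
    tx$chrom, IRanges::IRanges(tx$start + 1L, tx$end), tx$strand,
    type = "transcript", gene_id = tx$gene_id, transcript_id = tx$transcript_id,
    transcript_name = tx$transcript_name, transcript_biotype = tx$biotype
  )
  ex <- ann$exons
  rows$exon <- GenomicRanges::GRanges(
    ex$chrom, IRanges::IRanges(ex$start + 1L, ex$end), ex$strand,
    type = "exon", gene_id = ex$gene_id, transcript_id = ex$transcript_id
  )
  sn <- ann$snornas
  if (nrow(sn) > 0) {
    rows$sno <- GenomicRanges::GRanges(
      sn$chrom, IRanges::IRanges(sn$start + 1L, sn$end), sn$strand,
      type = "gene", gene_id = sn$sno_id, gene_biotype = "snoRNA",
      box_type = sn$box_type
    )
  }
  all_gr <- suppressWarnings(do.call(c, lapply(unname(rows), function(x) {
    S4Vectors::mcols(x) <- S4Vectors::mcols(x)[,
      intersect(c("type", "gene_id", "gene_biotype", "transcript_id",
                  "transcript_name", "transcript_biotype", "box_type"),
                names(S4Vectors::mcols(x))), drop = FALSE]
    x
  })))
  # harmonise metadata columns across record types
  all_cols <- c("type", "gene_id", "gene_biotype", "transcript_id",
                "transcript_name", "transcript_biotype", "box_type")
  md <- S4Vectors::mcols(all_gr)
  for (col in setdiff(all_cols, names(md))) md[[col]] <- NA_character_
  S4Vectors::mcols(all_gr) <- md[, all_cols]
  rtracklayer::export(all_gr, path, format = "gtf")
  invisible(path)
}

#' Introns of a transcript
#'
#' Introns are the gaps between consecutive exons, in 0-based half-open
#' coordinates. The 1-based `ordinal` follows the transcript's reading
#' direction (intron 1 follows exon 1 on the transcribed strand).
#'
#' @param ann A `snohost_annotation`.
#' @param transcript_id Transcript identifier.
#' @return A data frame with columns `chrom`, `start`, `end`, `strand`,
#'   `ordinal` (0 rows for single-exon transcripts).
#' @export
transcript_introns <- function(ann, transcript_id) {
  ex <- ann$exons[ann$exons$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(ex) == 0) stop("unknown transcript: ", transcript_id)
  ex <- ex[order(ex$start), , drop = FALSE]
  if (nrow(ex) == 1) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      ordinal = integer(0)))
  }
  n <- nrow(ex)
  introns <- data.frame(
    chrom = ex$chrom[-n],
    start = ex$end[-n],
    end = ex$start[-1],
    strand = ex$strand[-n],
    stringsAsFactors = FALSE
  )
  introns$ordinal <- if (ex$strand[1] == "+") seq_len(n - 1) else rev(seq_len(n - 1))
  validate_intervals(introns, "intron")
  introns
}

#' Resolve the host intron of a snoRNA
#'
#' Among the protein-coding transcripts of the snoRNA's host gene in which the
#' snoRNA lies entirely within one intron, the transcript with the smallest
#' Ensembl name number (the "-201" style suffix) is chosen; transcripts
#' without a numeric suffix sort after all numbered ones, ties broken
#' lexicographically by transcript id.
#'
#' @param ann A `snohost_annotation`.
#' @param sno_id snoRNA identifier from the registry.
#' @return A one-row data frame (`sno_id`, `transcript_id`, `chrom`, `start`,
#'   `end`, `strand`, `intron_ordinal`), or `NULL` if no transcript qualifies
#'   (including snoRNAs without a same-strand host gene).
#' @export
resolve_host_intron <- function(ann, sno_id) {
  s <- ann$snornas[ann$snornas$sno_id == sno_id, , drop = FALSE]
  if (nrow(s) != 1) stop("unknown snoRNA: ", sno_id)
  if (is.na(s$host_gene_id)) return(NULL)
  tx <- ann$transcripts[ann$transcripts$gene_id == s$host_gene_id, , drop = FALSE]
  if (nrow(tx) == 0) stop("host gene ", s$host_gene_id, " has no transcripts")
  tx <- tx[tx$biotype == "protein_coding", , drop = FALSE]
  if (nrow(tx) == 0) return(NULL)
  ord <- order(is.na(tx$name_number), tx$name_number, tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  for (i in seq_len(nrow(tx))) {
    introns <- transcript_introns(ann, tx$transcript_id[i])
    hit <- which(introns$chrom == s$chrom &
                   contains(introns$start, introns$end, s$start, s$end))
    if (length(hit) == 1) {
      return(data.frame(sno_id = sno_id,
                        transcript_id = tx$transcript_id[i],
                        chrom = introns$chrom[hit],
                        start = introns$start[hit],
                        end = introns$end[hit],
                        strand = introns$strand[hit],
                        intron_ordinal = introns$ordinal[hit],
                        stringsAsFactors = FALSE))
    }
  }
  NULL
}

#' Host introns for all snoRNAs in the registry
#'
#' @param ann A `snohost_annotation`.
#' @return A data frame with one row per snoRNA with a resolvable host intron
#'   (columns as in [resolve_host_intron()]).
#' @export
host_introns <- function(ann) {
  out <- lapply(ann$snornas$sno_id, function(id) resolve_host_intron(ann, id))
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    return(data.frame(sno_id = character(0), transcript_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      intron_ordinal = integer(0)))
  }
  do.call(rbind, out)
}

#' Eligible host-gene snoRNAs
#'
#' Returns exactly the snoRNAs with a defined host intron, i.e. snoRNAs on the
#' same strand as a host gene, entirely intronic in at least one protein-coding
#' transcript of that gene. Order of the registry is preserved.
#'
#' @param ann A `snohost_annotation`.
#' @return A subset of `ann$snornas`.
#' @export
eligible_host_snornas <- function(ann) {
  hi <- host_introns(ann)
  ann$snornas[ann$snornas$sno_id %in% hi$sno_id, , drop = FALSE]
}

#' Alternative (differential) splice sites of a gene
#'
#' An exon-boundary position is reported iff it is used as an exon boundary by
#' at least one isoform of the gene and not by all isoforms. Transcript-terminal
#' boundaries (transcription start/end) are not splice sites and are excluded.
#' Each position is labelled 5' (donor) or 3' (acceptor) relative to the
#' strand. Positions are boundary coordinates under the half-open convention
#' (an exon `[s, e)` contributes `s` and `e`).
#'
#' @param ann A `snohost_annotation`.
#' @param gene_id Gene identifier.
#' @return A data frame with columns `chrom`, `position`, `side` (`"5p"` or
#'   `"3p"`), `strand`, `n_using`, `n_transcripts`.
#' @export
alternative_splice_sites <- function(ann, gene_id) {
  tx <- ann$transcripts[ann$transcripts$gene_id == gene_id, , drop = FALSE]
  if (nrow(tx) == 0) stop("unknown gene: ", gene_id)
  empty <- data.frame(chrom = character(0), position = integer(0),
                      side = character(0), strand = character(0),
                      n_using = integer(0), n_transcripts = integer(0))
  if (nrow(tx) < 2) return(empty)
  per_tx <- lapply(tx$transcript_id, function(id) {
    ex <- ann$exons[ann$exons$transcript_id == id, , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    n <- nrow(ex)
    if (n < 2) {
      return(data.frame(position = integer(0), side = character(0)))
    }
    plus <- ex$strand[1] == "+"
    # donors sit at the exon end adjacent to a downstream intron
    donors <- if (plus) ex$end[-n] else ex$start[-1]
    acceptors <- if (plus) ex$start[-1] else ex$end[-n]
    data.frame(position = c(donors, acceptors),
               side = rep(c("5p", "3p"), c(length(donors), length(acceptors))),
               stringsAsFactors = FALSE)
  })
  all_sites <- unique(do.call(rbind, per_tx))
  if (nrow(all_sites) == 0) return(empty)
  n_tx <- nrow(tx)
  n_using <- vapply(seq_len(nrow(all_sites)), function(i) {
    sum(vapply(per_tx, function(p) {
      any(p$position == all_sites$position[i] & p$side == all_sites$side[i])
    }, logical(1)))
  }, integer(1))
  keep <- n_using >= 1 & n_using < n_tx
  out <- all_sites[keep, , drop = FALSE]
  if (nrow(out) == 0) return(empty)
  data.frame(chrom = tx$chrom[1], position = out$position, side = out$side,
             strand = tx$strand[1], n_using = n_using[keep],
             n_transcripts = n_tx, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Distance from a snoRNA to the closest alternative splice site
#'
#' The minimum over sites of the distance between the site position and the
#' nearer of the snoRNA's two boundaries; 0 if a site falls within the snoRNA.
#'
#' @param sno A one-row interval data frame (the snoRNA location).
#' @param sites A data frame with a `position` column (e.g. from
#'   [alternative_splice_sites()]).
#' @return Non-negative integer distance in nt, or `NA_integer_` if `sites`
#'   is empty.
#' @export
splice_distance <- function(sno, sites) {
  if (is.null(sites) || nrow(sites) == 0) return(NA_integer_)
  p <- sites$position
  d <- ifelse(p >= sno$start & p <= sno$end, 0L,
              pmin(abs(p - sno$start), abs(p - sno$end)))
  as.integer(min(d))
}

#' Number of annotated transcripts of a gene
#'
#' Counts transcripts of all biotypes.
#'
#' @param ann A `snohost_annotation`.
#' @param gene_id Gene identifier.
#' @return Integer count.
#' @export
transcript_count <- function(ann, gene_id) {
  if (!gene_id %in% ann$transcripts$gene_id &&
      !gene_id %in% ann$genes$gene_id) {
    stop("unknown gene: ", gene_id)
  }
  sum(ann$transcripts$gene_id == gene_id)
}

#' Cassette exons of a gene
#'
#' Exons (identical start/end) used by at least one isoform but absent from at
#' least one other isoform whose span covers the exon. For each cassette the
#' flanking exons are taken from the lowest-numbered transcript containing it.
#'
#' @param ann A `snohost_annotation`.
#' @param gene_id Gene identifier.
#' @return A data frame with the cassette exon and its transcript-level
#'   upstream/downstream flanking exon coordinates (genomic `up_*` = lower
#'   coordinate side), or 0 rows.
#' @export
cassette_exons <- function(ann, gene_id) {
  tx <- ann$transcripts[ann$transcripts$gene_id == gene_id, , drop = FALSE]
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      up_end = integer(0), down_start = integer(0),
                      transcript_id = character(0))
  if (nrow(tx) < 2) return(empty)
  ord <- order(is.na(tx$name_number), tx$name_number, tx$transcript_id)
  tx <- tx[ord, , drop = FALSE]
  ex_by_tx <- lapply(tx$transcript_id, function(id) {
    e <- ann$exons[ann$exons$transcript_id == id, , drop = FALSE]
    e[order(e$start), , drop = FALSE]
  })
  keys <- lapply(ex_by_tx, function(e) paste(e$start, e$end))
  out <- list()
  seen <- character(0)
  for (i in seq_along(ex_by_tx)) {
    e <- ex_by_tx[[i]]
    n <- nrow(e)
    if (n < 3) next
    for (k in 2:(n - 1)) {   # internal exons only: need both flanks
      key <- paste(e$start[k], e$end[k])
      if (key %in% seen) next
      absent_somewhere <- any(vapply(seq_along(keys), function(j) {
        j != i && !(key %in% keys[[j]]) &&
          tx$start[j] <= e$start[k] && e$end[k] <= tx$end[j]
      }, logical(1)))
      if (absent_somewhere) {
        seen <- c(seen, key)
        out[[length(out) + 1]] <- data.frame(
          chrom = e$chrom[k], start = e$start[k], end = e$end[k],
          strand = e$strand[k], up_end = e$end[k - 1],
          down_start = e$start[k + 1], transcript_id = tx$transcript_id[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(empty)
  do.call(rbind, out)
}
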