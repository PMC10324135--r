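test_that("GTF parsing converts coordinates and derives introns and hosts", {
  ann0 <- make_ann()
  gtf <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ann0, gtf)
  ann <- parse_annotation(gtf)

  # GTF is 1-based inclusive; internal coordinates 0-based half-open
  lines <- readLines(gtf)
  exon1 <- grep("\texon\t", lines, value = TRUE)[1]
  f <- strsplit(exon1, "\t")[[1]]
  expect_equal(as.integer(f[4]), 101L)   # start 100 -> GTF 101
  expect_equal(as.integer(f[5]), 200L)   # end stays 200

  # round trip: identical interval sets
  key <- function(df) sort(paste(df$transcript_id, df$chrom, df$start,
                                 df$end, df$strand))
  expect_identical(key(ann$exons), key(ann0$exons))
  expect_setequal(paste(ann$transcripts$transcript_id,
                        ann$transcripts$biotype),
                  paste(ann0$transcripts$transcript_id,
                        ann0$transcripts$biotype))

  # two-exon transcript -> one intron in the gap
  introns <- transcript_introns(ann, "GENEA-203")
  expect_equal(nrow(introns), 1L)
  expect_equal(c(introns$start, introns$end), c(200L, 700L))

  # host gene: same-strand containment
  sn <- ann$snornas
  expect_equal(sn$host_gene_id[sn$sno_id == "SNOA"], "GENEA")
  expect_true(is.na(sn$host_gene_id[sn$sno_id == "SNOC"]))
})

test_that("a snoRNA antisense to its containing gene gets no host", {
  ann0 <- make_ann()
  ann0$snornas$strand[ann0$snornas$sno_id == "SNOA"] <- "-"
  gtf <- tempfile(fileext = ".gtf")
  write_annotation_gtf(ann0, gtf)
  ann <- parse_annotation(gtf)
  expect_true(is.na(ann$snornas$host_gene_id[ann$snornas$sno_id == "SNOA"]))
  expect_false("SNOA" %in% eligible_host_snornas(ann)$sno_id)
})

test_that("host intron resolution prefers the lowest transcript number", {
  ann <- make_ann()
  hi <- resolve_host_intron(ann, "SNOA")
  expect_equal(hi$transcript_id, "GENEA-201")
  expect_equal(c(hi$start, hi$end), c(400L, 500L))
  expect_equal(hi$intron_ordinal, 2L)

  # snoRNA overlapping an exon of -201 but intronic in -202: -202 wins
  ann2 <- make_ann()
  ann2$snornas$start[1] <- 480L; ann2$snornas$end[1] <- 540L  # crosses exon 3
  hi2 <- resolve_host_intron(ann2, "SNOA")
  expect_equal(hi2$transcript_id, "GENEA-202")
  expect_equal(c(hi2$start, hi2$end), c(400L, 700L))

  # exonic in every protein-coding transcript: none
  ann3 <- make_ann()
  ann3$snornas$start[1] <- 150L; ann3$snornas$end[1] <- 190L
  expect_null(resolve_host_intron(ann3, "SNOA"))

  # intronic only in a non-protein-coding transcript: none
  ann4 <- make_ann()
  ann4$transcripts$biotype[ann4$transcripts$gene_id == "GENEA" &
                             ann4$transcripts$biotype == "protein_coding"] <-
    "retained_intron"
  expect_null(resolve_host_intron(ann4, "SNOA"))

  # minus-strand host works and containment invariant holds
  hib <- resolve_host_intron(ann, "SNOB")
  expect_equal(hib$transcript_id, "GENEB-201")
  s <- ann$snornas[ann$snornas$sno_id == "SNOB", ]
  expect_true(hib$start <= s$start && s$end <= hib$end)
  # ordinal is transcript-directional: genomic intron [2400,2600) is intron 1
  expect_equal(hib$intron_ordinal, 1L)
})

test_that("transcripts without a numeric name suffix sort last", {
  ann <- make_ann()
  ann$transcripts$transcript_name[1] <- "GENEA-alpha"
  ann$transcripts$name_number[1] <- NA_integer_
  hi <- resolve_host_intron(ann, "SNOA")
  expect_equal(hi$transcript_id, "GENEA-202")
})

test_that("eligible snoRNAs are exactly those with a host intron", {
  ann <- make_ann()
  el <- eligible_host_snornas(ann)
  expect_setequal(el$sno_id, c("SNOA", "SNOB"))
  expect_identical(el$sno_id, c("SNOA", "SNOB"))  # registry order preserved
})

test_that("alternative splice sites are boundaries used by some isoforms only", {
  ann <- make_ann()
  sites <- alternative_splice_sites(ann, "GENEA")
  # cassette exon [500,600) boundaries + the boundaries skipped by -203
  expect_setequal(sites$position, c(300L, 400L, 500L, 600L))
  # cassette acceptor at 500 is a 3' site on the + strand, donor at 600 a 5'
  expect_equal(sites$side[sites$position == 500L], "3p")
  expect_equal(sites$side[sites$position == 600L], "5p")

  # single isoform gene: no differential sites
  expect_equal(nrow(alternative_splice_sites(ann, "GENEB")), 0L)

  # duplicating an isoform changes nothing
  ann2 <- make_ann()
  dup_tx <- ann2$transcripts[1, ]; dup_tx$transcript_id <- "GENEA-299"
  dup_tx$transcript_name <- "GENEA-299"; dup_tx$name_number <- 299L
  ann2$transcripts <- rbind(ann2$transcripts, dup_tx)
  dup_ex <- ann2$exons[ann2$exons$transcript_id == "GENEA-201", ]
  dup_ex$transcript_id <- "GENEA-299"
  ann2$exons <- rbind(ann2$exons, dup_ex)
  s2 <- alternative_splice_sites(ann2, "GENEA")
  expect_identical(s2[order(s2$position, s2$side),
                      c("position", "side")],
                   sites[order(sites$position, sites$side),
                         c("position", "side")])

  # two isoforms with identical exon structure: empty
  ann3 <- make_ann()
  keep <- ann3$transcripts$transcript_id %in% c("GENEA-201", "GENEA-299")
  ann3$transcripts <- rbind(ann3$transcripts[1, ], dup_tx)
  ann3$exons <- rbind(dup_ex, {
    e <- dup_ex; e$transcript_id <- "GENEA-201"; e
  })
  expect_equal(nrow(alternative_splice_sites(ann3, "GENEA")), 0L)
})

test_that("splice distance follows the definition and strand symmetry", {
  sno <- genomic_interval("chr1", 1000, 1100, "+")
  expect_equal(splice_distance(sno, data.frame(position = 1220)), 120L)
  expect_equal(splice_distance(sno, data.frame(position = 1050)), 0L)
  expect_true(is.na(splice_distance(sno, data.frame(position = integer(0)))))
  expect_equal(splice_distance(sno, data.frame(position = c(1220, 900, 1050))),
               0L)

  # mirroring the whole locus leaves the distance unchanged
  L <- 10000
  sites <- data.frame(position = c(1220, 870))
  mirrored_sno <- genomic_interval("chr1", L - 1100, L - 1000, "-")
  mirrored_sites <- data.frame(position = L - sites$position)
  expect_equal(splice_distance(sno, sites),
               splice_distance(mirrored_sno, mirrored_sites))
})

test_that("transcript counts cover all biotypes", {
  ann <- make_ann()
  expect_equal(transcript_count(ann, "GENEA"), 3L)
  expect_equal(transcript_count(ann, "GENEB"), 1L)
  expect_error(transcript_count(ann, "NOPE"), "unknown gene")

  # a gene built with 27 isoforms reports 27
  ann27 <- make_ann()
  for (k in 2:27) {
    tx <- ann27$transcripts[4, ]
    tx$transcript_id <- tx$transcript_name <- sprintf("GENEB-2%02d", k)
    tx$name_number <- 200L + k
    ann27$transcripts <- rbind(ann27$transcripts, tx)
    ex <- ann27$exons[ann27$exons$transcript_id == "GENEB-201", ]
    ex$transcript_id <- tx$transcript_id
    ann27$exons <- rbind(ann27$exons, ex)
  }
  expect_equal(transcript_count(ann27, "GENEB"), 27L)
})

test_that("cassette exons are detected with their flanks", {
  ann <- make_ann()
  cx <- cassette_exons(ann, "GENEA")
  expect_true(nrow(cx) >= 1)
  main <- cx[cx$start == 500L, ]
  expect_equal(nrow(main), 1L)
  expect_equal(main$up_end, 400L)
  expect_equal(main$down_start, 700L)
})
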