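test_that("the generator is byte-identical given the same configuration", {
  cfg <- synthetic_config(seed = 9, n_genes = 4, n_samples = 3)
  d1 <- tempfile(); d2 <- tempfile()
  s1 <- simulate_snohost(cfg, d1)
  s2 <- simulate_snohost(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # different seed, different cosmos
  s3 <- simulate_snohost(synthetic_config(seed = 10, n_genes = 4,
                                          n_samples = 3), tempfile())
  expect_false(identical(readLines(s1$paths$fasta),
                         readLines(s3$paths$fasta)))
})

test_that("file-type substreams are independent of each other", {
  cfg <- synthetic_config(seed = 13, n_genes = 3, n_samples = 2)
  sim <- simulate_snohost(cfg, tempfile())
  # regenerating chimeras alone reproduces the cosmos's chimera file
  alone <- tempfile(fileext = ".tsv")
  generate_chimeras(cfg, sim$truth, alone)
  expect_identical(readLines(alone), readLines(sim$paths$chimeras))
})

test_that("ground truth is consistent with the emitted chimeras", {
  cfg <- synthetic_config(seed = 14, n_genes = 6, noise_chimeras = 0L)
  sim <- simulate_snohost(cfg, tempfile())
  reads <- load_chimeras(sim$paths$chimeras)
  # every planted interaction's support equals its emitted read count
  for (i in seq_len(nrow(sim$truth$planted))) {
    pl <- sim$truth$planted[i, ]
    s <- sim$truth$snornas[sim$truth$snornas$sno_id == pl$sno_id, ]
    in_sno <- (reads$start1 >= s$chunk_start & reads$end1 <= s$chunk_end) |
      (reads$start2 >= s$chunk_start & reads$end2 <= s$chunk_end)
    expect_equal(sum(in_sno), pl$support)
  }
  expect_equal(nrow(reads), sum(sim$truth$planted$support))
})

test_that("planted loci have the expected annotation geometry", {
  cfg <- synthetic_config(seed = 15, n_genes = 6)
  sim <- simulate_snohost(cfg, tempfile())
  ann <- parse_annotation(sim$paths$gtf)
  introns <- host_introns(ann)
  # every snoRNA is resolvable and contained in its host intron
  expect_setequal(introns$sno_id, sim$truth$snornas$sno_id)
  for (i in seq_len(nrow(introns))) {
    s <- ann$snornas[ann$snornas$sno_id == introns$sno_id[i], ]
    expect_true(introns$start[i] <= s$start && s$end <= introns$end[i])
  }
  # interacting genes: the cassette boundaries are the alternative sites
  g <- sim$truth$genes[sim$truth$genes$interacting, ][1, ]
  sites <- alternative_splice_sites(ann, g$gene_id)
  expect_setequal(sites$position, c(g$cassette_start, g$cassette_end))
  # and the planted target sequence is complementary to the snoRNA 3' end
  genome <- Biostrings::readDNAStringSet(sim$paths$fasta)
  pl <- sim$truth$planted[sim$truth$planted$gene_id == g$gene_id, ]
  sno <- ann$snornas[ann$snornas$sno_id == pl$sno_id, ]
  sno_seq <- chartr("T", "U", as.character(
    if (sno$strand == "-")
      Biostrings::reverseComplement(
        Biostrings::subseq(genome[[1]], sno$start + 1, sno$end))
    else Biostrings::subseq(genome[[1]], sno$start + 1, sno$end)))
  tgt_seq <- chartr("T", "U", as.character(
    if (sno$strand == "-")
      Biostrings::reverseComplement(
        Biostrings::subseq(genome[[1]], pl$target_start + 1, pl$target_end))
    else Biostrings::subseq(genome[[1]], pl$target_start + 1, pl$target_end)))
  d <- duplex_mfe(sno_seq, tgt_seq)
  expect_lt(d$mfe, -20)   # a fully complementary planted chunk
})

test_that("a single-gene, no-cassette configuration has no alternative sites", {
  cfg <- synthetic_config(seed = 16, n_genes = 1, fraction_interacting = 0,
                          extra_isoform_prob = 0, noise_chimeras = 0L)
  sim <- simulate_snohost(cfg, tempfile())
  ann <- parse_annotation(sim$paths$gtf)
  g <- ann$genes$gene_id[1]
  expect_equal(nrow(alternative_splice_sites(ann, g)), 0L)
  expect_equal(nrow(sim$truth$planted), 0L)
})

test_that("noise-only cosmoses yield no host-intron interactions", {
  fp <- 0L
  for (seed in 1:5) {
    cfg <- synthetic_config(seed = seed, n_genes = 5,
                            fraction_interacting = 0, noise_chimeras = 40L)
    sim <- simulate_snohost(cfg, tempfile())
    ann <- parse_annotation(sim$paths$gtf)
    out <- screen_interactions(ann, sim$paths$chimeras)
    fp <- fp + sum(out$category == "host_same_intron")
  }
  expect_equal(fp, 0L)
})

test_that("planted track signals are recovered from the emitted bedgraphs", {
  cfg <- synthetic_config(seed = 17, n_genes = 4, n_samples = 2,
                          extension_multipliers = c(1, 1))
  sim <- simulate_snohost(cfg, tempfile())
  cons <- read_track(sim$paths$conservation)
  pl <- sim$truth$planted[1, ]
  target <- genomic_interval(pl$chrom, pl$target_start, pl$target_end,
                             pl$strand)
  m_t <- as.numeric(mean_conservation(target, cons))
  expect_gt(m_t, 0.5)   # Beta(8,2) target against Beta(2,8) background
  s <- sim$truth$snornas[sim$truth$snornas$sno_id == pl$sno_id, ]
  g <- sim$truth$genes[sim$truth$genes$gene_id == pl$gene_id, ]
  background <- genomic_interval(pl$chrom, g$sno_intron_start,
                                 min(s$start, pl$target_start) - 5L)
  expect_lt(as.numeric(mean_conservation(background, cons)), 0.45)

  cov <- read_track(sim$paths$coverage[[1]])
  intron <- genomic_interval(pl$chrom, g$sno_intron_start, g$sno_intron_end)
  sno_iv <- genomic_interval(pl$chrom, s$start, s$end, s$strand)
  r <- extension_ratio(cov, sno_iv, target, intron)
  expect_gt(r, 3); expect_lt(r, 5)
})

test_that("self-read scenarios survive or fail the self filter as designed", {
  cfg <- synthetic_config(seed = 18, n_genes = 2, noise_chimeras = 0L,
                          self_read_scenarios = TRUE)
  sim <- simulate_snohost(cfg, tempfile())
  ann <- parse_annotation(sim$paths$gtf)
  reads <- load_chimeras(sim$paths$chimeras)
  kept <- filter_chimeras(reads, ann)
  n_planted <- nrow(sim$truth$planted)
  # per planted snoRNA: support reads + 1 surviving self read; the
  # both-arms-inside self read is discarded
  expect_equal(nrow(reads), n_planted * (cfg$reads_per_interaction + 2L))
  expect_equal(nrow(kept), n_planted * (cfg$reads_per_interaction + 1L))
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(), "seed")
  expect_error(synthetic_config(seed = 1, target_length = c(10, 12)), "17")
  expect_error(synthetic_config(seed = 1, n_samples = 3,
                                extension_multipliers = c(1, 2)), "not TRUE")
})
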