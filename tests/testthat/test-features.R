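test_that("mean conservation averages over the region, missing bases as zero", {
  track <- make_track(100, 120, 1.0)   # 20 nt all scored 1.0
  region <- genomic_interval("chr1", 100, 120)
  expect_equal(as.numeric(mean_conservation(region, track)), 1.0)

  track2 <- make_track(c(100, 105), c(105, 110), c(1.0, 0.0))
  expect_equal(as.numeric(mean_conservation(genomic_interval("chr1", 100, 110),
                                            track2)), 0.5)

  # 5 positions at 0.8, 5 missing
  track3 <- make_track(100, 105, 0.8)
  m <- mean_conservation(genomic_interval("chr1", 100, 110), track3)
  expect_equal(as.numeric(m), 0.4)
  expect_equal(attr(m, "missing_bases"), 5)

  # unknown chromosome: all missing, mean 0
  expect_equal(as.numeric(mean_conservation(genomic_interval("chrZ", 0, 10),
                                            track)), 0)
})

test_that("matched negatives mirror the target across the snoRNA", {
  intron <- genomic_interval("chr1", 1000, 2000)
  sno <- genomic_interval("chr1", 1400, 1500)
  # 40 nt target starting 30 nt after the snoRNA end
  target <- genomic_interval("chr1", 1530, 1570)
  neg <- matched_negative(target, sno, intron)
  expect_equal(c(neg$start, neg$end), c(1330, 1370))  # ends 30 nt before sno

  # zero distance: the negative abuts the opposite boundary
  t0 <- genomic_interval("chr1", 1500, 1540)
  n0 <- matched_negative(t0, sno, intron)
  expect_equal(n0$end, 1400)

  # mirrored interval exits the intron: none
  t_far <- genomic_interval("chr1", 1950, 1990)  # 450 nt from the boundary
  expect_null(matched_negative(t_far, sno, intron))

  # target overlapping the snoRNA is an error
  expect_error(matched_negative(genomic_interval("chr1", 1480, 1520),
                                sno, intron), "overlaps")

  # involution: mirroring the mirror returns the original
  for (gap in c(0, 10, 55)) {
    for (len in c(20, 40)) {
      tg <- genomic_interval("chr1", 1500 + gap, 1500 + gap + len)
      ng <- matched_negative(tg, sno, intron)
      back <- matched_negative(ng, sno, intron)
      expect_equal(c(back$start, back$end), c(tg$start, tg$end))
    }
  }
})

test_that("negative-region sampling is deterministic and stays in the flanks", {
  ann <- make_ann()
  introns <- host_introns(ann)
  snos <- ann$snornas[ann$snornas$sno_id %in% introns$sno_id, ]
  regs <- sample_negative_regions(snos, introns, lengths = c(10, 15), n = 50,
                                  seed = 99)
  regs2 <- sample_negative_regions(snos, introns, lengths = c(10, 15), n = 50,
                                   seed = 99)
  expect_identical(regs, regs2)
  expect_equal(nrow(regs), 50L)
  for (i in seq_len(nrow(regs))) {
    hi <- introns[introns$sno_id == regs$sno_id[i], ]
    s <- snos[snos$sno_id == regs$sno_id[i], ]
    expect_true(hi$start <= regs$start[i] && regs$end[i] <= hi$end)
    overlaps_sno <- min(regs$end[i], s$end) - max(regs$start[i], s$start) > 0
    expect_false(overlaps_sno)
  }
  expect_equal(nrow(sample_negative_regions(snos, introns, c(10), 0)), 0L)

  # flank exactly equal to the drawn length: the unique possible interval
  one_sno <- snos[snos$sno_id == "SNOA", ]   # intron [400,500), sno [420,480)
  one_introns <- introns[introns$sno_id == "SNOA", ]
  regs3 <- sample_negative_regions(one_sno, one_introns, lengths = 20L,
                                   n = 20, seed = 1)
  expect_true(all((regs3$start == 400 & regs3$end == 420) |
                    (regs3$start == 480 & regs3$end == 500)))
})

test_that("the conservation bootstrap behaves at its extremes", {
  expect_error(conservation_bootstrap(numeric(0), c(0.1)), "non-empty")
  # perfectly separated groups: observed 1.0 can never be reached by the null
  r <- conservation_bootstrap(rep(0.9, 20), rep(0.1, 40), n_boot = 1000,
                              seed = 3)
  expect_equal(r$p_value, 1 / 1001)
  expect_equal(r$proportion_target, 1)
  expect_equal(r$proportion_negative, 0)
  # all targets below the threshold: observed 0 is never exceeded, p = 1
  r2 <- conservation_bootstrap(rep(0.1, 20), runif(40), n_boot = 200, seed = 3)
  expect_equal(r2$p_value, 1)
  # deterministic given seed
  set.seed(77); t <- runif(10); n <- runif(30)
  a <- conservation_bootstrap(t, n, seed = 5)
  b <- conservation_bootstrap(t, n, seed = 5)
  expect_identical(a, b)
  expect_equal(a$n_boot, 1000)
})

test_that("planted conservation contrast is detected with high confidence", {
  # targets ~ Beta(8,2) vs negatives ~ Beta(2,8), 30 regions each
  set.seed(31)
  hits <- sum(replicate(20, {
    t <- rbeta(30, 8, 2); n <- rbeta(60, 2, 8)
    conservation_bootstrap(t, n, n_boot = 1000)$p_value <= 0.01
  }))
  expect_gte(hits, 19)
})

test_that("extension ratio follows its contract", {
  intron <- genomic_interval("chr1", 0, 500)
  sno <- genomic_interval("chr1", 100, 200)
  target <- genomic_interval("chr1", 230, 270)
  # uniform 10x in the window [202, 270), 5x elsewhere in the intron
  tr <- make_track(c(0, 202, 270), c(202, 270, 500), c(5, 10, 5))
  r <- extension_ratio(tr, sno, target, intron)
  num <- 10
  den <- (5 * 202 + 5 * 230 - 5 * 100) / (500 - 100 - 68)
  expect_equal(r, num / den)
  expect_equal(r, 2, tolerance = 1e-9)   # exactly 2: NOT a positive call
  expect_false(isTRUE(r > 2))

  # zero coverage outside the window: +infinity
  tr2 <- make_track(202, 270, 7)
  expect_equal(extension_ratio(tr2, sno, target, intron), Inf)

  # whole intron silent: none
  tr3 <- make_track(600, 700, 3)
  expect_true(is.na(extension_ratio(tr3, sno, target, intron)))

  # multiplying the whole track by a constant leaves the ratio unchanged
  tr4 <- make_track(c(0, 202, 270), c(202, 270, 500), 13 * c(5, 10, 5))
  expect_equal(extension_ratio(tr4, sno, target, intron), r)

  # window collapsed to nothing: none, with a warning
  t_close <- genomic_interval("chr1", 200, 201)
  expect_warning(out <- extension_ratio(tr, sno, t_close, intron), "window")
  expect_true(is.na(out))

  # upstream interactions mirror the window to the 5' side
  t_up <- genomic_interval("chr1", 40, 80)
  tr5 <- make_track(c(0, 40, 98), c(40, 98, 500), c(5, 10, 5))
  expect_gt(extension_ratio(tr5, sno, t_up, intron), 1.9)
})

test_that("branch points: best per intron, half-open overlap", {
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(intron_id = c("i1", "i1", "i2"),
                         chrom = "chr1", position = c(1550, 1600, 9000),
                         score = c(0.9, 0.4, 0.7)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  bp <- read_branch_points(path)
  expect_equal(nrow(bp), 2L)
  expect_equal(bp$position[bp$intron_id == "i1"], 1550)

  target <- genomic_interval("chr1", 1500, 1600)
  expect_true(bp_overlap(target, bp[bp$intron_id == "i1", ]))
  expect_false(bp_overlap(target, data.frame(chrom = "chr1", position = 1600)))
  expect_false(bp_overlap(target, NULL))
})

test_that("evidence classification applies the five strict thresholds", {
  fv <- data.frame(support = 36, duplex_mfe = -5.76, mean_conservation = 0.9,
                   splice_distance = 120, extension_ratio = 3.5)
  ev <- classify_evidence(fv)
  expect_equal(ev$evidence_count, 5L)

  # support must strictly exceed 3
  fv$support <- 3
  expect_equal(classify_evidence(fv)$evidence_count, 4L)
  expect_false(classify_evidence(fv)$pls_support)

  # boundary values all fail their strict thresholds
  fv2 <- data.frame(support = 3, duplex_mfe = 0, mean_conservation = 0.2,
                    splice_distance = 150, extension_ratio = 2)
  expect_equal(classify_evidence(fv2)$evidence_count, 0L)

  # missing values fail their criterion
  fv3 <- data.frame(support = 0, duplex_mfe = 0, mean_conservation = 0,
                    splice_distance = NA, extension_ratio = NA)
  expect_equal(classify_evidence(fv3)$evidence_count, 0L)

  # an infinite ratio is a positive extension call
  fv4 <- fv; fv4$extension_ratio <- Inf
  expect_true(classify_evidence(fv4)$extension)
})

test_that("evidence counts are monotone in each feature", {
  set.seed(41)
  base <- data.frame(support = sample(0:10, 50, TRUE),
                     duplex_mfe = round(runif(50, -10, 2), 2),
                     mean_conservation = round(runif(50), 2),
                     splice_distance = sample(c(0:400, NA), 50, TRUE),
                     extension_ratio = round(runif(50, 0, 5), 2))
  e0 <- classify_evidence(base)$evidence_count
  better <- base
  better$support <- base$support + sample(0:5, 50, TRUE)
  better$duplex_mfe <- base$duplex_mfe - runif(50, 0, 3)
  better$mean_conservation <- pmin(1, base$mean_conservation + runif(50, 0, .3))
  better$splice_distance <- pmax(0, base$splice_distance - sample(0:100, 50, TRUE))
  better$extension_ratio <- base$extension_ratio + runif(50, 0, 2)
  e1 <- classify_evidence(better)$evidence_count
  expect_true(all(e1 >= e0))
})
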