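# snohost

Screening snoRNA–host intron interactions from chimeric duplex reads.

## The problem

Intronic snoRNAs depend on their host gene's splicing for biogenesis, but the
relationship can run the other way too: a snoRNA that base-pairs *in cis*
with its own host intron can sequester the branch point of the neighbouring
alternative exon and thereby repress its inclusion. The tell-tale signals
are: chimeric reads from RNA–RNA interaction protocols (PARIS, LIGR-seq,
SPLASH) joining the snoRNA to its flanking intronic sequence; unexpected
sequence conservation of that intronic target; a thermodynamically stable
snoRNA–target duplex; accumulation of an "extended" snoRNA species covering
the target in structure-tolerant RNA-seq coverage; and a negative
correlation between that extension's abundance and the percent-spliced-in
(PSI) of the adjacent cassette exon across samples.

`snohost` is for computational RNA biologists who want to run this screen on
interval-level inputs (GTF + FASTA + chimera/junction/coverage tables) or to
study its statistical behaviour on fully synthetic loci with planted ground
truth.

## The method

1. **Host-intron resolution.** For each snoRNA, the same-strand containing
   gene; among its protein-coding transcripts where the snoRNA is entirely
   intronic, the lowest-numbered (Ensembl `-201` style) transcript's intron.
2. **Chimera screen.** Reads filtered (arm length ≥ 9 nt, a snoRNA arm, no
   intergenic arm, self-reads must extend ≥ 10 nt past the snoRNA), then
   merged by single-linkage whenever left arms *and* right arms overlap,
   support summed: an interaction with support
   *s* = Σ reads, categorised as `host_same_intron` / `host_other` /
   `other_gene`.
3. **Evidence matrix.** Five strict flags per host-intron interaction —
   support > 3; duplex MFE < 0 kcal/mol (reduced nearest-neighbour dynamic
   programme, exact optimum); mean conservation > 0.2 (with matched mirrored
   negatives and a 1000-resample bootstrap on the proportion of regions
   ≥ 0.5); distance to the closest alternative splice site < 150 nt;
   extension ratio > 2, where
   ratio = mean cov(snoRNA boundary + 2 nt … interaction end) /
   mean cov(rest of intron).
4. **Splicing.** PSI = inclusion / (inclusion + skip) per sample from
   junction tables, and Pearson correlation of depth-normalised extension
   abundance against PSI.

A deterministic generator (`simulate_snohost()`) emits genome, GTF, chimera,
conservation, coverage, depth, junction and branch-point files with planted
interactions, so the whole pipeline is testable without any download.

## Worked example

```r
library(snohost)

cfg <- synthetic_config(seed = 42, n_genes = 6, n_samples = 4,
                        extension_multipliers = c(0.8, 1, 1.4, 2))
sim <- simulate_snohost(cfg, tempfile())
scr <- snohost_screen(gtf = sim$paths$gtf, genome = sim$paths$fasta,
                      chimeras = sim$paths$chimeras,
                      conservation = sim$paths$conservation,
                      coverage = sim$paths$coverage, depths = sim$paths$depths,
                      junctions = sim$paths$junctions,
                      exon_overlaps = sim$paths$exon_overlaps,
                      branch_points = sim$paths$branch_points)
print(scr)
#> snoRNA-host interaction screen
#>   snoRNAs in registry:        6
#>   with resolvable host intron: 6
#>   merged interactions:        4
#>     host_same_intron: 3
#>     other_gene: 1
#>   host-intron interactions scored: 3
#>   evidence count per snoRNA (best interaction):
#>  5
#>  3
```

Three of the six snoRNAs were planted as interacting, and all three come back
with the full five evidence flags (60 noise chimeras produced one stray
`other_gene` interaction and no false host-intron calls):

```r
scr$evidence_by_sno[, c("sno_id", "support", "splice_distance",
                        "mean_conservation", "duplex_mfe",
                        "extension_ratio", "evidence_count")]
#>   sno_id support splice_distance mean_conservation duplex_mfe extension_ratio evidence_count
#> 1  SNO01       6              93         0.7858917        -67        7.653599              5
#> 2  SNO02       6              90         0.7928867        -50        7.257934              5
#> 3  SNO03       6             109         0.8010788        -64        7.072778              5
```

Support 6 exceeds the > 3 cutoff; the planted targets are reverse complements
of the snoRNA 3' ends, hence the strongly negative duplex energies; the
cassette exon sits ~100 nt away (< 150); conservation ~0.79 reflects the
planted Beta(8,2) contrast; and the extension window runs ~7× hotter than
the rest of the intron (> 2). Extension abundance is negatively coupled to
cassette PSI across the four samples:

```r
scr$correlations
#>   sno_id gene_id n          r     p_value constant
#> 1  SNO01  GENE01 4 -0.9938955 0.006104535    FALSE
#> 2  SNO02  GENE02 4 -0.9972411 0.002758916    FALSE
#> 3  SNO03  GENE03 4 -0.9909371 0.009062851    FALSE
```

The energetics are directly accessible too:

```r
duplex_mfe("GGGG", "CCCC")$mfe   # 4 GC pairs, 3 GC/GC stacks: 4 + 3*(-3)
#> [1] -5
fold_mfe("GGGAAACCC")            # hairpin with two GC/GC stacks
#> [1] -6
```

See `vignettes/snohost-methods.Rmd` for the models, thresholds, the
synthetic-cosmos design and its limitations.

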