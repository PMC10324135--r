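---
title: "Screening snoRNA-host intron interactions: models and methods"
author: "snohost"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening snoRNA-host intron interactions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snohost)
```

## The biological question

Most box C/D and H/ACA snoRNAs are encoded inside introns of a longer host
gene and are released by splicing. Beyond this biogenetic dependence, a
snoRNA can base-pair *in cis* with its own host intron: if the duplex covers
the branch point or other splicing signals of the neighbouring alternative
exon, the snoRNA sequence itself becomes a splicing regulator of its host
transcript. The canonical example is a box C/D snoRNA whose 3' end pairs with
the downstream intronic region that harbours the branch point of the adjacent
cassette exon; accumulation of the extended snoRNA-intron species then
correlates negatively with inclusion of that exon, shifting the host mRNA
toward a nonsense-mediated-decay-sensitive isoform.

`snohost` implements a desk-scale screen for such interactions. The raw
evidence unit is the *chimeric read* from proximity-ligation RNA-RNA
interaction protocols (PARIS, LIGR-seq, SPLASH): a read whose two arms map to
two genomic regions, witnessing a duplex. The screen filters and merges these
reads, resolves each snoRNA's host intron, and scores five orthogonal lines
of evidence per interaction.

## The screen, step by step

### Host-intron resolution

For each snoRNA the host gene is the same-strand gene whose span contains it
(the smallest such span if nested genes overlap). Among the host gene's
protein-coding transcripts in which the snoRNA lies entirely within one
intron, the transcript with the smallest Ensembl name number (the `-201`
style suffix, usually the main isoform) is chosen and its intron taken as the
host intron. snoRNAs on the opposite strand of their containing gene, not
intronic in any protein-coding transcript, or overlapping an exon in every
transcript are excluded. Transcripts without a numeric suffix sort after all
numbered ones (tie-broken lexicographically); whether such transcripts should
ever win is genuinely open, and this ordering is our choice.

### Chimeric-read filtering

A read is retained when (i) both arms are at least 9 nt long, (ii) at least
one arm overlaps a snoRNA on its strand, (iii) neither arm is intergenic, and
(iv) for reads whose two arms overlap the *same* snoRNA, at least one arm
extends at least 10 nt beyond a snoRNA boundary — otherwise the "interaction"
is indistinguishable from the snoRNA's internal structure. The self-read rule
admits several quantifier readings; we read it as "discard unless both arms
are >= 9 nt and >= 1 arm extends >= 10 nt outside", which keeps exactly the
reads that carry information about flanking intronic sequence. Both
thresholds are exposed (`min_arm_len`, `self_extension`).

### Merging and support

Reads are merged whenever their left arms overlap by >= 1 nt *and* their
right arms overlap by >= 1 nt (same chromosome and strand per arm).
Single-linkage transitive clustering is used: pairwise greedy merging would
be order-dependent, which we reject. Support is the sum of member supports
and datasets accumulate as a union. As the cluster representative we keep the
arms of the member with the largest total overlap against the rest of the
cluster (ties: longer arms, then smaller left start), and we record the
cluster-wide arm-span union alongside, so downstream features can use either;
the interaction region used by the feature stage is the span union by
default. The merge is a fixed point (merging its output changes nothing) and
order-independent, and total support is conserved — all three are tested
properties, with a brute-force transitive-closure oracle as the reference.

### Categories and orientation

Each merged interaction is assigned to the snoRNA overlapped by one arm (one
output per snoRNA if the two arms hit two different snoRNAs; for self-reads
the more-snoRNA-internal arm is the snoRNA arm). The target arm is
`host_same_intron` when contained in the host intron, `host_other` when
elsewhere in the host gene span, `other_gene` otherwise; arms on another
strand or chromosome can only be `other_gene`. Orientation compares the
target midpoint with the snoRNA span, strand-aware.

## The five evidence features

Only `host_same_intron` interactions are scored. Thresholds follow the
evidence matrix conventions, all strict:

| flag | feature | threshold |
|---|---|---|
| `pls_support` | merged chimeric-read support | > 3 reads |
| `stable_structure` | duplex MFE of snoRNA vs target region | < 0 kcal/mol |
| `conservation` | mean per-base conservation of the target | > 0.2 |
| `ase_proximity` | distance to closest alternative splice site | < 150 nt |
| `extension` | extension coverage ratio | > 2 |

Missing values fail their criterion; `evidence_count` is the number of
satisfied flags, and the classifier is monotone in every feature (tested).
An ambiguity worth noting: "stable structure" could be read as the
intermolecular duplex MFE or the per-nucleotide fold MFE; we use the duplex
MFE (the phrase "energy of the interaction duplex" points there) and also
report `mfe_per_nt` so the other reading remains available.

**Alternative splice sites.** A boundary position (with a donor/acceptor side
label) counts as alternative when used by at least one but not all isoforms
of the host gene — the comparison universe is the whole-gene isoform set, the
simplest faithful reading; transcript-terminal boundaries are not splice
sites and never count. The distance is the minimum over sites of the distance
to the nearer snoRNA boundary, 0 when a site falls inside the snoRNA.
Isoforms of all biotypes contribute sites; restricting to protein-coding
isoforms is a defensible alternative we did not take, since splice sites are
shared gene-level features.

**Conservation.** Mean per-base score over the target region, missing
positions scoring 0 (the missing count is attached as an attribute, since gap
conventions differ between score tracks). Two complementary controls are
implemented: (a) *matched negatives* — an interval of the target's length
mirrored to the opposite side of the snoRNA at the same boundary distance
(an involution, tested), used for the duplex-energy contrast; (b) *sampled
negatives* — regions drawn in the intronic flanks of non-interacting
snoRNAs, lengths resampled from the target length distribution, drawn 10
times independently to report the spread of the negative statistic. The
significance of "proportion of regions with mean score >= 0.5" uses a
bootstrap: the null resamples the negatives (sample size = number of
targets) 1000 times, and the p-value is add-one, `p = (1 + #(null >=
obs)) / (n_boot + 1)`, so p = 0 is impossible.

The calibration test for the bootstrap draws region scores uniformly on
[0, 1] with 100 regions per group. Uniform scores are the right null here:
with a realistic conserved/background contrast the proportion-above-0.5
statistic is degenerate (almost surely 0), so only a score distribution
straddling the threshold can probe the p-value's uniformity; 100 regions
match the scale of a transcriptome-wide screen's interaction set. The
statistic takes at most 101 values, so exact uniformity is impossible — the
test asserts uniformity to within that discreteness (fraction of p <= 0.05
within [0.03, 0.07], Kolmogorov-Smirnov distance < 0.08 at 500 replicates).

**Duplex and fold energetics.** The screen's comparative statements (target
vs matched negative, snoRNA-intron fold vs mature fold) need an energy model,
not any particular published parameterisation. We therefore ship a reduced
nearest-neighbour model whose every optimum is hand-checkable:

* pair kinds GC, AU, GU; stacks `GC/GC = -3`, `GC/AU = -2`, `AU/AU = -1`,
  anything involving GU `= -0.5` kcal/mol; helix initiation `+4`;
  interior-loop penalty `+0.5`/unpaired nt (duplex model only).
* `duplex_mfe()` solves the co-linear antiparallel pairing problem exactly in
  O(nm) (a corner-minimum recurrence handles arbitrary interior loops);
  unfavourable optima are clamped to 0 = "no interaction", which is what
  makes the `< 0` evidence threshold meaningful.
* `fold_mfe()` solves the nested-structure problem (no pseudoknots, minimum
  hairpin loop 3 nt, stacking energy only, isolated pairs free) exactly in
  O(n^3), in C++; sequences are truncated to their first 1000 nt and
  `mfe_per_nt()` divides by the (post-truncation) length to remove the
  length bias when comparing spans of different size.
* `enumerate_oracle()` recomputes both optima by exhaustive enumeration with
  standalone scorers for instances up to 14 nt total; the test suite checks
  DP = enumeration on 2000 random instances.

An external thermodynamic predictor can be substituted behind the same
signatures (sequences in, energy and pairing out); published duplex energies
are only reproducible through such an adapter, not by the built-in table.
The intramolecular span folded per interaction runs from the snoRNA through
the interaction-side remainder of the intron.

**Extension ratio.** Mean coverage from the snoRNA boundary facing the
interaction (+2 nt, so mature snoRNA reads are not counted) to the
interaction end, divided by mean coverage of the rest of the intron (intron
minus snoRNA minus the window). By contract the ratio is `Inf` when only the
window is covered, `NA` when the intron is silent or the window is empty,
and scale-invariant in the track. With several coverage samples the feature
takes the maximum per-sample ratio: an extension present in any tissue or
cell line counts, mirroring how tissue-specific accumulation is read.

**Branch points.** Branch points are consumed from a table (no prediction is
performed); only the top-scoring candidate per intron is used, and overlap is
half-open containment of the point in the target region. `bp_overlap` is
reported alongside the five flags but is not part of the evidence count.

## PSI and coupling to extension abundance

For a cassette exon, PSI = inclusion / (inclusion + skip), where inclusion
counts reads overlapping the exon by >= 1 nt and skip counts junction reads
joining exactly the upstream exon's end to the downstream exon's start.
Evidence is consumed from junction-count and exon-overlap tables (an
alignment-level reader is deliberately out of scope, keeping the module
format-light); a read matching the skip junction is never double-counted as
inclusion. Region abundances are normalised by the sample's total mapped
reads. Pearson correlation (with its two-sided test) relates per-sample
extension abundance to per-sample PSI; samples are aligned by identifier,
never by position, constant vectors are flagged rather than raised, and no
multiple-testing correction is applied since correlations are reported per
locus.

## The synthetic cosmos

`synthetic_config()` fixes the study conditions used by the test suite; they
are not tuning knobs. Defaults: 20 genes of 4-6 exons (90-180 nt) with
introns of 250-450 nt, one snoRNA (70-110 nt) per gene, 50% of snoRNAs
interacting, 6 chimeric reads per planted interaction spread over the 11
PARIS/LIGR-seq/SPLASH-style dataset labels, 60 noise chimeras (15% of noise
arms under 9 nt, random positions including intergenic space), conservation
Beta(8, 2) inside target regions against Beta(2, 8) background, intron
background coverage 10 reads/base with Poisson noise, a planted extension
ratio of 4, 12 samples whose extended-species abundance multiplier spans
0.5-2 with PSI coupled at slope -0.5 per multiplier unit around a baseline
of 0.5, and 200 splicing evidence reads per sample at a nominal depth of
1e5 (jittered 20% per sample). Within the snoRNA's intron the geometry
mirrors the canonical cassette-exon arrangement: 100-250 nt of upstream
intron (hosting matched negatives), then the snoRNA, a 20-40 nt gap, a
25-40 nt target region planted as the exact reverse complement of the
snoRNA's 3' chunk, and a 20-40 nt tail before the 3' splice site, with the
adjacent downstream exon made a cassette (skipped by a second protein-coding
isoform). The planted branch point sits 25 nt from the intron's 3' splice
site, so it falls inside the target region only when the tail is short —
branch-point overlap is deliberately not guaranteed.

Determinism: one root seed with named substreams per file type (locus,
chimeras, tracks, junctions, branch points), so regenerating one file type
never perturbs another and identical configurations give byte-identical
files (both tested). Tracks are emitted per-base over the snoRNA-hosting
introns only — the only regions any estimator reads.

What the generator does *not* emulate: read-level sequencing error,
alignment ambiguity, transcriptome-wide background interactions (noise arms
are uniform, not expression-weighted), overdispersed coverage (Poisson
only), paired-end fragment structure, or multi-isoform quantification.
Passing tests therefore demonstrate correctness of the screen's logic and
statistics under its stated model, not performance on real libraries, where
chimera false-positive structure and coverage dispersion are harsher.

Problem sizes in the test suite are chosen to keep the full run within a few
minutes: the end-to-end check uses the default 20-gene cosmos over 10 seeds,
recovery checks use 2-gene cosmoses over 100-200 seeds, oracle equivalences
use 1000 random instances each, and the bootstrap calibration uses 500
replicates at 1000 resamples.

## Numerical choices and degenerate inputs

* Internal coordinates are 0-based half-open everywhere; GTF converts at the
  I/O boundary, BED/bedGraph are native. This removes a whole class of
  off-by-one errors and makes "distance" unambiguous
  (`|site - boundary|` between point coordinates, containment = 0).
* Merging ties are broken deterministically (overlap, then arm length, then
  left start), so output is independent of input order.
* `compute_psi(0, 0)`, an empty extension window, a silent intron, an empty
  alternative-site set, and a constant correlation vector all yield `NA` (or
  a flag) rather than errors; the classifier treats `NA` as a failed
  criterion.
* The duplex DP clamps at 0 rather than reporting positive energies, and the
  fold DP's empty structure guarantees results <= 0.
* Bootstrap and all generators accept explicit seeds and restore the
  caller's RNG state.

## Known limitations

* The reduced energy table preserves comparative logic (complementary
  targets score far below random matched negatives) but its absolute
  kcal/mol values are not thermodynamic measurements.
* Decoy snoRNAs without any detected host-intron interaction receive an
  evidence count of 0 by construction; the evidence matrix, as in the
  original screen design, is defined over detected interactions only.
* Trans interactions (arms on different chromosomes or strands) are carried
  through as `other_gene` but not further characterised.
* The whole-gene isoform universe for alternative splice sites can call a
  boundary "alternative" merely because a short isoform does not reach it.
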