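---
title: "Methods behind musakit: genome size, SSR distances and ITS pseudogene calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind musakit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musakit)
```

`musakit` packages the three assays used to characterize wild banana
accessions — flow-cytometric genome sizing, microsatellite genotyping, and
ITS ribosomal-DNA analysis — together with simulators that generate each
kind of input with known ground truth. This vignette explains the models and
procedures, the tunable parameters and their defaults, the numerical
choices, and what the simulators do and do not emulate.

## Genome size from flow cytometry

A chopped leaf preparation contains nuclei of the sample and of a co-chopped
internal standard; the histogram of relative fluorescence therefore shows
two dominant G1 peaks. The physical model is linear: fluorescence is
proportional to DNA amount, so

$$2C_\text{sample} = 2C_\text{standard}\cdot
  \frac{\text{G1 peak mean}_\text{sample}}{\text{G1 peak mean}_\text{standard}},$$

with soybean (2C = 2.5 pg) as the default standard. The monoploid genome
size is $1C_x = 2C/2 \times 978$ Mbp (1 pg = 0.978·10⁹ bp), rounded half-up
to an integer as genome-size tables print it.

**Peak detection** (`detectG1Peaks`) smooths the histogram with a moving
average (default width 5 bins), finds local maxima above a noise floor
(default 5% of the tallest smoothed bin, minimum apex separation twice the
smoothing window), and fits a Gaussian by least squares in a window of ±3
half-widths-at-half-height around each apex (Levenberg–Marquardt, with a
moment-based fallback if the fit fails). The instrument software used for
the original measurements is proprietary and its peak statistic is not
documented; a smoothed-maximum-plus-Gaussian-fit is the conventional
transparent choice. Degenerate inputs fail loudly: an all-zero histogram is
invalid input, and fewer resolvable maxima than requested peaks is a
"peaks unresolved" error rather than a guess.

**Replicate structure.** `aggregateReplicates` averages each plant's repeat
measurements first and takes the accession mean and SD across plant means,
matching the three-plants × three-days design. A single plant yields SD 0
rather than NA, so downstream code never branches on missingness.

**Group comparison.** `bonferroniLetterGroups` fits a one-way ANOVA, tests
all pairs with pooled-error t statistics at the Bonferroni-adjusted level
$\alpha/\binom{k}{2}$ (two-sided, default familywise $\alpha = 0.01$), and
summarizes the result as a compact letter display via insert-and-absorb:
start with one letter covering everything; for each significant pair, split
every letter containing both members; absorb letters that became subsets.
Letters are ordered by ascending group mean. The display is exact by
construction: two accessions share a letter if and only if their pairwise
test is non-significant, and the test matrix is attached for inspection.

**Reconstructing replicates from summaries.** When only means and SDs are
printed, `reconstructReplicates` builds the deterministic symmetric pattern
$m + s\,a\,(-1,0,1,\dots)$ whose sample mean is exactly $m$ and sample SD
exactly $s$ (the triplet $\{m-s, m, m+s\}$ for $n=3$). This is a surrogate,
not data: two accessions' real measurement clouds can overlap differently
than their symmetric reconstructions do. On the shipped 21-accession table
the triplet reconstruction yields fewer letter groups than the published
twelve, and no uniform critical difference reproduces the published letters
exactly (the printed letters separate one pair at a mean difference of
0.025 pg while grouping another at 0.026 pg); the published grouping
evidently reflects the raw per-plant data, which are not printed. The
package therefore reports what the reconstruction computes and documents
the discrepancy rather than tuning toward the published count.

**Correlation.** `spearmanR` uses average ranks for ties (chromosome
numbers have only three levels here, so the tie policy matters) and is
checked in the tests against a brute-force rank-then-Pearson oracle at
1e-12. Accessions without a chromosome count enter the shipped analysis at
their sectional 2n (20 for non-*beccarii* Callimusa), which is what
reproduces the published correlation.

## SSR distances and UPGMA

Allele calls are sets of fragment sizes per locus. A single observed size is
treated as homozygous (standard SSR scoring convention), so per-accession
allele frequencies at a locus are 1 or 1/2. `binarize` produces the
presence/absence matrix with one column per observed (locus, size) pair;
unscored loci become zero blocks and are recorded.

`neiDistance` implements Nei's (1972) standard distance with the identity
terms $J_x$, $J_y$, $J_{xy}$ averaged over the loci scored in *both*
accessions (pairwise deletion). Two profiles sharing no allele anywhere have
$J_{xy}=0$ and infinite distance; the distance is capped (default 10, with
a warning) so clustering stays computable — the cap only needs to exceed
every finite distance in the panel. The shared-band Dice-complement
coefficient is available as `method = "dice"` since genotyping pipelines
differ in which coefficient they report.

`upgmaTree` delegates to size-weighted average-linkage clustering
(`hclust`/`phangorn`), producing an ultrametric tree; tie-breaking follows
the deterministic lowest-index convention of the underlying implementation,
so results are reproducible. `writeNewick` single-quotes labels containing
newick-reserved characters and round-trips through `readNewick`.

## ITS annotation and pseudogene classification

**Region delineation.** The 5.8S gene is located by semi-global alignment
of a reference 5.8S against the clone sequence (match +1, mismatch −1, gap
open 1, gap extend 1), accepted at ≥ 70% reference identity. Gap penalties
are deliberately below the cost of two mismatches so that short internal
deletions appear as gaps; the located span is then refined through a global
alignment to the reference, which also flags deletion-bearing copies
(internal reference positions lost). ITS1 is everything upstream, ITS2
everything downstream, optionally trimmed at 18S/26S anchor sequences.

**Reference sequences.** The literature source for the three conserved 5.8S
motifs does not print them alongside the feature table, so the package
ships the conserved angiosperm motif set M1 `CGATGAAGAACGCAGC`, M2
`GAATTGCAGAATCC`, M3 `TTTGAACGCA` as replaceable defaults — their lengths
are consistent with the `nt-14`/`nt-16` change positions the feature table
reports. The reference 5.8S itself is a synthetic 155-nt construct
embedding these motifs in fixed filler sequence; it is configuration, not a
biological claim, and any real 5.8S containing the motifs can be supplied
in its place.

**Motif scanning** reads each motif's reference positions through the
global alignment and reports substitutions in the table notation
(`nt-9 'A'`, 1-based within the motif) and deletions as ranges
(`nt1-nt3 'deletion'`). A motif with at least half its positions deleted is
`not present-deletion` and contributes its full length to the change count.

**Folding.** The built-in structure backend is deterministic base-pair
maximization (Nussinov dynamic programming, Rcpp) with Watson–Crick and
G·U/G·T pairs and a minimum hairpin loop of 3. Helices are maximal
unbranched chains of pairs containing ≥ 3 stacked pairs. The ITS2 counts as
*formed* when the fold has exactly four helices, each ending in its own
hairpin loop (a ≥ 3-stack closing a multiloop disqualifies the fold), with
mutually disjoint outer intervals — isolated pairs that maximization tends
to sprinkle between helices are not treated as topology. The canonical
landmarks are verified on the fold: a pyrimidine-pyrimidine internal
loop/mismatch in helix II and `TGGT` on the 5′ strand of helix III. The
5.8S counts as formed when ≥ 70% of the reference fold's base pairs are
recovered at alignment-mapped positions. Base-pair maximization is not a
thermodynamic model; "formed" is a topology test, not a free-energy claim,
and an MFE backend can be substituted by supplying a function with the same
return shape.

**Pseudogene rule.** A type is a putative pseudogene when any of: ITS2 not
formed; 5.8S not formed; 5.8S GC below `gcFloor`; or at least
`changesFloor` changed motif positions across M1–M3. The thresholds
(defaults `gcFloor = 48`, `changesFloor = 5`) were calibrated once against
the shipped 51-row feature table: types with three or even four motif
changes and intact structures are *not* labelled pseudogenes there, and a
type with 5.8S GC of 48.95% is unlabelled while labelled types reach down
to 46–49%. With these defaults the classifier reproduces the published
note column for 49 of 51 rows; the two disagreements are a row pair whose
printed features and labels are mutually inconsistent (one labelled
pseudogene with intact structures, its sibling unlabelled with a collapsed
ITS2 and 46.45% GC) and are documented as unresolvable rather than fitted.

**Types, diversity, trees.** Clone reads collapse into types by
single-linkage clustering at ≥ 99% pairwise identity (global alignment); a
cluster is summarized by the column-wise majority consensus over its reads
of the most common length, which removes sporadic sequencing errors at the
default 0.1% error rate. The published work does not state its collapse
criterion; 99% single-linkage merges singleton reads one error away from a
cluster while keeping planted variants apart, and is configurable.
Nucleotide diversity is the average pairwise proportion of differing sites
with pairwise deletion of gaps and ambiguities; segregating sites count
columns with ≥ 2 unambiguous states; haplotypes are exact-match groups.
Distances for phylogenetics are Jukes–Cantor,
$d = -\tfrac34\ln(1-\tfrac43 p)$, with saturation ($p \ge 0.75$) an error
unless a cap is requested (the bootstrap uses a cap of 5 substitutions/site
so extreme resamples stay computable). Trees are BioNJ with optional
midpoint rooting; bootstrap support resamples alignment columns with
replacement, rebuilds the JC+BioNJ tree per pseudoreplicate, and reports
per-bipartition frequencies on the full-data tree, deterministically under
a single seed.

## What the simulators emulate — and what they do not

`genFlowHistogram` draws Poisson counts around two Gaussian G1 peaks placed
at channels proportional to the 2C values (standard at channel 500 of 1024,
linear scale) plus an optional uniform debris continuum. It does not model
G2/S phases, nonlinear amplifier response, or structured debris, so peak
detection on real histograms may need the noise floor and smoothing window
adjusted.

`genSSRPanel` partitions each locus's allele pool into group-characteristic
subsets; accessions draw from their group subset with probability 0.9 and
from the whole pool otherwise, and with probability 0.05 a group shares
another group's subset at a locus. This plants a recoverable two-level
structure but has no mutation model, null alleles, or linkage.

`genITSFamily` concatenates a random ITS1 (length drawn from 215–223 nt, GC
60%), the reference 5.8S (155 nt), and a *designed* ITS2 (205–218 nt): four
hairpins with distinct G/C stems, a C/T pyrimidine 1×1 loop in helix II,
`TGGT` in the helix III stem, and poly-A loops/linkers/tails that cannot
pair against the stems — chosen so the base-pair-maximization fold is
exactly the intended topology at every envelope length. Types derive from
the template by ITS1 divergence (10 substitutions by default, keeping
planted types below the 99% collapse threshold), targeted motif changes,
helix III disruption, 5.8S GC erosion (default rate 0.16, chosen to land
near the low-40s–high-40s GC of published eroded copies), or internal 5.8S
deletion; reads get uniform substitution errors. Consequences to keep in
mind: the designed ITS2 is GC-poor (≈ 35–40%) compared with real ITS2
(≈ 60–70%), the poly-A exterior is artificial, and read errors are
substitution-only (no chimeras or indels). Passing recovery tests therefore
demonstrates that the pipeline recovers planted signal under clean
assumptions, not that it is robust to every artefact of real clone
libraries.

## Problem sizes and determinism

Tests and the acceptance script run everything at desk scale: 1024-bin
histograms with 5,000 nuclei per peak, SSR panels of 10 accessions × 19
loci, ITS families of 28 reads with up to 4 planted types, trees of ≤ 8
taxa for exact-recovery properties, and 100 bootstrap pseudoreplicates on
a 400-column alignment (the production default is 1000). Every stochastic
component takes an explicit seed and restores the RNG state afterwards
(`withr::with_seed`), so all generated fixtures are byte-reproducible; the
fold, clustering and letter-display algorithms are deterministic including
their tie-breaks.

## Known limitations

* The compact-letter count from summary-reconstructed replicates cannot be
  expected to match groupings computed on raw measurements (see above).
* Base-pair maximization overpairs relative to thermodynamic folding; the
  four-helix test is designed for engineered or clearly canonical/decayed
  sequences, and borderline real ITS2 folds deserve an MFE backend.
* The 5.8S "formed" criterion is relative to the configured reference fold;
  with a different reference the 0.7 recovery fraction may need revisiting.
* Nei's standard distance assumes the scored allele frequencies are the
  accession's true frequencies; with single-individual accessions this is a
  genotype identity measure, which is how genotyping platforms use it.
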