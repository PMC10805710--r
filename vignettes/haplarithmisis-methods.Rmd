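---
title: "Haplarithmisis-based preimplantation genetic testing: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplarithmisis-based preimplantation genetic testing: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplarithm)
```

## The problem

In vitro-produced embryos — the package's defaults emulate equine embryos
genotyped on a medium-density (~70K) SNP array — carry chromosomal and
genome-wide errors that are a major cause of developmental failure.
A single biopsy of a few trophectoderm cells, amplified by whole-genome
amplification (WGA), can be genotyped array-wide and analysed for two
questions at once: are there aneuploidies or ploidy abnormalities (PGT-A),
and which parental haplotypes were inherited at loci carrying known disease
or trait alleles (PGT-M)?

`haplarithm` implements the haplarithmisis approach to both questions.  The
inputs are per-SNP genotype calls (AA/AB/BB/NC), B-allele frequencies (BAF)
and LogR ratios for the embryo sample and its parents (plus grandparents or
a sibling embryo for phasing), in the tab-separated dialect produced by
array-genotyping software.  Genotype-quality filtering (e.g. a GenCall-style
confidence threshold, default 0.75 when a confidence column is present)
happens at import.

## The measurement model

For a SNP with `k` B alleles among `n` allele copies, the ideal BAF is
`k / n`; the ideal LogR is `log2(n / 2)`, the log-ratio of observed to
disomic-expected intensity.  A whole-chromosome monosomy, trisomy and
tetrasomy therefore sit at LogR −1, `log2(3/2)` ≈ 0.58 and 1, and their BAF
level sets are {0, 1}, {0, 1/3, 2/3, 1} and {0, 1/4, 1/2, 3/4, 1}.  Zero
copies have no defined LogR; the package reports a documented floor of −5.

## Phasing and informative SNPs

A parent's heterozygous (AB) SNPs are phased into homologue 1 / homologue 2
either from that parent's own parents (homologue 1 := the grandsire-derived
allele, resolvable wherever at least one grandparent call pins down the
transmission and the trio is Mendelian-consistent) or from a sibling embryo
sample (homologue 1 := the allele the sibling inherited, resolvable where
the other parent is homozygous).  Sibling-anchored phase is relative to the
sibling's — possibly recombinant — transmitted strand; haplotype blocks of
other embryos are then interpreted relative to the sibling, which is how
carrier-pedigree PGT-M is practised.  No population or statistical phasing
is attempted: unresolved SNPs are simply non-informative downstream.

An *informative SNP* for the maternal haplarithm track is one where the
mother is AB and phased, the father is homozygous, and the embryo BAF is
present (the embryo's discrete genotype call is deliberately ignored — the
BAF carries the signal even for SNPs the caller marks NC).  The haplarithm
value is `f = |BAF − b0|` with `b0` = 0 (other parent AA) or 1 (BB), and
the SNP is assigned to subtrack P1 if the mother's homologue-1 allele
differs from the father's allele, else P2.  Under biparental disomy the
subtrack of the inherited homologue sits at 0.5 and the other at 0; under a
maternal-loss monosomy both sit at 0; a meiosis-I-type heterodisomic
trisomy shows (1/3, 1/3).  In general subtrack P1 sits at `m1/n` where `m1`
is the copy number of maternal homologue 1 — this is the signature used for
joint copy-number/origin classification.

## Segmentation

The P1/P2 subtracks of each parent are segmented jointly per chromosome
(shared breakpoints), and the LogR track separately, by penalised
least-squares changepoint detection (PELT, implemented in C++): minimise
within-segment squared error plus a per-segment penalty.  `penalty = "auto"`
uses a BIC-like value `4·d·σ̂²·log(n)` with `σ̂` estimated robustly from
first differences within each subtrack, floored at 1e-8 so that noise-free
tracks split exactly at true level changes and nowhere else (a noise-free
single crossover yields exactly two segments).  The minimum segment size
(`min_seg_snps`) is 5 combined points: with roughly 100–400 informative
SNPs per chromosome per parent on a 70K array, a larger minimum makes
crossovers within the terminal handful of informative SNPs undetectable and
measurably hurts single-crossover recovery; 5 keeps recovery above 95%
without introducing spurious segments at default noise.

Haplotype blocks are read from the segmented subtracks with an absolute
`signature_tolerance` of 0.1 on the segment means; H1↔H2 transitions are
recombination breakpoints.  A breakpoint is localized only to the interval
between its two flanking informative SNPs; the package records that
uncertainty interval and the reported breakpoint position is its midpoint.

## Copy-number, mosaicism, ploidy and sex

For each chromosome the union of the LogR and the two parental
segmentations defines regions; each region lies inside exactly one segment
of each track, and its five observables (LogR mean, maternal P1/P2,
paternal P1/P2) are classified against the enumerated signature table of
homologue configurations (m1, m2, p1, p2) with total copy number up to 4
(the modeled maximum; the signature list stops at tetrasomy).  The call is
the nearest configuration by weighted Euclidean distance (default weights
1) if it fits within `classify_tolerance` 0.1; equidistant configurations
prefer the smaller copy-number change from disomy, then a maternal over a
paternal explanation (an arbitrary, documented tie-break).

If no pure configuration fits, a two-component cell mixture is fitted: a
fraction of cells disomic and the rest in an aberrant configuration.  The
mixture is formed physically — copy numbers average over cells, subtrack
levels are allele-count weighted, LogR is `log2` of the mean copy number —
and the aberrant fraction is optimised by least squares.  The region is
called mosaic when the mixture fits within tolerance, improves on the best
pure fit at least 2-fold, and the estimated aberrant fraction lies in
[0.2, 0.8].  Mosaicism has no quantitative community standard — it is
recognised qualitatively as deviation from full-aberration values — so
these three thresholds are package defaults, configurable in
`haplarithm_control()`.  A clear LogR
deviation that the subtracks do not confirm is reported as
`undefined_parental_origin` rather than forced into a configuration.

Adjacent regions agreeing on copy number merge (homologue composition may
change at every crossover without changing the state).  A chromosome is
reported as a single state when discordant regions cover at most 10% of its
length — short terminal regions around near-end crossovers have too few
informative SNPs for stable means — and as `partial:` otherwise.

Genome-wide ploidy is ruled on the autosomal chromosome states: a uniform
(≥ 90% of called autosomes) maternal trisomy is digynic triploidy, meiotic
in origin if heterodisomy (both maternal homologues in one region) is seen
anywhere and mitotic (a single duplicated maternal genotype) if not; the
paternal mirror is diandric triploidy; uniform single-parent monosomy is
gynogenetic/androgenetic haploidy; two copies all from one parent is
genome-wide uniparental disomy.  Widespread aberrations matching no pattern
are `complex`.  Sex follows the X chromosome: one maternal X and no
paternal X is male, one of each is female, anything else (including
triploid X constellations) is reported `undetermined` — the array carries
no Y probes.  Events are assigned meiotic/mitotic/low-grade-mosaic origin
by concordance across samples of one embryo: shared by all samples →
meiotic; in a strict subset of blastomeres → mitotic; in a biopsy but not
its whole blastocyst → low-grade mosaic.

## PGT-M locus calls

The haplotype block overlapping a locus of interest gives the inherited
homologue per parent.  A call is inconclusive when (i) the parent's
contribution is lost at the locus (no heterozygosity, e.g. monosomy), (ii)
no informative SNPs support the containing block around the locus, or
(iii) a recombination breakpoint co-localizes with the locus — assessed
against the breakpoint's uncertainty interval, not just its midpoint, so a
crossover that cannot be placed confidently outside the locus renders the
call inconclusive.  Reported flanking metrics are the distance in bp and
the number of informative SNPs to the closest upstream and downstream
recombination site (chromosome ends count as boundaries).  The five
default loci (B3GALNT2, PLOD1, MUTYH, STX17, GBE1) ship with synthetic
placeholder coordinates on the synthetic karyotype; real analyses must
supply reference coordinates.

## The synthetic-data generator

Because per-sample real arrays are not available for distribution, the
package ships a simulator that provides ground truth for every layer:

* **Karyotype**: 31 autosomes + X, lengths decreasing linearly from 190 to
  30 Mbp — an equine-like scale, overridable with exact assembly lengths.
  The X is simulated like an autosome; male embryos carry one maternal X
  and fathers transmit no X to them (no Y probes are modeled).
* **Array**: `n_snps` SNPs (default 70,000) placed uniformly, counts
  proportional to chromosome length; per-SNP B-allele frequencies uniform
  on [0.05, 0.5] and flipped to the complement with probability 1/2, which
  reproduces realistic informative-SNP yields (~20,000 per embryo with
  both parents phased, matching practice).
* **Meiosis**: Poisson crossovers at 1 per 100 Mbp, uniform positions, no
  interference; obligate crossovers off.  Nondisjunction `MI` transmits
  both homologues (heterodisomy genome-wide or per chromosome), `MII`
  transmits two identical copies of one recombined strand (a single
  genotype); nullisomic gametes omit a chromosome.
* **Embryos**: all cells share the zygotic (meiotic) karyotype; mitotic
  events (whole/segmental gains and losses, endoreduplication of one
  parental complement, reciprocal gain/loss pairs) apply to cell subsets.
* **Measurement**: biopsies pool allele counts over sampled cells after
  per-cell, per-allele drop-out (ADO); BAF is the surviving-allele B
  fraction plus truncated Gaussian noise; LogR is `log2(mean copies / 2)`
  plus Gaussian noise; genotype calls threshold the pooled B fraction at
  0.15/0.85 with random miscalls and missing calls.  Defaults for embryo
  samples are ADO 0.2 per cell, BAF SD 0.05, LogR SD 0.15, miscall 0.005,
  and missing rates 0.15/0.3/0.45 for blastocyst/biopsy/blastomere,
  emulating the observed coverage gradient from multi-cell to single-cell
  samples.  Parental bulk DNA is rendered noise-free.

What the simulator does *not* emulate: GC-content-dependent amplification
bias, locus-specific ADO hot spots, wave artifacts in LogR, linkage
disequilibrium between SNPs, genotyping-cluster asymmetries, and real
recombination maps with interference and hot spots.  Passing the recovery
suite therefore demonstrates that the analysis correctly inverts its own
measurement model at realistic noise levels — not that real-array
performance will be identical; thresholds for real data (call rate,
Mendelian inconsistency, conclusive-call criteria) must be calibrated on
reference samples with known haplotypes.

## Validation problem sizes

The bundled validation suite (`evaluate_recovery()`, also recomputed by
`scripts/acceptance.R`) simulates one four-grandparent pedigree and twenty
embryos on the full 70,000-SNP array: euploid males and females, maternal
and paternal meiotic monosomies and trisomies (MI and MII), 50% mitotic
mosaics, and digynic triploids of both origins, each rendered as a 10-cell
biopsy at default noise and analysed with grandparent phasing of both
parents.  Phasing fidelity is checked noise-free on a 500,000-SNP map
(> 10⁵ resolved SNPs in both phasing modes); unit tests use maps of
2,000–20,000 SNPs.  The noise-robustness check spans a 3-point grid at
1–3× the default BAF/LogR noise, where recovery degrades monotonically;
far beyond that range the auto-penalty grows so large that segmentation
collapses to whole chromosomes, which can *raise* whole-chromosome state
recovery again while destroying breakpoint resolution — a known and
documented behaviour, which is why the grid stops at 3×.

## Known limitations

* Copy numbers above 4 are collapsed onto the nearest modeled signature.
* Chromosome-level states tolerate up to 10% discordant span; a true
  segmental event shorter than that on an otherwise normal chromosome is
  visible in `region_calls` but not in the chromosome state string.
* Sibling-anchored phase makes block colours relative to the sibling;
  breakpoint positions are unaffected but homologue labels are not
  comparable across pedigrees phased through different anchors.
* The mosaic-fraction estimate assumes exactly two cell populations.
* Balanced rearrangements and segmental events below the informative-SNP
  resolution are invisible by construction.
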