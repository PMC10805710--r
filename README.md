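# haplarithm

Genome-wide haplotyping and copy-number analysis of SNP-array embryo
samples for preimplantation genetic testing (PGT), via *haplarithmisis*.

## What it does, and for whom

For labs and researchers running array-based PGT on in vitro-produced
embryos (the defaults emulate equine embryos on a ~70K SNP array), one
trophectoderm biopsy — or a single blastomere, or a whole blastocyst —
analysed together with the parents answers two questions at once:

* **PGT-A**: which chromosomes (or segments) are gained or lost, from
  which parent, by a meiotic or a mitotic mechanism; whether the genome is
  diploid, triploid (digynic/diandric), haploid or uniparental; and the
  embryo's sex from X-chromosome copy number.
* **PGT-M**: which parental haplotype (homologue 1 or 2) the embryo
  inherited at user-specified loci of interest, with the distance and
  informative-SNP counts to the flanking recombination sites, and explicit
  inconclusive calls when a monosomy, a recombination site or a lack of
  informative SNPs makes the haplotype unreadable.

## The method in brief

Parental AB genotypes are phased against grandparents (H1 := the
grandsire-derived allele) or a sibling embryo (H1 := the sibling's
transmitted allele).  At *informative SNPs* — target parent AB and phased,
other parent homozygous — the embryo BAF is folded into
`f = |BAF − b0|` (`b0` = 0 for AA, 1 for BB) and split into subtracks P1/P2
by which parental homologue carries the discriminating allele.  For a
configuration with `m1`, `m2` copies of the maternal homologues and `p1`,
`p2` paternal ones (`n = m1+m2+p1+p2`):

```
LogR = log2(n / 2)          subtrack levels = m1/n, m2/n, p1/n, p2/n
```

so disomy shows subtracks {0.5, 0} and LogR 0; monosomy/trisomy/tetrasomy
sit at LogR −1 / 0.58 / 1 with BAF level sets {0,1}, {0,⅓,⅔,1},
{0,¼,½,¾,1}.  Subtracks and LogR are segmented by penalised least-squares
changepoint detection (PELT, C++); each segment is classified against the
enumerated signature table, with a two-population cell-mixture fit for
mosaicism.  Haplotype blocks, recombination breakpoints, genome-wide
ploidy, sex, QC metrics (call rate, Mendelian inconsistency) and locus
calls follow.  A bundled simulator (pedigree, meiosis with recombination
and nondisjunction, multicell embryos with mitotic errors, WGA noise:
allele drop-out, miscalls, missing calls, BAF/LogR dispersion) provides
ground truth for every layer.

## Worked example

```r
library(haplarithm)

map    <- build_snp_map(n_snps = 70000, seed = 1)      # synthetic 70K array
ped    <- simulate_pedigree(map, seed = 2)             # parents + 4 grandparents
phase  <- phase_pedigree(ped)                          # grandparent phasing
sim    <- simulate_embryo_scenario(ped,
            list(type = "meiotic_monosomy", chrom = "31", parent = "mat",
                 sex = "male", id = "demo_embryo_01"), seed = 3)
biopsy <- render_array(sim$truth, map, noise = default_noise("biopsy"),
                       seed = 4)                       # 10-cell biopsy, WGA noise
fit    <- haplarithmisis(biopsy, ped$mother_arr, ped$father_arr, map,
                         phase, loci = default_loci())
fit
```

```
Haplarithmisis analysis of sample demo_embryo_01 (biopsy)
  informative SNPs: 24472, call rate 0.699, Mendelian inconsistency 0.0067
  genome: biparental_diploid | sex: male 
  aberrant chromosomes:
    chr31  maternal_loss
    chrX   paternal_loss
  loci of interest:
    B3GALNT2 : maternal H2 (flank 146/372 SNPs) | paternal H1 (flank 150/292 SNPs) 
    PLOD1 : maternal H2 (flank 68/314 SNPs) | paternal H1 (flank 64/56 SNPs) 
    MUTYH : maternal H2 (flank 110/272 SNPs) | paternal H1 (flank 97/23 SNPs) 
    STX17 : maternal H1 (flank 85/79 SNPs) | paternal H2 (flank 97/133 SNPs) 
    GBE1 : maternal H1 (flank 7/125 SNPs) | paternal H2 (flank 77/23 SNPs) 
```

Reading the output: the injected maternal loss of chromosome 31 is
recovered (`maternal_loss`, copies 0 maternal / 1 paternal); the X shows
one maternal and no paternal copy, so the embryo is male (`paternal_loss`
on X is the expected male constellation, not an aneuploidy).  About 24,500
informative SNPs drove the haplarithms, and each locus call names the
inherited homologue with its flanking informative-SNP support.
`plot(fit)` draws the five-panel haplarithm (LogR, Mat-BAF, maternal
blocks in pink/red, Pat-BAF, paternal blocks in light/dark blue);
`plot_circos_summary()` draws concentric per-sample chromosome-state
rings; `summarize_embryo()` emits the JSON/TSV report;
`classify_event_origin()` compares several samples of one embryo to label
events meiotic, mitotic or low-grade mosaic.  `run_pipeline("config.yaml")`
drives the whole analysis from sample tables on disk.

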