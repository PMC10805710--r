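Package: haplarithm
Title: Genome-Wide Haplotyping and Copy-Number Analysis for Preimplantation Genetic Testing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplarithmisis-based concurrent preimplantation genetic testing
    for aneuploidy (PGT-A) and monogenic traits (PGT-M) from SNP-array data.
    Parental genotypes are phased against grandparents or a sibling embryo,
    embryo B-allele frequencies at informative SNPs are split into
    parent-specific haplarithm subtracks, and joint changepoint segmentation
    of the subtracks and the LogR ratio yields inherited haplotype blocks,
    chromosome- and segment-level copy number with parental and
    meiotic/mitotic origin, genome-wide ploidy state, embryo sex, QC metrics
    and locus-level haplotype calls.  A bundled synthetic embryo simulator
    (pedigree genotypes, meiotic recombination, aneuploidy and ploidy errors,
    biopsy mixtures, whole-genome-amplification noise) provides ground truth
    for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
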