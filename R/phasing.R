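new_phased_parent <- function(h1_allele, source, n_inconsistent) {
  out <- list(h1_allele = h1_allele, source = source,
              n_phased = sum(!is.na(h1_allele)),
              n_inconsistent = n_inconsistent)
  class(out) <- "phased_parent"
  out
}

#' @export
print.phased_parent <- function(x, ...) {
  cat(sprintf("phased parent (%s): %d SNPs resolved, %d Mendelian-impossible\n",
              x$source, x$n_phased, x$n_inconsistent))
  invisible(x)
}

#' Phase a parent's heterozygous SNPs with that parent's own parents
#'
#' At SNPs where the target parent is AB, the allele deducibly transmitted
#' by the grandsire defines homologue 1 (H1 := grandsire-derived).  The SNP
#' is resolvable when at least one grandparent call pins down the
#' transmission and the trio is Mendelian-consistent; otherwise it is left
#' unresolved (Mendelian-impossible configurations are also counted).
#' Paternal and maternal grandparents are supported symmetrically.
#'
#' @param parent,grandsire,granddam `"sample_array"` objects on one map.
#' @return A `"phased_parent"`: `h1_allele` is `"A"`/`"B"`/`NA` per map SNP.
#' @export
phase_with_grandparents <- function(parent, grandsire, granddam) {
  p <- parent$gtype; gs <- grandsire$gtype; gd <- granddam$gtype
  n <- length(p)
  h1 <- rep(NA_character_, n)
  het <- p == "AB"
  # grandsire homozygous: he transmitted his only allele, unless the granddam
  # cannot supply the other allele (Mendelian-impossible)
  res_gsA <- het & gs == "AA" & gd != "AA"
  res_gsB <- het & gs == "BB" & gd != "BB"
  # grandsire ambiguous (AB or NC): a homozygous granddam pins her
  # transmission, the grandsire gave the other allele
  amb <- het & (gs %in% c("AB", "NC"))
  res_gdA <- amb & gd == "AA" & gs != "AA"   # granddam gave A -> grandsire B
  res_gdB <- amb & gd == "BB" & gs != "BB"
  h1[res_gsA] <- "A"
  h1[res_gsB] <- "B"
  h1[res_gdA] <- "B"
  h1[res_gdB] <- "A"
  incons <- het & ((gs == "AA" & gd == "AA") | (gs == "BB" & gd == "BB"))
  new_phased_parent(h1, "grandparent", sum(incons))
}

#' Phase a parent's heterozygous SNPs with a sibling embryo sample
#'
#' At SNPs where the target parent is AB, the other parent is homozygous and
#' the sibling has a call, the parental allele the sibling inherited (the
#' sibling allele not attributable to the other parent) defines homologue 1.
#' H1 is therefore anchored to the sibling's transmitted — possibly
#' recombinant — haplotype; downstream haplotype blocks of other embryos are
#' relative to it.  Sibling calls inconsistent with the parents are left
#' unresolved and counted.  A multi-cell, low-noise sibling sample (e.g. a
#' biopsied whole blastocyst) should be used.
#'
#' @param parent,other_parent,sibling `"sample_array"` objects on one map.
#' @return A `"phased_parent"`.
#' @export
phase_with_sibling <- function(parent, other_parent, sibling) {
  p <- parent$gtype; o <- other_parent$gtype; s <- sibling$gtype
  n <- length(p)
  h1 <- rep(NA_character_, n)
  base <- p == "AB" & o %in% c("AA", "BB") & s %in% c("AA", "AB", "BB")
  oa <- substr(o, 1, 1)                 # other parent's only allele
  # sibling hom: both alleles equal; parent gave that allele if consistent
  sib_homA <- base & s == "AA"
  sib_homB <- base & s == "BB"
  sib_het <- base & s == "AB"
  h1[sib_homA & oa == "A"] <- "A"
  h1[sib_homB & oa == "B"] <- "B"
  h1[sib_het & oa == "A"] <- "B"        # parent gave the non-other allele
  h1[sib_het & oa == "B"] <- "A"
  incons <- (sib_homA & oa == "B") | (sib_homB & oa == "A")
  new_phased_parent(h1, "sibling", sum(incons))
}
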