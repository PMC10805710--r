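#' Read a table of loci of interest
#'
#' Tab-separated columns `gene`, `chrom`, `start_bp`, `end_bp`, `note`;
#' intervals are 1-based closed.  With `strict_bed = TRUE` the coordinates
#' are interpreted as 0-based half-open (BED) and converted.
#'
#' @param path file path.
#' @param strict_bed interpret coordinates as BED-style.
#' @return data.frame of loci, unique by gene name.
#' @export
read_locus_table <- function(path, strict_bed = FALSE) {
  loci <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            colClasses = c(chrom = "character"))
  need <- c("gene", "chrom", "start_bp", "end_bp")
  miss <- setdiff(need, names(loci))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(loci$gene)) stop("loci must be unique by gene name")
  if (strict_bed) loci$start_bp <- loci$start_bp + 1L
  if (any(loci$end_bp < loci$start_bp)) stop("end_bp < start_bp")
  if (is.null(loci$note)) loci$note <- ""
  loci
}

#' Default loci of interest
#'
#' The five equine genes screened in haplotype-based PGT-M (B3GALNT2 for
#' congenital hydrocephalus on chromosome 1; PLOD1 for warmblood fragile
#' foal syndrome and MUTYH for cerebellar abiotrophy on chromosome 2;
#' STX17 for grey coat colour on chromosome 25; GBE1 for glycogen branching
#' enzyme deficiency on chromosome 26), with synthetic placeholder
#' coordinates on the default synthetic karyotype.  Real analyses must
#' supply reference-assembly coordinates via [read_locus_table()].
#'
#' @return data.frame of loci.
#' @export
default_loci <- function() {
  read_locus_table(system.file("extdata", "loci_synthetic.tsv",
                               package = "haplarithm"))
}

call_one_parent_locus <- function(locus, parent, blocks, breakpoints,
                                  region_calls, informative, chrom_len) {
  res <- list(haplotype = "inconclusive", reason = "none",
              upstream_bp = NA_real_, downstream_bp = NA_real_,
              upstream_n = NA_integer_, downstream_n = NA_integer_)
  copies <- if (parent == "mat") region_calls$maternal_copies else
    region_calls$paternal_copies
  overl <- region_calls$start_bp <= locus$end_bp &
    region_calls$end_bp >= locus$start_bp
  inf <- informative[informative$parent == parent &
                       informative$chrom == locus$chrom, , drop = FALSE]
  bp <- breakpoints[breakpoints$parent == parent &
                      breakpoints$chrom == locus$chrom, , drop = FALSE]

  up_bp <- bp$pos_bp[bp$pos_bp < locus$start_bp]
  dn_bp <- bp$pos_bp[bp$pos_bp > locus$end_bp]
  up <- if (length(up_bp)) max(up_bp) else 1
  dn <- if (length(dn_bp)) min(dn_bp) else chrom_len
  res$upstream_bp <- locus$start_bp - up
  res$downstream_bp <- dn - locus$end_bp
  res$upstream_n <- sum(inf$pos_bp >= up & inf$pos_bp < locus$start_bp)
  res$downstream_n <- sum(inf$pos_bp > locus$end_bp & inf$pos_bp <= dn)
  in_locus_n <- sum(inf$pos_bp >= locus$start_bp & inf$pos_bp <= locus$end_bp)

  if (any(overl) && any(copies[overl] == 0, na.rm = TRUE)) {
    res$reason <- "no_heterozygosity"
    return(res)
  }
  lo <- if (is.null(bp$lo_bp)) bp$pos_bp else bp$lo_bp
  hi <- if (is.null(bp$hi_bp)) bp$pos_bp else bp$hi_bp
  if (any(lo <= locus$end_bp & hi >= locus$start_bp)) {
    res$reason <- "recombination_at_locus"
    return(res)
  }
  if (res$upstream_n + res$downstream_n + in_locus_n == 0) {
    res$reason <- "no_informative_snps"
    return(res)
  }
  bl <- blocks[blocks$parent == parent & blocks$chrom == locus$chrom, ,
               drop = FALSE]
  hit <- bl[bl$start_bp <= locus$end_bp & bl$end_bp >= locus$start_bp, ,
            drop = FALSE]
  if (!nrow(hit)) {
    # locus beyond block coverage: inherit the nearest block's call
    if (!nrow(bl)) { res$reason <- "no_informative_snps"; return(res) }
    mid <- (locus$start_bp + locus$end_bp) / 2
    hit <- bl[which.min(pmin(abs(bl$start_bp - mid), abs(bl$end_bp - mid))), ,
              drop = FALSE]
  }
  inh <- unique(hit$inherited)
  if (length(inh) == 1 && inh %in% c("H1", "H2")) {
    res$haplotype <- inh
    res$reason <- "none"
  } else if (all(inh == "none")) {
    res$reason <- "no_heterozygosity"
  } else if (all(inh == "both")) {
    res$reason <- "no_heterozygosity"
  } else if (length(inh) > 1 && all(inh %in% c("H1", "H2"))) {
    res$reason <- "recombination_at_locus"
  } else {
    res$reason <- "no_informative_snps"
  }
  res
}

#' Call the inherited parental haplotypes at a locus of interest
#'
#' The haplotype block overlapping the locus gives the inherited homologue
#' per parent.  Calls are inconclusive when the parent's contribution is
#' lost at the locus (no heterozygosity, e.g. monosomy), when no
#' informative SNPs flank the locus within its containing block, or when a
#' recombination breakpoint co-localises with the locus.  Flanking metrics
#' report the distance (bp) and the number of informative SNPs to the
#' closest upstream and downstream recombination site (chromosome ends
#' count as boundaries).
#'
#' @param fit a `"haplarithmisis"` object.
#' @param locus one-row data.frame (or list) with `gene`, `chrom`,
#'   `start_bp`, `end_bp`.
#' @return list of class `"locus_call"` with `gene`, `mat`, `pat` (each the
#'   per-parent call with haplotype, reason and flanking metrics).
#' @export
call_locus <- function(fit, locus) {
  if (!(locus$chrom %in% fit$chrom_calls$chrom))
    stop("locus chromosome absent from data: ", locus$chrom)
  kar <- fit$karyotype
  rc <- fit$region_calls[fit$region_calls$chrom == locus$chrom, ,
                         drop = FALSE]
  out <- list(
    gene = locus$gene,
    mat = call_one_parent_locus(locus, "mat", fit$blocks, fit$breakpoints,
                                rc, fit$informative, kar[[locus$chrom]]),
    pat = call_one_parent_locus(locus, "pat", fit$blocks, fit$breakpoints,
                                rc, fit$informative, kar[[locus$chrom]]))
  class(out) <- "locus_call"
  out
}

#' @export
print.locus_call <- function(x, ...) {
  fmt <- function(p, lab) {
    if (p$reason == "none")
      sprintf("%s %s (flank %d/%d SNPs)", lab, p$haplotype,
              p$upstream_n, p$downstream_n)
    else sprintf("%s inconclusive (%s)", lab, p$reason)
  }
  cat(x$gene, ":", fmt(x$mat, "maternal"), "|", fmt(x$pat, "paternal"), "\n")
  invisible(x)
}
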