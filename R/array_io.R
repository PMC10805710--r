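#' Write a sample table in the GenomeStudio-like export dialect
#'
#' Tab-separated, one header row, columns `Sample ID`, `SNP Name`, `Chr`,
#' `Position`, `GType`, `B Allele Freq`, `Log R Ratio`; one row per map SNP
#' in map order; no-calls written literally as `NC`; missing numeric values
#' written as `NaN`; numerics printed with 6 decimals.
#'
#' @param sample a `"sample_array"`.
#' @param map the SNP map the sample is aligned to.
#' @param path output file path.
#' @export
write_sample_table <- function(sample, map, path) {
  num <- function(x) ifelse(is.na(x), "NaN", sprintf("%.6f", x))
  lines <- c(
    paste("Sample ID", "SNP Name", "Chr", "Position", "GType",
          "B Allele Freq", "Log R Ratio", sep = "\t"),
    paste(attr(sample, "sample_id") %||% "sample", map$snp_id, map$chrom,
          format(map$pos_bp, scientific = FALSE, trim = TRUE),
          sample$gtype, num(sample$baf), num(sample$logr), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample table in the GenomeStudio-like export dialect
#'
#' Rows are matched to the map by SNP name and reordered to map order; map
#' SNPs absent from the file become NC with missing BAF/LogR.  Duplicate SNP
#' rows keep the last occurrence (with a warning).  If a `GC Score` column
#' is present, rows below `gencall_threshold` are set to NC (the upstream
#' genotype-quality filter).
#'
#' @param path file path.
#' @param map the SNP map.
#' @param role sample role stored on the result.
#' @param gencall_threshold minimum genotype confidence when a `GC Score`
#'   column is present.
#' @return A `"sample_array"`.
#' @export
read_sample_table <- function(path, map, role = "embryo",
                              gencall_threshold = 0.75) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           colClasses = "character", na.strings = NULL)
  need <- c("SNP Name", "Chr", "Position", "GType", "B Allele Freq",
            "Log R Ratio")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  badchr <- which(!(tab$Chr %in% unique(map$chrom)))
  if (length(badchr))
    stop(sprintf("line %d: unresolvable chromosome label '%s'",
                 badchr[1] + 1L, tab$Chr[badchr[1]]))
  parse_num <- function(col) {
    x <- suppressWarnings(as.numeric(ifelse(tab[[col]] %in%
                                              c("NaN", "NA", ""), NA,
                                            tab[[col]])))
    bad <- which(is.na(x) & !(tab[[col]] %in% c("NaN", "NA", "")))
    if (length(bad))
      stop(sprintf("line %d: malformed numeric field in '%s': '%s'",
                   bad[1] + 1L, col, tab[[col]][bad[1]]))
    x
  }
  baf <- parse_num("B Allele Freq")
  logr <- parse_num("Log R Ratio")
  gtype <- tab$GType
  if ("GC Score" %in% names(tab)) {
    gc <- parse_num("GC Score")
    gtype[!is.na(gc) & gc < gencall_threshold] <- "NC"
  }

  if (anyDuplicated(tab$`SNP Name`)) {
    warning("duplicate SNP rows; keeping the last occurrence")
  }
  ord <- match(map$snp_id, tab$`SNP Name`)
  if (anyDuplicated(tab$`SNP Name`)) {
    last <- tapply(seq_len(nrow(tab)), tab$`SNP Name`, max)
    ord <- unname(last[map$snp_id])
  }
  g <- ifelse(is.na(ord), "NC", gtype[ord])
  g[!(g %in% c("AA", "AB", "BB", "NC"))] <- "NC"
  sid <- if ("Sample ID" %in% names(tab) && nrow(tab)) tab$`Sample ID`[1]
         else "sample"
  new_sample_array(map, sid, role, g,
                   ifelse(is.na(ord), NA_real_, baf[ord]),
                   ifelse(is.na(ord), NA_real_, logr[ord]))
}

#' Genotype call (coverage) rate
#'
#' Fraction of map SNPs with a genotype call other than NC.
#'
#' @param sample a `"sample_array"`.
#' @export
call_rate <- function(sample) mean(sample$gtype != "NC")

# genotype -> B-allele count (NA for NC)
gt_code <- function(g) c(AA = 0L, AB = 1L, BB = 2L)[g]

#' Mendelian inconsistency rate of an embryo against its parents
#'
#' Over SNPs where embryo, mother and father all have genotype calls, the
#' fraction where the embryo genotype is impossible under biparental disomic
#' inheritance from the parental called genotypes.  Used as a generic QC
#' metric (the disomy-based test is applied regardless of the embryo's
#' actual karyotype).
#'
#' @param embryo,mother,father `"sample_array"` objects on one map.
#' @export
mendelian_inconsistency_rate <- function(embryo, mother, father) {
  e <- gt_code(embryo$gtype); m <- gt_code(mother$gtype)
  f <- gt_code(father$gtype)
  ok <- !is.na(e) & !is.na(m) & !is.na(f)
  if (!any(ok)) return(NA_real_)
  e <- e[ok]; m <- m[ok]; f <- f[ok]
  # embryo allele pair (a1, a2): consistent if one allele can come from each
  # parent.  Encode parent transmissible alleles: hom -> that allele only.
  can_give <- function(p, a) (a == 0L & p <= 1L) | (a == 1L & p >= 1L)
  a1 <- ifelse(e == 2L, 1L, 0L)           # first embryo allele
  a2 <- ifelse(e == 0L, 0L, 1L)           # second embryo allele
  cons <- (can_give(m, a1) & can_give(f, a2)) |
          (can_give(m, a2) & can_give(f, a1))
  mean(!cons)
}

#' Per-sample QC metrics
#'
#' @param sample embryo `"sample_array"`.
#' @param mother,father parental samples (optional; inconsistency is NA
#'   without them).
#' @param n_informative count of informative SNPs, if known.
#' @return list of class `"qc_metrics"`.
#' @export
qc_metrics <- function(sample, mother = NULL, father = NULL,
                       n_informative = NA_integer_) {
  out <- list(
    call_rate = call_rate(sample),
    mendelian_inconsistency_rate =
      if (is.null(mother) || is.null(father)) NA_real_
      else mendelian_inconsistency_rate(sample, mother, father),
    n_informative_snps = n_informative)
  class(out) <- "qc_metrics"
  out
}

#' @export
print.qc_metrics <- function(x, ...) {
  cat(sprintf("call rate %.4f, Mendelian inconsistency %.4f, informative SNPs %s\n",
              x$call_rate, x$mendelian_inconsistency_rate,
              format(x$n_informative_snps)))
  invisible(x)
}
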