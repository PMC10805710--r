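#' Whole-genome-amplification noise configuration
#'
#' Models the dominant artifacts of single-cell/few-cell array genotyping:
#' per-cell per-allele drop-out (ADO), random genotype miscalls, missing
#' genotype calls, and Gaussian dispersion of the BAF and LogR measurements.
#' Bulk (parental) samples are rendered with all rates at 0.
#'
#' @param ado_rate per-cell, per-SNP, per-allele drop-out probability.
#' @param miscall_rate probability a called genotype is replaced by a random
#'   different genotype.
#' @param missing_rate probability a genotype call is set to NC (BAF/LogR
#'   are retained; the discrete call carries the coverage rate).
#' @param baf_sd,logr_sd Gaussian noise SDs on the measurements.
#' @param logr_floor reported LogR for zero copies (log2(0) is undefined).
#' @export
noise_config <- function(ado_rate = 0, miscall_rate = 0, missing_rate = 0,
                         baf_sd = 0, logr_sd = 0, logr_floor = -5) {
  rates <- c(ado_rate, miscall_rate, missing_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must be in [0, 1]")
  if (baf_sd < 0 || logr_sd < 0) stop("noise SDs must be >= 0")
  list(ado_rate = ado_rate, miscall_rate = miscall_rate,
       missing_rate = missing_rate, baf_sd = baf_sd, logr_sd = logr_sd,
       logr_floor = logr_floor)
}

# genotype call from pooled B fraction (array-clustering-like thresholds)
call_from_bfrac <- function(bfrac, lo = 0.15, hi = 0.85) {
  g <- rep("AB", length(bfrac))
  g[bfrac < lo] <- "AA"
  g[bfrac > hi] <- "BB"
  g[is.na(bfrac)] <- "NC"
  g
}

new_sample_array <- function(map, sample_id, role, gtype, baf, logr) {
  out <- data.frame(snp_id = map$snp_id, gtype = gtype, baf = baf,
                    logr = logr, stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  attr(out, "role") <- role
  class(out) <- c("sample_array", "data.frame")
  out
}

#' Render a noisy SNP-array measurement of an embryo biopsy
#'
#' Pools allele counts over the sampled cells after per-cell allele drop-out.
#' Ideal BAF is B/(A+B) of the surviving alleles; ideal LogR is
#' log2(mean true copy number across sampled cells / 2), floored at
#' `logr_floor` for zero copies.  Observed values add truncated (BAF) /
#' plain (LogR) Gaussian noise.  The genotype call applies the pooled
#' B-fraction threshold rule, then miscall and missing perturbations; SNPs
#' where every allele dropped are NC with missing BAF.
#'
#' @param embryo an `"embryo_truth"` object.
#' @param map the SNP map.
#' @param cells indices of the cells in the biopsy (default: all cells).
#' @param noise a [noise_config()].
#' @param sample_id,role stored on the result.
#' @param seed integer seed.
#' @return A `"sample_array"` data.frame (`snp_id`, `gtype`, `baf`, `logr`).
#' @export
render_array <- function(embryo, map, cells = seq_along(embryo$cells),
                         noise = noise_config(), sample_id = embryo$embryo_id,
                         role = "biopsy", seed = NULL) {
  if (!length(cells)) stop("cells must be non-empty")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(map)
  nA <- nB <- copies <- numeric(n)
  chroms <- names(embryo$cells[[1]])
  for (ch in chroms) {
    idx <- chrom_idx(map, ch)
    for (ci in cells) {
      for (cp in embryo$cells[[ci]][[ch]]) {
        pres <- cp$present
        copies[idx] <- copies[idx] + pres
        keep <- if (noise$ado_rate > 0)
          pres & stats::runif(length(idx)) >= noise$ado_rate else pres
        nB[idx] <- nB[idx] + (keep & cp$alleles == 1L)
        nA[idx] <- nA[idx] + (keep & cp$alleles == 0L)
      }
    }
  }
  tot <- nA + nB
  baf_ideal <- ifelse(tot > 0, nB / tot, NA_real_)
  cn_mean <- copies / length(cells)
  logr_ideal <- ifelse(cn_mean > 0, log2(cn_mean / 2), noise$logr_floor)

  gtype <- call_from_bfrac(baf_ideal)
  called <- gtype != "NC"
  if (noise$miscall_rate > 0) {
    flip <- called & stats::runif(n) < noise$miscall_rate
    gtype[flip] <- vapply(gtype[flip], function(g)
      sample(setdiff(c("AA", "AB", "BB"), g), 1), "")
  }
  if (noise$missing_rate > 0)
    gtype[stats::runif(n) < noise$missing_rate] <- "NC"

  baf <- baf_ideal
  if (noise$baf_sd > 0)
    baf <- pmin(1, pmax(0, baf_ideal + stats::rnorm(n, 0, noise$baf_sd)))
  logr <- logr_ideal
  if (noise$logr_sd > 0) logr <- logr_ideal + stats::rnorm(n, 0, noise$logr_sd)

  new_sample_array(map, sample_id, role, gtype, baf, logr)
}

#' Render a bulk (parental) array from true haplotypes
#'
#' A diploid bulk-DNA sample: ideal BAF is 0/0.5/1 from the two true
#' alleles, ideal LogR is 0.  Bulk samples are normally rendered noise-free.
#'
#' @inheritParams render_array
#' @param truth a `"truth_haplotypes"` object.
#' @export
render_bulk <- function(truth, map, noise = noise_config(),
                        sample_id = truth$individual_id, role = "mother",
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(map)
  nB <- truth$h1 + truth$h2
  baf_ideal <- nB / 2
  gtype <- call_from_bfrac(baf_ideal)
  if (noise$missing_rate > 0)
    gtype[stats::runif(n) < noise$missing_rate] <- "NC"
  baf <- baf_ideal
  if (noise$baf_sd > 0)
    baf <- pmin(1, pmax(0, baf_ideal + stats::rnorm(n, 0, noise$baf_sd)))
  logr <- if (noise$logr_sd > 0) stats::rnorm(n, 0, noise$logr_sd) else
    numeric(n)
  new_sample_array(map, sample_id, role, gtype, baf, logr)
}

#' @export
print.sample_array <- function(x, ...) {
  cat("SNP-array sample", attr(x, "sample_id"),
      sprintf("(%s): %d SNPs, call rate %.3f\n",
              attr(x, "role"), nrow(x), call_rate(x)))
  invisible(x)
}
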