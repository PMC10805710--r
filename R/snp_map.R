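#' Default equine-like karyotype
#'
#' Chromosome lengths for a 31-autosome + X karyotype with lengths decreasing
#' linearly from 190 Mbp (chromosome 1) to 30 Mbp, an equine-like genome
#' scale.  Any named vector of positive lengths can be used in its place, so
#' exact reference-assembly lengths may be supplied by the user.
#'
#' @return Named numeric vector of chromosome lengths in bp; names are
#'   `"1"`..`"31"` and `"X"`.
#' @export
equine_karyotype <- function() {
  len <- seq(190e6, 30e6, length.out = 32)
  names(len) <- c(as.character(1:31), "X")
  len
}

#' Build a synthetic SNP-array map
#'
#' Draws SNP positions uniformly within each chromosome, with the number of
#' SNPs per chromosome proportional to chromosome length (multinomial
#' allocation, at least one SNP per chromosome).  Each SNP receives a
#' population B-allele frequency drawn uniformly from `maf_range` and flipped
#' to `1 - f` with probability 1/2 so neither allele is systematically minor.
#'
#' @param karyotype named vector of chromosome lengths in bp.
#' @param n_snps total number of SNPs; must be at least the number of
#'   chromosomes.
#' @param seed integer seed; identical seeds give identical maps.
#' @param maf_range range of the minor-allele frequency distribution.
#' @return A `data.frame` of class `"snp_map"` with columns `snp_id`,
#'   `chrom`, `pos_bp`, `bfreq`, sorted by (chrom, pos); chromosome lengths
#'   are kept in `attr(, "karyotype")`.
#' @export
build_snp_map <- function(karyotype = equine_karyotype(), n_snps = 70000,
                          seed = NULL, maf_range = c(0.05, 0.5)) {
  if (any(karyotype <= 0)) stop("chromosome lengths must be positive")
  if (n_snps < length(karyotype))
    stop("n_snps must be at least the number of chromosomes")
  if (!is.null(seed)) set.seed(seed)

  p <- karyotype / sum(karyotype)
  counts <- as.vector(stats::rmultinom(1, n_snps - length(karyotype), p)) + 1
  chrom <- rep(names(karyotype), counts)
  pos <- unlist(lapply(seq_along(karyotype), function(i) {
    sort(ceiling(stats::runif(counts[i]) * karyotype[i]))
  }), use.names = FALSE)
  f <- stats::runif(n_snps, maf_range[1], maf_range[2])
  flip <- stats::runif(n_snps) < 0.5
  f[flip] <- 1 - f[flip]

  map <- data.frame(
    snp_id = paste0("SNP_", chrom, "_", unlist(lapply(counts, seq_len))),
    chrom = chrom,
    pos_bp = as.numeric(pos),
    bfreq = f,
    stringsAsFactors = FALSE
  )
  attr(map, "karyotype") <- karyotype
  class(map) <- c("snp_map", "data.frame")
  map
}

#' @export
print.snp_map <- function(x, ...) {
  cat("SNP map:", nrow(x), "SNPs on", length(unique(x$chrom)),
      "chromosomes\n")
  invisible(x)
}

# indices of map SNPs on one chromosome
chrom_idx <- function(map, chrom) which(map$chrom == chrom)

map_karyotype <- function(map) {
  k <- attr(map, "karyotype")
  if (is.null(k)) {
    k <- tapply(map$pos_bp, map$chrom, max)
    k <- k[unique(map$chrom)]
  }
  k
}
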