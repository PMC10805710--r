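#' Control parameters for the haplarithmisis analysis
#'
#' @param penalty segmentation penalty (`"auto"` or a positive number);
#'   passed to [segment_track()].
#' @param min_seg_snps minimum informative SNPs per segment.
#' @param signature_tolerance absolute tolerance on subtrack means for
#'   haplotype-block calling.
#' @param classify_tolerance maximum weighted signature distance for a
#'   pure copy-number call.
#' @param weights length-5 weights (LogR, mat P1, mat P2, pat P1, pat P2)
#'   of the signature distance.
#' @param mosaic_range admissible aberrant-cell-fraction interval for a
#'   mosaic call.
#' @param mosaic_improvement minimum pure/mixture fit-distance ratio for a
#'   mosaic call.
#' @param min_region_snps minimum SNPs per track for a reportable
#'   sub-chromosomal region.
#' @param max_copies maximum modeled copy number.
#' @param logr_floor reported LogR for zero copies.
#' @export
haplarithm_control <- function(penalty = "auto", min_seg_snps = 5,
                               signature_tolerance = 0.1,
                               classify_tolerance = 0.1,
                               weights = c(1, 1, 1, 1, 1),
                               mosaic_range = c(0.2, 0.8),
                               mosaic_improvement = 2,
                               min_region_snps = 5, max_copies = 4,
                               logr_floor = -5) {
  list(penalty = penalty, min_seg_snps = min_seg_snps,
       signature_tolerance = signature_tolerance,
       classify_tolerance = classify_tolerance, weights = weights,
       mosaic_range = mosaic_range, mosaic_improvement = mosaic_improvement,
       min_region_snps = min_region_snps, max_copies = max_copies,
       logr_floor = logr_floor,
       signature_table = signature_table(max_copies, logr_floor))
}

#' Haplarithmisis: genome-wide haplotyping and copy-number analysis
#'
#' The central analysis.  From phased parental genotypes and the embryo
#' sample's BAF/LogR values it selects informative SNPs, builds and
#' segments the parent-specific haplarithm subtracks and the LogR track,
#' derives inherited haplotype blocks and recombination breakpoints,
#' classifies chromosome- and region-level copy number with parental
#' origin and mosaicism, calls genome-wide ploidy and embryo sex, computes
#' QC metrics, and (optionally) calls the inherited haplotypes at loci of
#' interest.
#'
#' @param embryo embryo `"sample_array"`.
#' @param mother,father parental `"sample_array"`s.
#' @param map the SNP map all samples are aligned to.
#' @param phase list with `"phased_parent"` entries `mother` and/or
#'   `father` (from [phase_with_grandparents()] or [phase_with_sibling()]).
#' @param loci data.frame of loci of interest (or `NULL` to skip PGT-M).
#' @param control a [haplarithm_control()].
#' @return Object of class `"haplarithmisis"`.
#' @export
haplarithmisis <- function(embryo, mother, father, map, phase,
                           loci = NULL, control = haplarithm_control()) {
  stopifnot(nrow(embryo) == nrow(map), nrow(mother) == nrow(map),
            nrow(father) == nrow(map))
  informative <- select_informative(embryo, mother, father, phase, map)
  qc <- qc_metrics(embryo, mother, father,
                   n_informative = nrow(informative))

  seg_mat <- segment_haplarithm(informative, "mat", map, control$penalty,
                                control$min_seg_snps)
  seg_pat <- segment_haplarithm(informative, "pat", map, control$penalty,
                                control$min_seg_snps)
  seg_lr <- segment_logr(embryo, map, control$penalty, control$min_seg_snps)

  bm <- call_blocks(seg_mat, "mat", control$signature_tolerance)
  bp <- call_blocks(seg_pat, "pat", control$signature_tolerance)
  blocks <- rbind(bm$blocks, bp$blocks)
  breakpoints <- rbind(bm$breakpoints, bp$breakpoints)

  chroms <- unique(map$chrom)
  region_calls <- NULL
  chrom_calls <- NULL
  for (ch in chroms) {
    rc <- classify_chromosome(ch, seg_lr, seg_mat, seg_pat, informative,
                              embryo, map, control)
    region_calls <- rbind(region_calls, rc)
    chrom_calls <- rbind(chrom_calls, chromosome_state(rc))
  }
  rownames(chrom_calls) <- NULL

  ploidy <- call_genome_ploidy(chrom_calls, region_calls)

  fit <- list(sample_id = attr(embryo, "sample_id"),
              role = attr(embryo, "role"),
              qc = qc, phase = phase, informative = informative,
              segments = list(mat = seg_mat, pat = seg_pat, logr = seg_lr),
              blocks = blocks, breakpoints = breakpoints,
              region_calls = region_calls, chrom_calls = chrom_calls,
              ploidy = ploidy, sex = ploidy$sex,
              karyotype = map_karyotype(map), map = map, embryo = embryo,
              control = control, locus_calls = NULL)
  class(fit) <- "haplarithmisis"
  if (!is.null(loci)) {
    fit$locus_calls <- lapply(seq_len(nrow(loci)), function(i)
      call_locus(fit, loci[i, ]))
    names(fit$locus_calls) <- loci$gene
  }
  fit
}

#' @export
print.haplarithmisis <- function(x, ...) {
  cat("Haplarithmisis analysis of sample", x$sample_id,
      sprintf("(%s)\n", x$role))
  cat(sprintf("  informative SNPs: %d, call rate %.3f, Mendelian inconsistency %.4f\n",
              x$qc$n_informative_snps, x$qc$call_rate,
              x$qc$mendelian_inconsistency_rate))
  cat("  genome:", x$ploidy$genome, "| sex:", x$sex, "\n")
  ab <- x$chrom_calls[x$chrom_calls$state != "disomy", , drop = FALSE]
  if (nrow(ab)) {
    cat("  aberrant chromosomes:\n")
    for (i in seq_len(nrow(ab)))
      cat(sprintf("    chr%-3s %s\n", ab$chrom[i], ab$state[i]))
  } else cat("  no chromosomal aberrations detected\n")
  if (!is.null(x$locus_calls)) {
    cat("  loci of interest:\n")
    for (lc in x$locus_calls) { cat("    "); print(lc) }
  }
  invisible(x)
}

#' @export
summary.haplarithmisis <- function(object, ...) {
  out <- list(sample_id = object$sample_id,
              qc = object$qc,
              genome = object$ploidy$genome,
              sex = object$sex,
              chrom_states = stats::setNames(object$chrom_calls$state,
                                             object$chrom_calls$chrom),
              n_breakpoints = nrow(object$breakpoints),
              locus_calls = object$locus_calls)
  class(out) <- "summary.haplarithmisis"
  out
}

#' @export
print.summary.haplarithmisis <- function(x, ...) {
  cat("Sample:", x$sample_id, "\n")
  print(x$qc)
  cat("genome:", x$genome, "| sex:", x$sex, "\n")
  cat("chromosome states:\n")
  st <- x$chrom_states
  for (i in seq_along(st))
    cat(sprintf("  %-3s %s\n", names(st)[i], st[i]))
  invisible(x)
}
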