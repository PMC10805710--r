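#' Determine embryo sex from the X-chromosome copy-number call
#'
#' One maternal X and no paternal X -> male; one X from each parent ->
#' female; any other configuration -> undetermined.  (The array carries no
#' Y probes; sex rests on X copy number and parental origin alone.)
#'
#' @param x_call a `"cn_call"` (or one-row data.frame) for the X chromosome.
#' @return `"male"`, `"female"` or `"undetermined"`.
#' @export
determine_sex <- function(x_call) {
  if (is.null(x_call)) return("undetermined")
  m <- x_call$maternal_copies
  p <- x_call$paternal_copies
  if (length(m) != 1 || is.na(m) || is.na(p)) return("undetermined")
  if (isTRUE(x_call$mosaic_flag)) return("undetermined")
  if (m == 1 && p == 0) return("male")
  if (m == 1 && p == 1) return("female")
  "undetermined"
}

#' Call the genome-wide ploidy state
#'
#' Pattern rules over the autosomal chromosome-level calls: a uniform
#' maternal trisomy (2 maternal + 1 paternal) is digynic triploidy, split
#' into meiotic origin when heterodisomy (both maternal homologues in one
#' region) is seen on at least one chromosome and mitotic origin (a single
#' duplicated maternal genotype) when it is not; the paternal pattern gives
#' diandric triploidy; uniform single-parent monosomy gives gynogenetic /
#' androgenetic haploidy; two copies all from one parent give genome-wide
#' uniparental disomy.  A pattern must cover at least `min_frac` of the
#' called autosomes.  Widespread aberrations matching no pattern are
#' `complex`; otherwise the genome is biparental diploid (chromosome-level
#' aneuploidies are reported separately).
#'
#' @param chrom_calls data.frame of chromosome-level calls (one row per
#'   chromosome, columns as produced by [classify_segment()] plus `chrom`).
#' @param region_calls data.frame of region-level calls (used for the
#'   heterodisomy check; may equal `chrom_calls`).
#' @param min_frac pattern-coverage threshold.
#' @return list of class `"ploidy_call"`: `genome`, `sex`, `n_called`,
#'   `n_matching`.
#' @export
call_genome_ploidy <- function(chrom_calls, region_calls = chrom_calls,
                               min_frac = 0.9) {
  aut <- chrom_calls[chrom_calls$chrom != "X", , drop = FALSE]
  called <- aut[!(aut$state %in% c("undetermined")) &
                  !is.na(aut$maternal_copies), , drop = FALSE]
  xcall <- chrom_calls[chrom_calls$chrom == "X", , drop = FALSE]
  sex <- determine_sex(if (nrow(xcall)) xcall[1, ] else NULL)
  n_aut <- nrow(aut)
  if (n_aut == 0 || nrow(called) / n_aut < 0.9) {
    out <- list(genome = "undetermined", sex = sex,
                n_called = nrow(called), n_matching = 0L,
                reason = "insufficient chromosome coverage")
    class(out) <- "ploidy_call"
    return(out)
  }
  m <- called$maternal_copies
  p <- called$paternal_copies
  frac <- function(cond) sum(cond) / nrow(called)
  raut <- region_calls[region_calls$chrom != "X", , drop = FALSE]
  hetero_mat <- any(raut$m1 >= 1 & raut$m2 >= 1, na.rm = TRUE)
  hetero_pat <- any(raut$p1 >= 1 & raut$p2 >= 1, na.rm = TRUE)

  genome <- "biparental_diploid"
  n_matching <- sum(m == 1 & p == 1)
  if (frac(m == 2 & p == 1) >= min_frac) {
    genome <- if (hetero_mat) "digynic_triploid_meiotic"
              else "digynic_triploid_mitotic"
    n_matching <- sum(m == 2 & p == 1)
  } else if (frac(m == 1 & p == 2) >= min_frac) {
    genome <- "diandric_triploid"
    n_matching <- sum(m == 1 & p == 2)
  } else if (frac(m == 1 & p == 0) >= min_frac) {
    genome <- "gynogenetic_haploid"
    n_matching <- sum(m == 1 & p == 0)
  } else if (frac(m == 0 & p == 1) >= min_frac) {
    genome <- "androgenetic_haploid"
    n_matching <- sum(m == 0 & p == 1)
  } else if (frac(m == 2 & p == 0) >= min_frac) {
    genome <- "gw_maternal_UPD"
    n_matching <- sum(m == 2 & p == 0)
  } else if (frac(m == 0 & p == 2) >= min_frac) {
    genome <- "gw_paternal_UPD"
    n_matching <- sum(m == 0 & p == 2)
  } else if (frac(m != 1 | p != 1) >= 0.5) {
    genome <- "complex"
    n_matching <- sum(m != 1 | p != 1)
  }
  out <- list(genome = genome, sex = sex, n_called = nrow(called),
              n_matching = n_matching, reason = NULL)
  class(out) <- "ploidy_call"
  out
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat(sprintf("genome: %s, sex: %s (%d/%d autosomes matching)\n",
              x$genome, x$sex, x$n_matching, x$n_called))
  invisible(x)
}

#' Classify the meiotic/mitotic origin of chromosomal events across samples
#'
#' Compares chromosome-level aberration events (chromosome, state,
#' maternal/paternal copies) across several samples of one embryo.  For a
#' trophectoderm biopsy with its whole blastocyst: an event shared by all
#' samples is meiotic (present in all cells); an event seen only in the
#' biopsy is low-grade mosaic (present in a small fraction of cells).  For
#' a set of single blastomeres: events in every blastomere are meiotic,
#' events in a strict subset are mitotic.  With a single sample every event
#' is of undetermined origin.
#'
#' @param calls named list of chromosome-call data.frames (one per sample).
#' @param roles character vector of sample roles, parallel to `calls`
#'   (`"biopsy"`, `"blastocyst"`, `"blastomere"`).
#' @return data.frame with `chrom`, `state`, `samples`, `origin`.
#' @export
classify_event_origin <- function(calls, roles = names(calls)) {
  stopifnot(length(calls) >= 1)
  events <- lapply(calls, function(cc) {
    sel <- !(cc$state %in% c("disomy", "undetermined")) &
      !startsWith(cc$state, "partial:disomy")
    paste(cc$chrom[sel], cc$state[sel], sep = "|")
  })
  all_ev <- unique(unlist(events))
  if (!length(all_ev))
    return(data.frame(chrom = character(), state = character(),
                      samples = character(), origin = character(),
                      stringsAsFactors = FALSE))
  origin <- vapply(all_ev, function(e) {
    inwhich <- vapply(events, function(v) e %in% v, TRUE)
    if (length(calls) == 1L) return("undetermined")
    if (all(inwhich)) return("meiotic")
    if (any(roles == "blastocyst")) {
      # biopsy + blastocyst design
      if (any(inwhich & roles == "biopsy") &&
          !any(inwhich & roles == "blastocyst"))
        return("low_grade_mosaic")
      return("undetermined")
    }
    "mitotic"                          # strict subset of blastomeres
  }, "")
  parts <- strsplit(all_ev, "|", fixed = TRUE)
  data.frame(
    chrom = vapply(parts, `[[`, "", 1),
    state = vapply(parts, `[[`, "", 2),
    samples = vapply(all_ev, function(e)
      paste(names(calls)[vapply(events, function(v) e %in% v, TRUE)],
            collapse = ","), ""),
    origin = unname(origin), stringsAsFactors = FALSE, row.names = NULL)
}
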