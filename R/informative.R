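#' Select informative SNPs and compute haplarithm subtrack values
#'
#' A SNP is informative for the maternal track when the mother is AB and
#' phased, the father is homozygous, and the embryo BAF is present (the
#' embryo's discrete call is irrelevant: the BAF carries the signal); the
#' paternal track is symmetric.  The subtrack is P1 when the target parent's
#' H1 allele differs from the other parent's homozygous allele, else P2, and
#' the haplarithm value is `f = |embryo_baf - b0|` with `b0 = 0` if the
#' other parent is AA and `b0 = 1` if BB.  Under biparental disomy the
#' subtrack carrying the inherited homologue sits at 0.5 and the other at 0.
#'
#' @param embryo,mother,father `"sample_array"` objects on one map.
#' @param phase list with `"phased_parent"` entries `mother` and/or `father`
#'   (a missing entry disables that parent's track).
#' @param map the SNP map.
#' @return data.frame (`idx`, `chrom`, `pos_bp`, `parent`, `subtrack`, `f`).
#' @export
select_informative <- function(embryo, mother, father, phase, map) {
  one_track <- function(target, other, ph, parent) {
    if (is.null(ph)) return(NULL)
    sel <- which(target$gtype == "AB" & !is.na(ph$h1_allele) &
                   other$gtype %in% c("AA", "BB") & !is.na(embryo$baf))
    if (!length(sel)) return(NULL)
    other_allele <- substr(other$gtype[sel], 1, 1)
    b0 <- ifelse(other_allele == "A", 0, 1)
    data.frame(idx = sel, chrom = map$chrom[sel], pos_bp = map$pos_bp[sel],
               parent = parent,
               subtrack = ifelse(ph$h1_allele[sel] != other_allele,
                                 "P1", "P2"),
               f = abs(embryo$baf[sel] - b0), stringsAsFactors = FALSE)
  }
  out <- rbind(one_track(mother, father, phase$mother, "mat"),
               one_track(father, mother, phase$father, "pat"))
  if (is.null(out))
    out <- data.frame(idx = integer(), chrom = character(),
                      pos_bp = numeric(), parent = character(),
                      subtrack = character(), f = numeric(),
                      stringsAsFactors = FALSE)
  out[order(out$parent, match(out$chrom, unique(map$chrom)), out$pos_bp), ,
      drop = FALSE]
}
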