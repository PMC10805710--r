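#' Call inherited haplotype blocks from haplarithm segments
#'
#' Per segment the inherited parental homologue follows from the joint
#' P1/P2 pattern: under disomy the subtrack carrying the inherited
#' homologue sits at 0.5 and the other at 0, so (P1 high, P2 ~ 0) -> H1 and
#' (P1 ~ 0, P2 high) -> H2 (the same logic covers single-homologue trisomy
#' levels 2/3 and 3/4); two comparable non-zero levels -> `both`
#' (heterodisomy, e.g. 1/3 and 1/3 under a meiosis-I error); both ~ 0 ->
#' `none` (loss of that parent's contribution); anything else ->
#' `undetermined`.  Adjacent segments with the same call are merged;
#' recombination breakpoints are the H1 <-> H2 transitions, positioned at
#' the midpoint between the flanking segments.
#'
#' @param segments output of [segment_haplarithm()] for one parent.
#' @param parent `"mat"` or `"pat"`.
#' @param signature_tolerance absolute tolerance on subtrack means.
#' @return list with `blocks` (data.frame `chrom`, `start_bp`, `end_bp`,
#'   `parent`, `inherited`, `support`) and `breakpoints` (data.frame
#'   `chrom`, `parent`, `pos_bp`).
#' @export
call_blocks <- function(segments, parent, signature_tolerance = 0.1) {
  tol <- signature_tolerance
  if (is.null(segments) || !nrow(segments))
    return(list(blocks = data.frame(), breakpoints = data.frame()))
  p1 <- segments$mean_P1
  p2 <- segments$mean_P2
  p1[is.na(p1)] <- 0; p2[is.na(p2)] <- 0
  inh <- rep("undetermined", nrow(segments))
  inh[p1 < tol & p2 < tol] <- "none"
  inh[abs(p1 - p2) < tol & pmin(p1, p2) > tol] <- "both"
  inh[p2 < tol & p1 >= 0.25] <- "H1"
  inh[p1 < tol & p2 >= 0.25] <- "H2"

  blocks <- NULL
  bps <- NULL
  for (ch in unique(segments$chrom)) {
    sel <- which(segments$chrom == ch)
    s <- segments[sel, , drop = FALSE]
    calls <- inh[sel]
    run <- rle(calls)
    ends <- cumsum(run$lengths)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    b <- data.frame(chrom = ch,
                    start_bp = s$start_bp[starts],
                    end_bp = s$end_bp[ends],
                    parent = parent, inherited = run$values,
                    support = vapply(seq_along(starts), function(i)
                      sum(s$n_P1[starts[i]:ends[i]] +
                            s$n_P2[starts[i]:ends[i]]), 0L),
                    stringsAsFactors = FALSE)
    blocks <- rbind(blocks, b)
    if (nrow(b) > 1) {
      for (i in seq_len(nrow(b) - 1L)) {
        a <- b$inherited[i]; z <- b$inherited[i + 1L]
        if ((a == "H1" && z == "H2") || (a == "H2" && z == "H1")) {
          # the breakpoint is localized only to the gap between the
          # flanking informative SNPs; keep that uncertainty interval
          bps <- rbind(bps, data.frame(
            chrom = ch, parent = parent,
            pos_bp = (b$end_bp[i] + b$start_bp[i + 1L]) / 2,
            lo_bp = b$end_bp[i], hi_bp = b$start_bp[i + 1L],
            stringsAsFactors = FALSE))
        }
      }
    }
  }
  list(blocks = blocks,
       breakpoints = bps %||% data.frame(chrom = character(),
                                         parent = character(),
                                         pos_bp = numeric(),
                                         lo_bp = numeric(),
                                         hi_bp = numeric(),
                                         stringsAsFactors = FALSE))
}
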