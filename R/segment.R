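#' Joint piecewise-constant segmentation of ordered track values
#'
#' Penalised least-squares changepoint detection (PELT) minimising the
#' within-segment sum of squared deviations plus `penalty` per segment.
#' Points may belong to different subtracks (e.g. haplarithm P1/P2); the
#' cost sums per-subtrack squared error within each segment so the
#' subtracks share breakpoints.  `penalty = "auto"` uses a BIC-like value
#' `4 * d * sigma2 * log(n)` with `sigma2` estimated robustly from
#' first differences within each subtrack (floored at 1e-8 so noise-free
#' tracks segment only at exact level changes).
#'
#' @param pos positions (bp), non-decreasing.
#' @param values numeric track values at `pos`.
#' @param track subtrack membership (integers 1..d or character labels).
#' @param penalty positive number or `"auto"`.
#' @param min_seg_snps minimum points (all subtracks combined) per segment.
#' @return data.frame of segments: `start_idx`, `end_idx`, `start_bp`,
#'   `end_bp`, per-subtrack counts `n_<t>` and means `mean_<t>`, and
#'   `low_support` flag when a chromosome had fewer than `min_seg_snps`
#'   points.
#' @export
segment_track <- function(pos, values, track = rep(1L, length(values)),
                          penalty = "auto", min_seg_snps = 5) {
  stopifnot(length(pos) == length(values), length(track) == length(values))
  lv <- sort(unique(track))
  tr0 <- match(track, lv) - 1L
  d <- length(lv)
  n <- length(values)
  if (n == 0) return(NULL)

  if (identical(penalty, "auto")) {
    s2 <- vapply(seq_len(d), function(t) {
      v <- values[tr0 == t - 1L]
      if (length(v) < 3) return(0)
      (stats::mad(diff(v)) / sqrt(2))^2
    }, 0)
    penalty <- max(1e-8, 4 * d * mean(s2) * log(n))
  }
  low <- n < min_seg_snps
  ends <- if (low) n else
    pelt_segment(values, tr0, d, penalty, as.integer(min_seg_snps))
  starts <- c(1L, utils::head(ends, -1L) + 1L)

  seg <- data.frame(start_idx = starts, end_idx = ends,
                    start_bp = pos[starts], end_bp = pos[ends])
  for (t in seq_len(d)) {
    inb <- function(i) {
      sel <- tr0[starts[i]:ends[i]] == t - 1L
      values[starts[i]:ends[i]][sel]
    }
    vals <- lapply(seq_along(starts), inb)
    seg[[paste0("n_", lv[t])]] <- vapply(vals, length, 0L)
    seg[[paste0("mean_", lv[t])]] <-
      vapply(vals, function(v) if (length(v)) mean(v) else NA_real_, 0)
  }
  seg$low_support <- low
  seg
}

#' Segment a haplarithm (per parent, per chromosome)
#'
#' Applies [segment_track()] jointly to the P1/P2 subtracks of one parent's
#' informative SNPs, chromosome by chromosome.
#'
#' @param informative output of [select_informative()].
#' @param parent `"mat"` or `"pat"`.
#' @param map the SNP map.
#' @param penalty,min_seg_snps see [segment_track()].
#' @return data.frame of segments with columns `chrom`, `start_bp`,
#'   `end_bp`, `n_P1`, `n_P2`, `mean_P1`, `mean_P2`, `low_support`.
#' @export
segment_haplarithm <- function(informative, parent, map, penalty = "auto",
                               min_seg_snps = 5) {
  inf <- informative[informative$parent == parent, , drop = FALSE]
  out <- lapply(unique(map$chrom), function(ch) {
    x <- inf[inf$chrom == ch, , drop = FALSE]
    if (!nrow(x)) return(NULL)
    seg <- segment_track(x$pos_bp, x$f, x$subtrack, penalty, min_seg_snps)
    for (col in c("n_P1", "n_P2", "mean_P1", "mean_P2"))
      if (is.null(seg[[col]]))
        seg[[col]] <- if (startsWith(col, "n_")) 0L else NA_real_
    cbind(chrom = ch, seg[c("start_bp", "end_bp", "n_P1", "n_P2",
                            "mean_P1", "mean_P2", "low_support")],
          stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Segment the genome-wide LogR track
#'
#' Piecewise-constant least-squares segmentation of the embryo LogR values
#' ordered by position, chromosome by chromosome (the copy-number track of
#' the haplarithm plot).
#'
#' @param embryo a `"sample_array"`.
#' @param map the SNP map.
#' @param penalty,min_seg_snps see [segment_track()].
#' @return data.frame with `chrom`, `start_bp`, `end_bp`, `n`, `mean_logr`,
#'   `low_support`.
#' @export
segment_logr <- function(embryo, map, penalty = "auto", min_seg_snps = 5) {
  out <- lapply(unique(map$chrom), function(ch) {
    sel <- which(map$chrom == ch & !is.na(embryo$logr))
    if (!length(sel)) return(NULL)
    seg <- segment_track(map$pos_bp[sel], embryo$logr[sel],
                         penalty = penalty, min_seg_snps = min_seg_snps)
    data.frame(chrom = ch, start_bp = seg$start_bp, end_bp = seg$end_bp,
               n = seg$n_1, mean_logr = seg$mean_1,
               low_support = seg$low_support, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
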