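# Join the LogR and parental haplarithm segmentations of one chromosome on
# the union of their breakpoints and classify each region.  Every region
# between consecutive union breakpoints lies inside exactly one segment of
# each track, so the region's observables are that segment's (stable,
# full-segment) means; adjacent regions whose calls agree are then merged,
# which collapses pure crossovers (homologue switches that do not change
# copy number) back into one chromosome-level call.
classify_chromosome <- function(chrom, logr_seg, mat_seg, pat_seg,
                                informative, embryo, map, control) {
  tab <- control$signature_table
  kar <- map_karyotype(map)
  pick <- function(seg) {
    if (is.null(seg)) return(NULL)
    s <- seg[seg$chrom == chrom, , drop = FALSE]
    if (nrow(s)) s else NULL
  }
  lr <- pick(logr_seg); ms <- pick(mat_seg); ps <- pick(pat_seg)
  inner_bp <- function(s) {
    if (is.null(s) || nrow(s) < 2) return(numeric())
    (s$end_bp[-nrow(s)] + s$start_bp[-1]) / 2
  }
  cuts <- sort(unique(c(inner_bp(lr), inner_bp(ms), inner_bp(ps))))
  bounds <- c(0, cuts, kar[[chrom]] + 1)

  seg_at <- function(s, mid) {
    if (is.null(s)) return(NULL)
    i <- findInterval(mid, s$start_bp)
    s[max(1L, i), , drop = FALSE]
  }

  regions <- lapply(seq_len(length(bounds) - 1L), function(i) {
    mid <- (bounds[i] + bounds[i + 1L]) / 2
    l <- seg_at(lr, mid); m <- seg_at(ms, mid); p <- seg_at(ps, mid)
    call <- classify_segment(
      if (is.null(l)) NA_real_ else l$mean_logr,
      if (is.null(m)) c(NA_real_, NA_real_) else c(m$mean_P1, m$mean_P2),
      if (is.null(p)) c(NA_real_, NA_real_) else c(p$mean_P1, p$mean_P2),
      tab, tolerance = control$classify_tolerance,
      weights = control$weights, mosaic_range = control$mosaic_range,
      mosaic_improvement = control$mosaic_improvement)
    c(list(chrom = chrom, start_bp = max(1, ceiling(bounds[i])),
           end_bp = min(kar[[chrom]], floor(bounds[i + 1L]))),
      unclass(call))
  })

  df <- do.call(rbind, lapply(regions, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  # merge adjacent regions that agree on copy number (homologue
  # composition may change at crossovers without changing the state)
  key <- paste(ifelse(df$state %in% c("undetermined",
                                      "undefined_parental_origin"),
                      df$state, ""),
               df$maternal_copies, df$paternal_copies, df$mosaic_flag)
  run <- rle(key)
  ends <- cumsum(run$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  merged <- df[starts, , drop = FALSE]
  merged$end_bp <- df$end_bp[ends]
  merged$fit_distance <- vapply(seq_along(starts), function(i)
    max(df$fit_distance[starts[i]:ends[i]]), 0)
  rownames(merged) <- NULL
  merged
}

# chromosome-level summary of region calls: the single call if uniform.
# Regions disagreeing with the dominant call are tolerated when they cover
# at most 10% of the chromosome (short terminal segments around crossovers
# near chromosome ends carry too few informative SNPs for stable means);
# otherwise the chromosome is reported as partial.
chromosome_state <- function(region_calls) {
  if (nrow(region_calls) == 1L) {
    out <- region_calls
    out$partial <- FALSE
    return(out)
  }
  span <- region_calls$end_bp - region_calls$start_bp
  key <- paste(ifelse(region_calls$state %in%
                        c("undetermined", "undefined_parental_origin"),
                      region_calls$state, ""),
               region_calls$maternal_copies,
               region_calls$paternal_copies, region_calls$mosaic_flag)
  dom <- names(sort(tapply(span, key, sum), decreasing = TRUE))[1]
  other_span <- sum(span[key != dom])
  i <- which(key == dom)[1]
  out <- region_calls[i, , drop = FALSE]
  out$start_bp <- min(region_calls$start_bp)
  out$end_bp <- max(region_calls$end_bp)
  if (other_span / sum(span) <= 0.1) {
    out$partial <- FALSE
  } else {
    out$state <- paste0("partial:", paste(unique(region_calls$state),
                                          collapse = "/"))
    out$partial <- TRUE
  }
  out
}
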