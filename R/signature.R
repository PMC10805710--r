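#' Expected measurement signatures of copy-number configurations
#'
#' Enumerates configurations c = (m1, m2, p1, p2): copy counts of the two
#' maternal and two paternal homologues, total n = m1+m2+p1+p2 up to
#' `max_copies`.  Expected values follow the array measurement model:
#' LogR = log2(n/2) (so -1, log2(3/2) = 0.58, 1 for monosomy, trisomy,
#' tetrasomy; `logr_floor` for nullisomy) and the haplarithm subtrack
#' levels are the homologue's allele share m1/n, m2/n, p1/n, p2/n (0 and
#' 0.5 for biparental disomy; level sets {0, 1/3, 2/3} for trisomy and
#' {0, 1/4, 1/2, 3/4} for tetrasomy).
#'
#' @param max_copies maximum modeled total copy number (higher true copy
#'   numbers collapse onto the nearest modeled signature).
#' @param logr_floor reported LogR for zero copies.
#' @return data.frame with columns `m1`, `m2`, `p1`, `p2`, `n`, `logr`,
#'   `mat_P1`, `mat_P2`, `pat_P1`, `pat_P2`, `state`, and `copy_change`
#'   (total homologue-count change from biparental disomy, used for
#'   tie-breaking).
#' @export
signature_table <- function(max_copies = 4, logr_floor = -5) {
  g <- expand.grid(m1 = 0:max_copies, m2 = 0:max_copies,
                   p1 = 0:max_copies, p2 = 0:max_copies)
  g <- g[rowSums(g) <= max_copies, ]
  n <- rowSums(g)
  tab <- data.frame(g, n = n,
                    logr = ifelse(n > 0, log2(n / 2), logr_floor),
                    mat_P1 = ifelse(n > 0, g$m1 / n, 0),
                    mat_P2 = ifelse(n > 0, g$m2 / n, 0),
                    pat_P1 = ifelse(n > 0, g$p1 / n, 0),
                    pat_P2 = ifelse(n > 0, g$p2 / n, 0))
  tab$state <- state_label(tab$m1, tab$m2, tab$p1, tab$p2)
  # distance from the disomy configurations in homologue-count space,
  # minimised over the H1/H2 labelling of the disomic state
  cc <- function(m1, m2, p1, p2) {
    dm <- pmin(abs(m1 - 1) + m2, m1 + abs(m2 - 1))
    dp <- pmin(abs(p1 - 1) + p2, p1 + abs(p2 - 1))
    dm + dp
  }
  tab$copy_change <- cc(tab$m1, tab$m2, tab$p1, tab$p2)
  # maternal-before-paternal tie-break key: maternal aberrations sort first
  tab$mat_first <- with(tab, pmin(abs(p1 - 1) + p2, p1 + abs(p2 - 1)))
  rownames(tab) <- NULL
  tab
}

# human-readable state labels from homologue copy counts
state_label <- function(m1, m2, p1, p2) {
  m <- m1 + m2; p <- p1 + p2; n <- m + p
  lab <- character(length(n))
  for (i in seq_along(n)) {
    if (n[i] == 0) { lab[i] <- "nullisomy"; next }
    if (m[i] == 1 && p[i] == 1) { lab[i] <- "disomy"; next }
    if (m[i] == 2 && p[i] == 0) {
      lab[i] <- if (m1[i] == 1) "maternal_UPD_hetero" else "maternal_UPD_iso"
      next
    }
    if (p[i] == 2 && m[i] == 0) {
      lab[i] <- if (p1[i] == 1) "paternal_UPD_hetero" else "paternal_UPD_iso"
      next
    }
    parts <- character()
    if (m[i] == 0) parts <- c(parts, "maternal_loss")
    if (p[i] == 0) parts <- c(parts, "paternal_loss")
    if (m[i] > 1) parts <- c(parts, "maternal_gain")
    if (p[i] > 1) parts <- c(parts, "paternal_gain")
    lab[i] <- paste(parts, collapse = "+")
  }
  lab
}

# signature vector of one table row (or of a mixture)
sig_vec <- function(row) {
  c(row$logr, row$mat_P1, row$mat_P2, row$pat_P1, row$pat_P2)
}

# physical mixture of a disomic and an aberrant cell population:
# fraction rho of cells disomic (config d), 1 - rho aberrant (config c).
# Copy numbers average over cells; subtrack levels are allele-count
# weighted, i.e. (rho * k_d + (1 - rho) * k_c) / nbar.
mixture_signature <- function(dis, ab, rho, logr_floor = -5) {
  nbar <- 2 * rho + ab$n * (1 - rho)
  counts_d <- c(dis$m1, dis$m2, dis$p1, dis$p2)
  counts_a <- c(ab$m1, ab$m2, ab$p1, ab$p2)
  k <- rho * counts_d + (1 - rho) * counts_a
  logr <- if (nbar > 0) log2(nbar / 2) else logr_floor
  c(logr, if (nbar > 0) k / nbar else rep(0, 4))
}

#' Classify one segment's copy-number configuration
#'
#' Finds the configuration whose expected signature (LogR plus the four
#' haplarithm subtrack levels) is nearest to the observed segment means by
#' weighted Euclidean distance.  If the best pure configuration fits within
#' `tolerance` it is called directly.  Otherwise a two-component mixture of
#' disomic and aberrant cells is fitted over the aberrant fraction (the
#' measurement model for mosaicism in a multicell biopsy); if the mixture
#' improves the fit by at least `mosaic_improvement`-fold and the estimated
#' aberrant fraction lies in `mosaic_range`, the segment is called mosaic
#' for the aberrant configuration.  Failing that, a clear LogR deviation
#' without subtrack confirmation is reported as
#' `"undefined_parental_origin"`, anything else as `"undetermined"`.
#' Equidistant configurations prefer the smaller change from disomy, then
#' maternal before paternal.
#'
#' @param logr_mean observed segment LogR mean.
#' @param mat_means,pat_means numeric length-2 vectors of the P1/P2
#'   subtrack means (NA allowed; missing observables are dropped from the
#'   distance and from the call's confidence).
#' @param table a [signature_table()].
#' @param tolerance maximum weighted distance for a pure-state call.
#' @param weights length-5 weights for (logr, mat P1, mat P2, pat P1,
#'   pat P2).
#' @param mosaic_range admissible aberrant-fraction interval for a mosaic
#'   call.
#' @param mosaic_improvement minimum pure/mixture distance ratio.
#' @return list of class `"cn_call"`: `state`, `m1`, `m2`, `p1`, `p2`,
#'   `maternal_copies`, `paternal_copies`, `mosaic_flag`,
#'   `mosaic_fraction`, `fit_distance`.
#' @export
classify_segment <- function(logr_mean, mat_means, pat_means,
                             table = signature_table(), tolerance = 0.1,
                             weights = c(1, 1, 1, 1, 1),
                             mosaic_range = c(0.2, 0.8),
                             mosaic_improvement = 2) {
  obs <- c(logr_mean, mat_means, pat_means)
  use <- !is.na(obs)
  w <- weights[use]
  sig <- as.matrix(table[, c("logr", "mat_P1", "mat_P2", "pat_P1",
                             "pat_P2")])[, use, drop = FALSE]
  d2 <- colSums(w * (t(sig) - obs[use])^2)
  dist <- sqrt(d2)
  ord <- order(round(dist, 9), table$copy_change, table$mat_first)
  best <- ord[1]
  mk <- function(i, mosaic = FALSE, frac = NA_real_, fdist) {
    out <- list(state = table$state[i],
                m1 = table$m1[i], m2 = table$m2[i],
                p1 = table$p1[i], p2 = table$p2[i],
                maternal_copies = table$m1[i] + table$m2[i],
                paternal_copies = table$p1[i] + table$p2[i],
                mosaic_flag = mosaic, mosaic_fraction = frac,
                fit_distance = fdist)
    class(out) <- "cn_call"
    out
  }
  if (dist[best] <= tolerance)
    return(mk(best, fdist = dist[best]))

  # mixture fit: every aberrant configuration against every disomy variant
  dis_idx <- which(table$state == "disomy")
  ab_idx <- which(table$state != "disomy")
  bestmix <- list(dist = Inf)
  for (ai in ab_idx) {
    ab <- table[ai, ]
    for (di in dis_idx) {
      dis <- table[di, ]
      fdist <- function(phi) {
        e <- mixture_signature(dis, ab, 1 - phi)[use]
        sqrt(sum(w * (e - obs[use])^2))
      }
      op <- stats::optimize(fdist, c(0, 1))
      if (op$objective < bestmix$dist)
        bestmix <- list(dist = op$objective, frac = op$minimum, ab = ai)
    }
  }
  if (is.finite(bestmix$dist) && bestmix$dist <= tolerance &&
      dist[best] / max(bestmix$dist, 1e-12) >= mosaic_improvement &&
      bestmix$frac >= mosaic_range[1] && bestmix$frac <= mosaic_range[2]) {
    call <- mk(bestmix$ab, mosaic = TRUE, frac = bestmix$frac,
               fdist = bestmix$dist)
    call$state <- paste0("mosaic_", call$state)
    return(call)
  }
  # LogR shows an aberration the subtracks do not confirm
  subtr_obs <- obs[-1][!is.na(obs[-1])]
  if (!is.na(logr_mean) && abs(logr_mean) > 2.5 * tolerance) {
    out <- mk(best, fdist = dist[best])
    out$state <- "undefined_parental_origin"
    out$m1 <- out$m2 <- out$p1 <- out$p2 <- NA_integer_
    out$maternal_copies <- out$paternal_copies <- NA_integer_
    return(out)
  }
  out <- mk(best, fdist = dist[best])
  out$state <- "undetermined"
  out
}
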