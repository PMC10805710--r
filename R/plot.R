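# cumulative genome coordinates for genome-wide panels
genome_coords <- function(karyotype, chroms = names(karyotype)) {
  len <- karyotype[chroms]
  offs <- c(0, cumsum(as.numeric(len)))[seq_along(len)]
  names(offs) <- chroms
  list(offsets = offs, total = sum(as.numeric(len)), lengths = len)
}

block_col <- function(parent, inherited) {
  pal <- list(mat = c(H1 = "#f8a5c2", H2 = "#c0392b"),   # pink / red
              pat = c(H1 = "#aed6f1", H2 = "#1a5276"))   # light / dark blue
  other <- c(both = "#9b59b6", none = "grey85", undetermined = "grey60")
  ifelse(inherited %in% c("H1", "H2"), pal[[parent]][inherited],
         other[inherited])
}

#' Plot a haplarithm (five stacked panels)
#'
#' From top to bottom: genome-wide LogR (copy-number track), the maternal
#' haplarithm subtracks (Mat-BAF; P1 dark, P2 light), the maternally
#' inherited haplotype blocks (pink/red = maternal homologue 1/2), the
#' paternal subtracks (Pat-BAF) and the paternally inherited blocks
#' (light/dark blue = paternal homologue 1/2).  Loci of interest are
#' marked by vertical lines.
#'
#' @param x a `"haplarithmisis"` object.
#' @param chrom optional chromosome label to restrict the plot.
#' @param loci optional loci to mark.
#' @param ... ignored.
#' @export
plot.haplarithmisis <- function(x, chrom = NULL, loci = NULL, ...) {
  chroms <- if (is.null(chrom)) names(x$karyotype) else chrom
  gc <- genome_coords(x$karyotype, chroms)
  tx <- function(ch, pos) gc$offsets[[ch]] + pos
  op <- graphics::par(mfrow = c(5, 1), mar = c(1.5, 4, 0.8, 1),
                      oma = c(2, 0, 2, 0))
  on.exit(graphics::par(op))

  draw_marks <- function() {
    if (is.null(loci)) return()
    sel <- loci[loci$chrom %in% chroms, , drop = FALSE]
    if (nrow(sel))
      graphics::abline(v = mapply(tx, sel$chrom,
                                  (sel$start_bp + sel$end_bp) / 2),
                       col = "goldenrod1", lwd = 2)
  }
  draw_bounds <- function() {
    if (length(chroms) > 1)
      graphics::abline(v = cumsum(as.numeric(gc$lengths)), col = "grey80")
  }

  # LogR
  sel <- x$map$chrom %in% chroms
  graphics::plot(mapply(tx, x$map$chrom[sel], x$map$pos_bp[sel]),
                 x$embryo$logr[sel], pch = ".", col = "grey40",
                 xlim = c(0, gc$total), ylim = c(-2, 2), xlab = "",
                 ylab = "LogR", xaxt = "n")
  graphics::abline(h = 0, col = "grey70")
  lr <- x$segments$logr[x$segments$logr$chrom %in% chroms, , drop = FALSE]
  graphics::segments(mapply(tx, lr$chrom, lr$start_bp),
                     lr$mean_logr,
                     mapply(tx, lr$chrom, lr$end_bp), lr$mean_logr,
                     col = "red", lwd = 2)
  draw_bounds(); draw_marks()
  graphics::mtext(paste("Haplarithm:", x$sample_id), outer = TRUE, line = 0.5)

  for (par in c("mat", "pat")) {
    inf <- x$informative[x$informative$parent == par &
                           x$informative$chrom %in% chroms, , drop = FALSE]
    cols <- if (par == "mat") c(P1 = "#c0392b", P2 = "#f8a5c2")
            else c(P1 = "#1a5276", P2 = "#aed6f1")
    graphics::plot(mapply(tx, inf$chrom, inf$pos_bp), inf$f, pch = ".",
                   col = cols[inf$subtrack], xlim = c(0, gc$total),
                   ylim = c(0, 1), xlab = "",
                   ylab = paste0(toupper(substr(par, 1, 1)),
                                 substr(par, 2, 3), "-BAF"), xaxt = "n")
    sg <- x$segments[[par]]
    sg <- sg[sg$chrom %in% chroms, , drop = FALSE]
    for (st in c("P1", "P2"))
      graphics::segments(mapply(tx, sg$chrom, sg$start_bp),
                         sg[[paste0("mean_", st)]],
                         mapply(tx, sg$chrom, sg$end_bp),
                         sg[[paste0("mean_", st)]],
                         col = cols[st], lwd = 2)
    draw_bounds(); draw_marks()

    bl <- x$blocks[x$blocks$parent == par & x$blocks$chrom %in% chroms, ,
                   drop = FALSE]
    graphics::plot(NA, xlim = c(0, gc$total), ylim = c(0, 1), xlab = "",
                   ylab = paste(par, "blocks"), xaxt = "n", yaxt = "n")
    if (nrow(bl))
      graphics::rect(mapply(tx, bl$chrom, bl$start_bp), 0.2,
                     mapply(tx, bl$chrom, bl$end_bp), 0.8,
                     col = block_col(par, bl$inherited), border = NA)
    draw_bounds(); draw_marks()
  }
  invisible(x)
}

#' Write a haplarithm figure to a file
#'
#' @param fit a `"haplarithmisis"` object.
#' @param path output PNG path.
#' @param chrom optional chromosome restriction.
#' @param loci optional loci to mark.
#' @param width,height,res PNG device parameters (fixed for deterministic
#'   rendering).
#' @export
plot_haplarithm <- function(fit, path, chrom = NULL, loci = NULL,
                            width = 1600, height = 1000, res = 120) {
  grDevices::png(path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  plot(fit, chrom = chrom, loci = loci)
  invisible(path)
}

state_col <- function(state) {
  base <- c(disomy = "grey92",
            maternal_loss = "#e74c3c", paternal_loss = "#3498db",
            maternal_gain = "#f39c12", paternal_gain = "#2980b9",
            nullisomy = "black",
            maternal_UPD_hetero = "#8e44ad", maternal_UPD_iso = "#9b59b6",
            paternal_UPD_hetero = "#16a085", paternal_UPD_iso = "#1abc9c",
            undefined_parental_origin = "#27ae60",   # green, by convention
            undetermined = "grey70")
  out <- base[state]
  out[startsWith(state, "mosaic_")] <- "#f5b7b1"
  out[startsWith(state, "partial:")] <- "#f0e68c"
  out[is.na(out)] <- "grey50"
  out
}

#' Circos-style per-sample chromosome-state summary
#'
#' Concentric rings (one per sample, outermost first) over chromosomes
#' 1..X; ring sectors are coloured by the chromosome-level state, with
#' green marking errors of undefined parental origin.
#'
#' @param calls named list of chromosome-call data.frames.
#' @param path output PNG path.
#' @param karyotype chromosome lengths (for sector angles).
#' @param width,height,res PNG device parameters.
#' @export
plot_circos_summary <- function(calls, path, karyotype = equine_karyotype(),
                                width = 900, height = 900, res = 120) {
  stopifnot(length(calls) >= 1)
  grDevices::png(path, width = width, height = height, res = res)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(1, 1, 2, 1))
  graphics::plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1,
                 axes = FALSE, xlab = "", ylab = "",
                 main = "Chromosome constitution per sample")
  len <- as.numeric(karyotype)
  ang <- 2 * pi * c(0, cumsum(len) / sum(len))
  nring <- length(calls)
  for (r in seq_len(nring)) {
    cc <- calls[[r]]
    r_out <- 1 - (r - 1) * 0.9 / nring
    r_in <- r_out - 0.8 * 0.9 / nring
    for (i in seq_along(karyotype)) {
      ch <- names(karyotype)[i]
      st <- cc$state[match(ch, cc$chrom)]
      if (is.na(st)) st <- "undetermined"
      th <- seq(ang[i], ang[i + 1], length.out = 20)
      graphics::polygon(c(r_out * cos(th), rev(r_in * cos(th))),
                        c(r_out * sin(th), rev(r_in * sin(th))),
                        col = state_col(st), border = "white", lwd = 0.5)
    }
  }
  mid <- (ang[-1] + ang[-length(ang)]) / 2
  graphics::text(1.06 * cos(mid), 1.06 * sin(mid), names(karyotype),
                 cex = 0.55)
  invisible(path)
}
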