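#' Summarize an analyzed embryo as a report record
#'
#' One flat record per sample: QC metrics, the per-chromosome state string,
#' ploidy label, sex and per-locus calls; suitable for a TSV row and
#' round-trippable JSON.
#'
#' @param fit a `"haplarithmisis"` object.
#' @param json_path optional path to also write the record as JSON.
#' @return list of class `"embryo_report"`.
#' @export
summarize_embryo <- function(fit, json_path = NULL) {
  states <- stats::setNames(fit$chrom_calls$state, fit$chrom_calls$chrom)
  loci <- lapply(fit$locus_calls, function(lc) list(
    gene = lc$gene,
    maternal = lc$mat$haplotype, maternal_reason = lc$mat$reason,
    paternal = lc$pat$haplotype, paternal_reason = lc$pat$reason,
    upstream_bp = lc$mat$upstream_bp, downstream_bp = lc$mat$downstream_bp,
    upstream_n = lc$mat$upstream_n, downstream_n = lc$mat$downstream_n))
  rec <- list(
    sample_id = fit$sample_id,
    role = fit$role,
    call_rate = fit$qc$call_rate,
    mendelian_inconsistency_rate = fit$qc$mendelian_inconsistency_rate,
    n_informative_snps = fit$qc$n_informative_snps,
    genome = fit$ploidy$genome,
    sex = fit$sex,
    chrom_states = as.list(states),
    n_breakpoints = nrow(fit$breakpoints),
    loci = loci)
  class(rec) <- "embryo_report"
  if (!is.null(json_path))
    jsonlite::write_json(unclass(rec), json_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  rec
}

report_tsv_row <- function(rec) {
  data.frame(
    sample_id = rec$sample_id, role = rec$role,
    call_rate = rec$call_rate,
    mendelian_inconsistency_rate = rec$mendelian_inconsistency_rate,
    n_informative_snps = rec$n_informative_snps,
    genome = rec$genome, sex = rec$sex,
    chrom_states = paste(names(rec$chrom_states),
                         unlist(rec$chrom_states), sep = ":",
                         collapse = ";"),
    loci = if (length(rec$loci))
      paste(vapply(rec$loci, function(l)
        sprintf("%s=M:%s/P:%s", l$gene, l$maternal, l$paternal), ""),
        collapse = ";") else "",
    stringsAsFactors = FALSE)
}

#' Write a SNP map as TSV
#' @param map a `"snp_map"`.
#' @param path output path.
#' @export
write_snp_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a SNP map from TSV
#' @param path file with columns `snp_id`, `chrom`, `pos_bp` (and
#'   optionally `bfreq`).
#' @param karyotype chromosome lengths; inferred from max positions if
#'   omitted.
#' @export
read_snp_map <- function(path, karyotype = NULL) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  ord <- order(match(map$chrom, unique(map$chrom)), map$pos_bp)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  attr(map, "karyotype") <- karyotype %||%
    stats::setNames(as.numeric(tapply(map$pos_bp, map$chrom, max)[unique(map$chrom)]),
                    unique(map$chrom))
  class(map) <- c("snp_map", "data.frame")
  map
}

#' Run the full analysis pipeline from a configuration
#'
#' The configuration (YAML file path or list) names the SNP map, the
#' samples with their roles, the phasing mode and the loci of interest:
#' \preformatted{
#' map: map.tsv
#' out_dir: out
#' phasing:
#'   mode: grandparents        # or "sibling"
#'   parent: father            # parent phased by grandparents
#'   grandsire: gs.tsv
#'   granddam: gd.tsv
#'   sibling: sib.tsv          # sibling mode: phases both parents
#' samples:
#'   mother: mother.tsv
#'   father: father.tsv
#'   embryos:
#'     - {id: e1, path: e1.tsv, role: biopsy}
#' loci: loci.tsv              # optional
#' plots: false
#' min_call_rate: 0.2
#' }
#' Embryo samples whose call rate falls below `min_call_rate` or that
#' yield no informative SNPs are reported as failed analyses rather than
#' aborting the run.
#'
#' @param config list or path to a YAML file.
#' @return invisibly, a list with `fits`, `reports`, the summary
#'   data.frame and the output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$map) || is.null(config$samples))
    stop("configuration must name 'map' and 'samples'")
  map <- read_snp_map(config$map)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  mother <- read_sample_table(config$samples$mother, map, role = "mother")
  father <- read_sample_table(config$samples$father, map, role = "father")

  ph <- config$phasing
  if (is.null(ph$mode)) stop("phasing mode missing from configuration")
  phase <- list(mother = NULL, father = NULL)
  if (ph$mode == "grandparents") {
    if (is.null(ph$grandsire) || is.null(ph$granddam))
      stop("grandparent phasing requires 'grandsire' and 'granddam' samples")
    gs <- read_sample_table(ph$grandsire, map, role = "grandsire")
    gd <- read_sample_table(ph$granddam, map, role = "granddam")
    target <- ph$parent %||% "father"
    phase[[target]] <- phase_with_grandparents(
      if (target == "father") father else mother, gs, gd)
  } else if (ph$mode == "sibling") {
    if (is.null(ph$sibling))
      stop("sibling phasing requires a 'sibling' sample")
    sib <- read_sample_table(ph$sibling, map, role = "blastocyst")
    phase$mother <- phase_with_sibling(mother, father, sib)
    phase$father <- phase_with_sibling(father, mother, sib)
  } else stop("unknown phasing mode: ", ph$mode)

  loci <- if (!is.null(config$loci)) read_locus_table(config$loci) else NULL
  min_cr <- config$min_call_rate %||% 0.2

  fits <- list(); reports <- list(); rows <- NULL
  for (e in config$samples$embryos) {
    emb <- read_sample_table(e$path, map, role = e$role %||% "embryo")
    attr(emb, "sample_id") <- e$id %||% attr(emb, "sample_id")
    cr <- call_rate(emb)
    message(sprintf("[%s] read %d SNPs, call rate %.3f", e$id, nrow(emb), cr))
    if (cr < min_cr) {
      message(sprintf("[%s] failed analysis: call rate below %.2f",
                      e$id, min_cr))
      rows <- rbind(rows, data.frame(
        sample_id = e$id, role = e$role %||% "embryo", call_rate = cr,
        mendelian_inconsistency_rate = NA, n_informative_snps = NA,
        genome = "failed_analysis", sex = NA, chrom_states = "", loci = "",
        stringsAsFactors = FALSE))
      next
    }
    fit <- haplarithmisis(emb, mother, father, map, phase, loci = loci)
    message(sprintf("[%s] %d informative SNPs, genome %s, sex %s",
                    e$id, fit$qc$n_informative_snps, fit$ploidy$genome,
                    fit$sex))
    if (fit$qc$n_informative_snps == 0) {
      message(sprintf("[%s] failed analysis: no informative SNPs", e$id))
      rows <- rbind(rows, data.frame(
        sample_id = e$id, role = e$role %||% "embryo", call_rate = cr,
        mendelian_inconsistency_rate = NA, n_informative_snps = 0L,
        genome = "failed_analysis", sex = NA, chrom_states = "", loci = "",
        stringsAsFactors = FALSE))
      next
    }
    rec <- summarize_embryo(fit, file.path(out_dir, paste0(e$id, ".json")))
    fits[[e$id]] <- fit
    reports[[e$id]] <- rec
    rows <- rbind(rows, report_tsv_row(rec))
    if (isTRUE(config$plots))
      plot_haplarithm(fit, file.path(out_dir, paste0(e$id, ".png")),
                      loci = loci)
  }
  if (isTRUE(config$plots) && length(fits))
    plot_circos_summary(lapply(fits, `[[`, "chrom_calls"),
                        file.path(out_dir, "circos_summary.png"),
                        karyotype = map_karyotype(map))
  utils::write.table(rows, file.path(out_dir, "summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(list(fits = fits, reports = reports, summary = rows,
                 out_dir = out_dir))
}
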