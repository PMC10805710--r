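# truth inherited homologue of one parent's gamete at a position:
# the strand source (1/2 -> H1/H2) at the nearest map SNP; NA when the
# gamete carries zero or several strands with differing source there.
truth_homologue_at <- function(gamete, map, chrom, pos) {
  strands <- gamete[[chrom]]
  if (length(strands) == 0) return(NA_character_)
  idx <- chrom_idx(map, chrom)
  i <- which.min(abs(map$pos_bp[idx] - pos))
  srcs <- unique(vapply(strands, function(s) s$source[i], 0L))
  if (length(srcs) != 1) return(NA_character_)
  c("H1", "H2")[srcs]
}

#' End-to-end recovery evaluation on a simulated scenario suite
#'
#' Simulates a pedigree and a suite of embryos with known truth, renders
#' noisy biopsy arrays, runs the full haplarithmisis analysis with
#' grandparent phasing, and scores chromosome-state recovery, genome-label
#' and sex recovery, and conclusive locus-call correctness against truth.
#' A chromosome that is truly mosaic in the biopsy counts as recovered
#' when it is flagged mosaic or called as its majority state.
#'
#' @param scenarios list of scenarios (default [scenario_suite()]).
#' @param map SNP map (default: the full 70,000-SNP synthetic array).
#' @param noise biopsy noise (default [default_noise()]`("biopsy")`).
#' @param n_cells cells per biopsy.
#' @param loci loci of interest (default [default_loci()]).
#' @param seed integer seed.
#' @param control analysis control parameters.
#' @param keep_fits also return each embryo's full fit and simulation
#'   truth in the per-embryo details (memory-heavy; for inspection).
#' @return list with per-embryo results and the summary metrics
#'   `chrom_state_accuracy`, `genome_label_accuracy`, `sex_accuracy`,
#'   `locus_accuracy`, `n_conclusive_loci`.
#' @export
evaluate_recovery <- function(scenarios = scenario_suite(),
                              map = build_snp_map(n_snps = 70000),
                              noise = default_noise("biopsy"),
                              n_cells = 10, loci = default_loci(),
                              seed = 1,
                              control = haplarithm_control(),
                              keep_fits = FALSE) {
  set.seed(seed)
  ped <- simulate_pedigree(map)
  phase <- phase_pedigree(ped)

  n_chrom_ok <- n_chrom <- 0L
  genome_ok <- sex_ok <- logical(0)
  genome_eval <- character(0)
  locus_ok <- locus_n <- 0L
  details <- list()

  for (sc in scenarios) {
    sim <- simulate_embryo_scenario(ped, sc, n_cells = n_cells)
    arr <- render_array(sim$truth, map, noise = noise,
                        sample_id = sc$id, role = "biopsy")
    fit <- haplarithmisis(arr, ped$mother_arr, ped$father_arr, map, phase,
                          loci = loci, control = control)
    cc <- fit$chrom_calls
    ok <- logical(nrow(cc))
    for (i in seq_len(nrow(cc))) {
      ch <- cc$chrom[i]
      tm <- sim$expected_mat[[ch]]; tp <- sim$expected_pat[[ch]]
      if (ch %in% sim$mosaic_chroms) {
        ok[i] <- isTRUE(cc$mosaic_flag[i]) ||
          (identical(cc$maternal_copies[i], tm) &&
             identical(cc$paternal_copies[i], tp))
      } else {
        ok[i] <- !isTRUE(cc$mosaic_flag[i]) && !isTRUE(cc$partial[i]) &&
          identical(cc$maternal_copies[i], tm) &&
          identical(cc$paternal_copies[i], tp)
      }
    }
    n_chrom_ok <- n_chrom_ok + sum(ok)
    n_chrom <- n_chrom + length(ok)

    is_mosaic_embryo <- startsWith(sc$type, "mitotic_")
    if (!is_mosaic_embryo) {
      genome_ok <- c(genome_ok, fit$ploidy$genome == sim$expected_genome)
      genome_eval <- c(genome_eval, sc$id)
    }
    sex_ok <- c(sex_ok, fit$sex == sim$expected_sex)

    locus_err <- character()
    for (lc in fit$locus_calls) {
      locus <- loci[loci$gene == lc$gene, ]
      mid <- (locus$start_bp + locus$end_bp) / 2
      for (par in c("mat", "pat")) {
        pc <- lc[[par]]
        if (pc$reason != "none") next
        g <- if (par == "mat") sim$mat_gamete else sim$pat_gamete
        tr <- truth_homologue_at(g, map, locus$chrom, mid)
        if (is.na(tr)) next
        locus_n <- locus_n + 1L
        locus_ok <- locus_ok + (pc$haplotype == tr)
        if (pc$haplotype != tr)
          locus_err <- c(locus_err,
                         sprintf("%s/%s called %s truth %s", lc$gene, par,
                                 pc$haplotype, tr))
      }
    }
    details[[sc$id]] <- list(scenario = sc, fit_chrom = cc,
                             genome = fit$ploidy$genome, sex = fit$sex,
                             chrom_ok = ok, locus_errors = locus_err,
                             fit = if (keep_fits) fit,
                             sim = if (keep_fits) sim)
  }
  list(chrom_state_accuracy = n_chrom_ok / n_chrom,
       n_chrom = n_chrom,
       genome_label_accuracy = mean(genome_ok),
       n_genome_eval = length(genome_ok),
       sex_accuracy = mean(sex_ok),
       locus_accuracy = if (locus_n) locus_ok / locus_n else NA_real_,
       n_conclusive_loci = locus_n,
       details = details)
}
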