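# combine two transmitted gametes into a child's truth haplotypes;
# h1 is the sire-derived strand, h2 the dam-derived strand, so grandparent
# phasing (H1 := grandsire-derived) recovers exactly h1.
child_from_gametes <- function(g_sire, g_dam, map, individual_id) {
  n <- nrow(map)
  h1 <- integer(n); h2 <- integer(n)
  src1 <- integer(n); src2 <- integer(n)
  for (ch in names(g_sire)) {
    idx <- chrom_idx(map, ch)
    h1[idx] <- g_sire[[ch]][[1]]$alleles
    h2[idx] <- g_dam[[ch]][[1]]$alleles
    src1[idx] <- g_sire[[ch]][[1]]$source
    src2[idx] <- g_dam[[ch]][[1]]$source
  }
  out <- list(individual_id = individual_id, h1 = h1, h2 = h2,
              src1 = src1, src2 = src2)
  class(out) <- "truth_haplotypes"
  out
}

#' Simulate a two-generation pedigree with noise-free parental arrays
#'
#' Four founder grandparents produce the mother and the father; bulk
#' parental and grandparental arrays are rendered noise-free.  Both
#' parents' true homologue 1 is the strand transmitted by their sire, so
#' grandparent phasing is anchored to the truth phase.
#'
#' @param map a SNP map.
#' @param seed integer seed.
#' @return list with the map, truth haplotypes (`mother`, `father`,
#'   grandparents) and `"sample_array"`s (`mother_arr`, `father_arr`,
#'   `pat_gs_arr`, `pat_gd_arr`, `mat_gs_arr`, `mat_gd_arr`).
#' @export
simulate_pedigree <- function(map, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pgs <- simulate_founder(map, individual_id = "pat_grandsire")
  pgd <- simulate_founder(map, individual_id = "pat_granddam")
  mgs <- simulate_founder(map, individual_id = "mat_grandsire")
  mgd <- simulate_founder(map, individual_id = "mat_granddam")
  father <- child_from_gametes(simulate_meiosis(pgs, map),
                               simulate_meiosis(pgd, map), map, "father")
  mother <- child_from_gametes(simulate_meiosis(mgs, map),
                               simulate_meiosis(mgd, map), map, "mother")
  list(map = map, mother = mother, father = father,
       pat_grandsire = pgs, pat_granddam = pgd,
       mat_grandsire = mgs, mat_granddam = mgd,
       mother_arr = render_bulk(mother, map, role = "mother"),
       father_arr = render_bulk(father, map, role = "father"),
       pat_gs_arr = render_bulk(pgs, map, role = "grandsire"),
       pat_gd_arr = render_bulk(pgd, map, role = "granddam"),
       mat_gs_arr = render_bulk(mgs, map, role = "grandsire"),
       mat_gd_arr = render_bulk(mgd, map, role = "granddam"))
}

#' Phase both parents of a simulated pedigree with the grandparents
#'
#' @param ped a [simulate_pedigree()] result.
#' @return list with `"phased_parent"` entries `mother` and `father`.
#' @export
phase_pedigree <- function(ped) {
  list(mother = phase_with_grandparents(ped$mother_arr, ped$mat_gs_arr,
                                        ped$mat_gd_arr),
       father = phase_with_grandparents(ped$father_arr, ped$pat_gs_arr,
                                        ped$pat_gd_arr))
}

#' Default biopsy-type noise profiles
#'
#' Whole-genome-amplification noise levels by sample type: per-cell allele
#' drop-out 0.2, BAF dispersion 0.05, LogR dispersion 0.15, a small miscall
#' rate and a missing-call rate increasing from whole blastocyst to biopsy
#' to single blastomere (emulating the coverage gradient of multi- versus
#' few-cell samples).
#'
#' @param role `"blastocyst"`, `"biopsy"` or `"blastomere"`.
#' @export
default_noise <- function(role = "biopsy") {
  missing <- switch(role, blastocyst = 0.15, biopsy = 0.3,
                    blastomere = 0.45, 0.3)
  noise_config(ado_rate = 0.2, miscall_rate = 0.005, missing_rate = missing,
               baf_sd = 0.05, logr_sd = 0.15)
}

#' Simulate one embryo under a named error scenario
#'
#' Scenario types: `"euploid"`; `"meiotic_monosomy"` / `"meiotic_trisomy"`
#' (fields `chrom`, `parent`, and `mech` `"MI"`/`"MII"` for trisomies);
#' `"mitotic_trisomy"` / `"mitotic_monosomy"` (whole-chromosome event in a
#' `frac` fraction of cells — a mosaic); `"digynic_MI"` / `"digynic_MII"`
#' (genome-wide extra maternal genome of meiotic-heterodisomic or
#' single-genotype origin).  `sex` picks whether the father transmits an X.
#'
#' @param ped a [simulate_pedigree()] result.
#' @param scenario list describing the scenario (see above).
#' @param n_cells embryo cell count.
#' @param seed integer seed.
#' @return list with `truth` (the `"embryo_truth"`), `scenario`, expected
#'   per-chromosome maternal/paternal copies (`expected_mat`,
#'   `expected_pat`, majority across cells), `mosaic_chroms`,
#'   `expected_genome`, `expected_sex`, and the maternal/paternal gametes.
#' @export
simulate_embryo_scenario <- function(ped, scenario = list(type = "euploid"),
                                     n_cells = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  map <- ped$map
  type <- scenario$type
  sex <- scenario$sex %||% "female"
  has_x <- "X" %in% names(map_karyotype(map))
  mat_nd <- "none"; mat_omit <- character()
  pat_nd <- "none"
  pat_omit <- if (sex == "male" && has_x) "X" else character()
  plan <- NULL
  if (type == "meiotic_monosomy") {
    if (scenario$parent == "mat")
      mat_omit <- c(mat_omit, scenario$chrom)
    else pat_omit <- c(pat_omit, scenario$chrom)
  } else if (type == "meiotic_trisomy") {
    nd <- stats::setNames(scenario$mech %||% "MI", scenario$chrom)
    if (scenario$parent == "mat") mat_nd <- nd else pat_nd <- nd
  } else if (type == "digynic_MI") {
    mat_nd <- "MI"
  } else if (type == "digynic_MII") {
    mat_nd <- "MII"
  } else if (type %in% c("mitotic_trisomy", "mitotic_monosomy")) {
    frac <- scenario$frac %||% 0.5
    cells <- seq_len(max(1, round(frac * n_cells)))
    # zygote copy order: maternal strands first, then paternal
    copy <- if (scenario$parent == "mat") 1L else 2L
    plan <- list(list(
      type = if (type == "mitotic_trisomy") "whole_gain" else "whole_loss",
      chrom = scenario$chrom, copy = copy, cells = cells))
  } else if (type != "euploid") stop("unknown scenario type: ", type)

  mat_g <- simulate_meiosis(ped$mother, map, nondisjunction = mat_nd,
                            omit_chroms = mat_omit)
  pat_g <- simulate_meiosis(ped$father, map, nondisjunction = pat_nd,
                            omit_chroms = pat_omit)
  truth <- assemble_embryo(mat_g, pat_g, map, mitotic_plan = plan,
                           n_cells = n_cells,
                           embryo_id = scenario$id %||% "embryo")

  cn <- truth_copy_number(truth)
  maj <- function(mx) apply(mx, 1, function(v)
    as.integer(names(sort(table(v), decreasing = TRUE))[1]))
  exp_mat <- maj(cn$mat); exp_pat <- maj(cn$pat)
  mosaic <- rownames(cn$mat)[apply(cn$mat, 1, function(v) length(unique(v))) > 1 |
                               apply(cn$pat, 1, function(v) length(unique(v))) > 1]
  exp_sex <- if (!has_x) "undetermined" else {
    xm <- exp_mat[["X"]]; xp <- exp_pat[["X"]]
    if (xm == 1 && xp == 0) "male" else
      if (xm == 1 && xp == 1) "female" else "undetermined"
  }
  exp_genome <- switch(type, digynic_MI = "digynic_triploid_meiotic",
                       digynic_MII = "digynic_triploid_mitotic",
                       "biparental_diploid")
  list(truth = truth, scenario = scenario, mat_gamete = mat_g,
       pat_gamete = pat_g, expected_mat = exp_mat, expected_pat = exp_pat,
       mosaic_chroms = mosaic, expected_genome = exp_genome,
       expected_sex = exp_sex)
}

#' The default validation scenario suite
#'
#' Twenty embryos spanning euploid male/female, meiotic monosomies and
#' trisomies (MI and MII, both parents), 50% mitotic mosaics, and digynic
#' triploidy of meiotic and mitotic origin.
#'
#' @return list of scenario lists.
#' @export
scenario_suite <- function() {
  s <- list()
  sexes <- rep(c("female", "male"), 4)
  for (i in 1:8)
    s[[i]] <- list(type = "euploid", sex = sexes[i])
  s[[9]] <- list(type = "meiotic_monosomy", chrom = "31", parent = "mat")
  s[[10]] <- list(type = "meiotic_monosomy", chrom = "28", parent = "mat")
  s[[11]] <- list(type = "meiotic_monosomy", chrom = "13", parent = "pat")
  s[[12]] <- list(type = "meiotic_trisomy", chrom = "9", parent = "mat",
                  mech = "MI")
  s[[13]] <- list(type = "meiotic_trisomy", chrom = "17", parent = "mat",
                  mech = "MII")
  s[[14]] <- list(type = "meiotic_trisomy", chrom = "4", parent = "pat",
                  mech = "MI")
  s[[15]] <- list(type = "mitotic_trisomy", chrom = "7", parent = "mat",
                  frac = 0.5)
  s[[16]] <- list(type = "mitotic_monosomy", chrom = "13", parent = "pat",
                  frac = 0.5)
  s[[17]] <- list(type = "digynic_MI")
  s[[18]] <- list(type = "digynic_MII")
  s[[19]] <- list(type = "digynic_MI", sex = "male")
  s[[20]] <- list(type = "euploid", sex = "male")
  for (i in seq_along(s)) s[[i]]$id <- sprintf("embryo%02d", i)
  s
}
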