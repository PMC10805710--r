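#' Simulate a founder individual's true haplotypes
#'
#' Draws the two haplotypes independently per SNP from the SNP's population
#' B-allele frequency, so the expected heterozygosity at a SNP with B
#' frequency f is 2 f (1 - f).
#'
#' @param map a [build_snp_map()] map.
#' @param maf_spec per-SNP B-allele frequencies (recycled); defaults to the
#'   map's `bfreq` column.
#' @param seed integer seed.
#' @param individual_id identifier stored on the result.
#' @return Object of class `"truth_haplotypes"`: list with `individual_id`
#'   and integer vectors `h1`, `h2` (0 = A, 1 = B) over all map SNPs.
#' @export
simulate_founder <- function(map, maf_spec = map$bfreq, seed = NULL,
                             individual_id = "founder") {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(map)
  f <- rep_len(maf_spec, n)
  if (any(f < 0 | f > 1)) stop("allele frequencies must be in [0, 1]")
  out <- list(individual_id = individual_id,
              h1 = stats::rbinom(n, 1L, f),
              h2 = stats::rbinom(n, 1L, f))
  class(out) <- "truth_haplotypes"
  out
}

#' Crossover model configuration
#'
#' Crossover counts per chromosome are Poisson with mean
#' `length_bp * rate_per_bp` (default 1 crossover per 100 Mbp), positions
#' uniform, no interference.  `fixed_count` overrides the Poisson draw with
#' an exact per-chromosome crossover count (used for controlled experiments).
#'
#' @param rate_per_bp expected crossovers per bp.
#' @param fixed_count `NULL`, or a single count applied to every chromosome.
#' @export
recomb_config <- function(rate_per_bp = 1e-8, fixed_count = NULL) {
  list(rate_per_bp = rate_per_bp, fixed_count = fixed_count)
}

# one recombined strand for one chromosome: mosaic of h1/h2 switching at
# crossover positions.  Returns list(alleles, source, cx_pos).
recombine_chrom <- function(parent, idx, chrom_len, recomb) {
  k <- if (!is.null(recomb$fixed_count)) recomb$fixed_count
       else stats::rpois(1, chrom_len * recomb$rate_per_bp)
  cx <- sort(stats::runif(k) * chrom_len)
  start <- sample(1:2, 1)
  src <- rep.int(start, length(idx))
  if (k > 0) {
    nswitch <- findInterval(attr(idx, "pos"), cx)
    src <- 1L + (start - 1L + nswitch) %% 2L
  }
  alleles <- ifelse(src == 1L, parent$h1[idx], parent$h2[idx])
  list(alleles = as.integer(alleles), source = as.integer(src), cx_pos = cx)
}

#' Simulate meiosis for one parent
#'
#' Produces gamete haplotype strands per chromosome.  With
#' `nondisjunction = "none"` each chromosome yields one recombined strand.
#' `"MI"` yields two strands, one starting from each homologue and each
#' independently recombined, so the gamete carries both parental homologues
#' genome-wide (heterodisomy).  `"MII"` yields two identical copies of one
#' recombined strand (a single parental genotype).  Chromosomes listed in
#' `omit_chroms` are absent from the gamete (nullisomic gamete).
#'
#' @param parent a `"truth_haplotypes"` object.
#' @param map the SNP map.
#' @param recomb a [recomb_config()].
#' @param nondisjunction `"none"`, `"MI"` or `"MII"`; either one label
#'   applied genome-wide or a named vector by chromosome label.
#' @param omit_chroms chromosome labels to leave out of the gamete.
#' @param seed integer seed.
#' @return Object of class `"gamete"`: named list (by chromosome) of lists
#'   of strands; each strand has `alleles`, `source` (1/2 homologue of
#'   origin per SNP) and `cx_pos` (crossover positions, bp).
#' @export
simulate_meiosis <- function(parent, map, recomb = recomb_config(),
                             nondisjunction = "none",
                             omit_chroms = character(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kar <- map_karyotype(map)
  chroms <- names(kar)
  nd <- if (length(nondisjunction) == 1L && is.null(names(nondisjunction)))
    stats::setNames(rep(nondisjunction, length(chroms)), chroms)
  else {
    full <- stats::setNames(rep("none", length(chroms)), chroms)
    full[names(nondisjunction)] <- nondisjunction
    full
  }
  bad <- setdiff(unique(nd), c("none", "MI", "MII"))
  if (length(bad)) stop("invalid nondisjunction label: ", bad[1])

  out <- lapply(chroms, function(ch) {
    if (ch %in% omit_chroms) return(list())
    idx <- chrom_idx(map, ch)
    attr(idx, "pos") <- map$pos_bp[idx]
    switch(nd[[ch]],
      none = list(recombine_chrom(parent, idx, kar[[ch]], recomb)),
      MI = {
        s1 <- recombine_chrom(parent, idx, kar[[ch]], recomb)
        s2 <- recombine_chrom(parent, idx, kar[[ch]], recomb)
        # force the two strands to start from different homologues
        if (s1$source[1] == s2$source[1]) {
          s2$source <- 3L - s2$source
          s2$alleles <- as.integer(
            ifelse(s2$source == 1L, parent$h1[idx], parent$h2[idx]))
        }
        list(s1, s2)
      },
      MII = {
        s <- recombine_chrom(parent, idx, kar[[ch]], recomb)
        list(s, s)
      })
  })
  names(out) <- chroms
  class(out) <- "gamete"
  out
}

#' Assemble a multicell embryo from two gametes
#'
#' All cells share the zygotic karyotype formed by the maternal and paternal
#' gametes (meiotic errors carried by the gametes therefore appear in every
#' cell).  Mitotic events from `mitotic_plan` are applied only to their cell
#' subsets.  Each event is a list with fields:
#' \describe{
#'   \item{type}{`"whole_gain"`, `"whole_loss"`, `"seg_gain"`, `"seg_loss"`
#'     or `"genome_gain"` (endoreduplication of one parental complement).}
#'   \item{chrom}{chromosome label (not used for `genome_gain`).}
#'   \item{copy}{1-based index of the zygotic copy on that chromosome.}
#'   \item{cells}{integer cell indices affected.}
#'   \item{start_bp,end_bp}{closed interval for segmental events.}
#'   \item{parent}{`"mat"`/`"pat"`, for `genome_gain`.}
#' }
#'
#' @param mat_gamete,pat_gamete [simulate_meiosis()] gametes.
#' @param map the SNP map.
#' @param mitotic_plan list of events (may be `NULL`).
#' @param n_cells number of cells.
#' @param embryo_id identifier.
#' @param seed integer seed (events themselves are deterministic; the seed
#'   only matters if a plan is stochastic upstream).
#' @return Object of class `"embryo_truth"`: list with `embryo_id`, `cells`
#'   (per cell, per chromosome, a list of copies: `parent`, `alleles`,
#'   `source`, `present` logical mask over the chromosome's SNPs) and
#'   `events` (a data.frame log with meiotic and mitotic entries).
#' @export
assemble_embryo <- function(mat_gamete, pat_gamete, map, mitotic_plan = NULL,
                            n_cells = 1, embryo_id = "embryo", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  chroms <- names(map_karyotype(map))
  zygote <- lapply(chroms, function(ch) {
    nsnp <- length(chrom_idx(map, ch))
    mk <- function(strand, parent) {
      list(parent = parent, alleles = strand$alleles, source = strand$source,
           cx_pos = strand$cx_pos, present = rep(TRUE, nsnp))
    }
    c(lapply(mat_gamete[[ch]], mk, parent = "mat"),
      lapply(pat_gamete[[ch]], mk, parent = "pat"))
  })
  names(zygote) <- chroms

  # meiotic event log: deviations from 1 maternal + 1 paternal copy
  ev <- list()
  for (ch in chroms) {
    nm <- sum(vapply(zygote[[ch]], function(cp) cp$parent == "mat", TRUE))
    np <- length(zygote[[ch]]) - nm
    if (nm != 1L)
      ev[[length(ev) + 1L]] <- data.frame(
        type = if (nm > 1) "gain" else "loss", origin = "meiotic",
        parent = "mat", chrom = ch, cells = NA, stringsAsFactors = FALSE)
    if (np != 1L)
      ev[[length(ev) + 1L]] <- data.frame(
        type = if (np > 1) "gain" else "loss", origin = "meiotic",
        parent = "pat", chrom = ch, cells = NA, stringsAsFactors = FALSE)
  }

  cells <- rep(list(zygote), n_cells)

  for (e in (mitotic_plan %||% list())) {
    stopifnot(!is.null(e$type), !is.null(e$cells))
    if (identical(e$type, "genome_gain")) {
      for (ci in e$cells) for (ch in chroms) {
        dup <- Filter(function(cp) cp$parent == e$parent, zygote[[ch]])
        cells[[ci]][[ch]] <- c(cells[[ci]][[ch]], dup)
      }
      ev[[length(ev) + 1L]] <- data.frame(
        type = "genome_gain", origin = "mitotic", parent = e$parent,
        chrom = "all", cells = paste(e$cells, collapse = ","),
        stringsAsFactors = FALSE)
      next
    }
    ch <- e$chrom
    if (e$copy > length(zygote[[ch]]))
      stop("mitotic event references copy ", e$copy,
           " absent from the zygote on chromosome ", ch)
    idx <- chrom_idx(map, ch)
    pos <- map$pos_bp[idx]
    parent <- zygote[[ch]][[e$copy]]$parent
    for (ci in e$cells) {
      cl <- cells[[ci]][[ch]]
      if (e$type == "whole_loss") {
        cl[[e$copy]] <- NULL
      } else if (e$type == "whole_gain") {
        cl[[length(cl) + 1L]] <- zygote[[ch]][[e$copy]]
      } else if (e$type == "seg_loss") {
        mask <- pos >= e$start_bp & pos <= e$end_bp
        cl[[e$copy]]$present <- cl[[e$copy]]$present & !mask
      } else if (e$type == "seg_gain") {
        cp <- zygote[[ch]][[e$copy]]
        cp$present <- pos >= e$start_bp & pos <= e$end_bp
        cl[[length(cl) + 1L]] <- cp
      } else stop("unknown mitotic event type: ", e$type)
      cells[[ci]][[ch]] <- cl
    }
    ev[[length(ev) + 1L]] <- data.frame(
      type = e$type, origin = "mitotic", parent = parent, chrom = ch,
      cells = paste(e$cells, collapse = ","), stringsAsFactors = FALSE)
  }

  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(type = character(), origin = character(), parent = character(),
               chrom = character(), cells = character(),
               stringsAsFactors = FALSE)
  out <- list(embryo_id = embryo_id, cells = cells, events = events)
  class(out) <- "embryo_truth"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True per-cell copy numbers of an embryo
#'
#' Whole-chromosome maternal/paternal copy counts per cell (segmental
#' presence masks are ignored; a copy counts if it is present anywhere on
#' the chromosome).
#'
#' @param embryo an `"embryo_truth"` object.
#' @param cells cell indices (default all).
#' @return list of matrices (`mat`, `pat`), chromosomes x cells.
#' @export
truth_copy_number <- function(embryo, cells = seq_along(embryo$cells)) {
  chroms <- names(embryo$cells[[1]])
  count <- function(ci, ch, parent) {
    sum(vapply(embryo$cells[[ci]][[ch]],
               function(cp) cp$parent == parent && any(cp$present), TRUE))
  }
  mat <- vapply(cells, function(ci)
    vapply(chroms, count, 0L, ci = ci, parent = "mat"), integer(length(chroms)))
  pat <- vapply(cells, function(ci)
    vapply(chroms, count, 0L, ci = ci, parent = "pat"), integer(length(chroms)))
  mat <- matrix(mat, nrow = length(chroms), dimnames = list(chroms, NULL))
  pat <- matrix(pat, nrow = length(chroms), dimnames = list(chroms, NULL))
  list(mat = mat, pat = pat)
}
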