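# shared fixtures: everything is generated in code at test time

two_chrom_karyotype <- function(len = 50e6) c("1" = len, "2" = len)

# a tiny hand-built sample_array on an explicit map
manual_sample <- function(map, gtype, baf = NULL, logr = NULL,
                          id = "s", role = "embryo") {
  n <- nrow(map)
  stopifnot(length(gtype) == n)
  out <- data.frame(snp_id = map$snp_id, gtype = gtype,
                    baf = baf %||% rep(NA_real_, n),
                    logr = logr %||% rep(0, n), stringsAsFactors = FALSE)
  attr(out, "sample_id") <- id
  attr(out, "role") <- role
  class(out) <- c("sample_array", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a small map for unit tests (deterministic)
tiny_map <- function(n = 10, seed = 42) {
  build_snp_map(two_chrom_karyotype(), n_snps = n, seed = seed)
}

# one-row locus helper
locus_row <- function(gene, chrom, start, end) {
  data.frame(gene = gene, chrom = chrom, start_bp = start, end_bp = end,
             note = "", stringsAsFactors = FALSE)
}

# noise-free diploid embryo plus pedigree on a given map
noisefree_diploid <- function(map, seed = 5, sex = "female", n_cells = 1) {
  ped <- simulate_pedigree(map, seed = seed)
  sim <- simulate_embryo_scenario(ped, list(type = "euploid", sex = sex,
                                            id = "e"), n_cells = n_cells)
  arr <- render_array(sim$truth, map, noise = noise_config(),
                      sample_id = "e", role = "biopsy")
  list(ped = ped, sim = sim, arr = arr, phase = phase_pedigree(ped))
}
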