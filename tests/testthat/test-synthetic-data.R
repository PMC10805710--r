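test_that("SNP map allocation is length-proportional, sorted and seeded", {
  map <- build_snp_map(two_chrom_karyotype(), n_snps = 100, seed = 1)
  counts <- table(map$chrom)
  expect_setequal(names(counts), c("1", "2"))
  # equal lengths: binomial split around 50/50
  expect_gt(min(counts), 30)
  for (ch in c("1", "2"))
    expect_false(is.unsorted(map$pos_bp[map$chrom == ch]))
  expect_false(anyDuplicated(map$snp_id) > 0)
  expect_identical(map, build_snp_map(two_chrom_karyotype(),
                                      n_snps = 100, seed = 1))

  big <- build_snp_map(n_snps = 70000, seed = 2)
  expect_equal(nrow(big), 70000)
  expect_setequal(unique(big$chrom), c(as.character(1:31), "X"))

  expect_error(build_snp_map(c("1" = -5), n_snps = 10), "positive")
  expect_error(build_snp_map(two_chrom_karyotype(), n_snps = 1), "at least")
})

test_that("founder heterozygosity follows 2f(1-f)", {
  map <- build_snp_map(two_chrom_karyotype(), n_snps = 10000, seed = 2)
  f <- simulate_founder(map, maf_spec = 0.5, seed = 3)
  het <- mean(f$h1 != f$h2)
  expect_lt(abs(het - 0.5), 0.02)

  allA <- simulate_founder(map, maf_spec = 0, seed = 3)
  expect_true(all(allA$h1 == 0) && all(allA$h2 == 0))

  expect_identical(simulate_founder(map, seed = 9),
                   simulate_founder(map, seed = 9))
})

test_that("meiosis produces the expected strand structure", {
  map <- tiny_map(n = 400, seed = 4)
  par <- simulate_founder(map, seed = 5, individual_id = "p")
  nocx <- recomb_config(fixed_count = 0)

  g <- simulate_meiosis(par, map, recomb = nocx, seed = 6)
  for (ch in c("1", "2")) {
    idx <- which(map$chrom == ch)
    s <- g[[ch]][[1]]
    expect_length(g[[ch]], 1)
    expect_true(identical(s$alleles, par$h1[idx]) ||
                  identical(s$alleles, par$h2[idx]))
  }

  mi <- simulate_meiosis(par, map, recomb = nocx, nondisjunction = "MI",
                         seed = 7)
  for (ch in c("1", "2")) {
    idx <- which(map$chrom == ch)
    al <- lapply(mi[[ch]], `[[`, "alleles")
    expect_length(al, 2)
    # one strand is h1, the other h2: heterodisomy at every het SNP
    expect_setequal(vapply(al, paste, "", collapse = ""),
                    c(paste(par$h1[idx], collapse = ""),
                      paste(par$h2[idx], collapse = "")))
  }

  mii <- simulate_meiosis(par, map, nondisjunction = "MII", seed = 8)
  for (ch in c("1", "2"))
    expect_identical(mii[[ch]][[1]]$alleles, mii[[ch]][[2]]$alleles)

  null <- simulate_meiosis(par, map, omit_chroms = "2", seed = 9)
  expect_length(null[["2"]], 0)

  expect_error(simulate_meiosis(par, map, nondisjunction = "MIII"),
               "invalid nondisjunction")
})

test_that("embryo assembly separates meiotic and mitotic events", {
  map <- build_snp_map(stats::setNames(rep(40e6, 10), as.character(1:10)),
                       n_snps = 500, seed = 10)
  mo <- simulate_founder(map, seed = 11, individual_id = "m")
  fa <- simulate_founder(map, seed = 12, individual_id = "f")

  # no events: identical biparental diploid cells
  e0 <- assemble_embryo(simulate_meiosis(mo, map, seed = 13),
                        simulate_meiosis(fa, map, seed = 14), map,
                        n_cells = 4)
  cn <- truth_copy_number(e0)
  expect_true(all(cn$mat == 1) && all(cn$pat == 1))
  expect_identical(e0$cells[[1]], e0$cells[[4]])

  # maternal MI trisomy of chromosome 9 is shared by every cell
  e1 <- assemble_embryo(
    simulate_meiosis(mo, map, nondisjunction = c("9" = "MI"), seed = 15),
    simulate_meiosis(fa, map, seed = 16), map, n_cells = 4)
  cn1 <- truth_copy_number(e1)
  expect_true(all(cn1$mat["9", ] == 2) && all(cn1$pat["9", ] == 1))
  expect_true(all(cn1$mat[rownames(cn1$mat) != "9", ] == 1))
  expect_true(e1$events$origin[e1$events$chrom == "9"] == "meiotic")

  # reciprocal mitotic loss/gain of the paternal chr 10 copy
  plan <- list(list(type = "whole_loss", chrom = "10", copy = 2L, cells = 1L),
               list(type = "whole_gain", chrom = "10", copy = 2L, cells = 2L))
  e2 <- assemble_embryo(simulate_meiosis(mo, map, seed = 17),
                        simulate_meiosis(fa, map, seed = 18), map,
                        mitotic_plan = plan, n_cells = 4)
  cn2 <- truth_copy_number(e2)
  expect_equal(unname(cn2$pat["10", ]), c(0L, 2L, 1L, 1L))
  expect_true(all(cn2$mat["10", ] == 1))
  expect_true(all(e2$events$origin[e2$events$type %in%
                                     c("whole_loss", "whole_gain")] ==
                    "mitotic"))

  expect_error(assemble_embryo(simulate_meiosis(mo, map, seed = 19),
                               simulate_meiosis(fa, map, seed = 20), map,
                               mitotic_plan = list(list(type = "whole_loss",
                                                        chrom = "1",
                                                        copy = 7L,
                                                        cells = 1L)),
                               n_cells = 2),
               "absent from the zygote")
})

test_that("noise-free measurements follow the BAF/LogR model", {
  map <- build_snp_map(c("1" = 30e6), n_snps = 300, seed = 21)
  mo <- simulate_founder(map, seed = 22)
  fa <- simulate_founder(map, seed = 23)
  emb <- assemble_embryo(simulate_meiosis(mo, map, seed = 24),
                         simulate_meiosis(fa, map, seed = 25), map,
                         n_cells = 1)
  arr <- render_array(emb, map, noise = noise_config())
  # diploid: ideal BAF in {0, 1/2, 1}, LogR exactly 0
  expect_true(all(arr$baf %in% c(0, 0.5, 1)))
  expect_true(all(arr$logr == 0))
  # conservation: pooled genotype equals the cell's true allele pair
  b_true <- emb$cells[[1]][["1"]][[1]]$alleles +
    emb$cells[[1]][["1"]][[2]]$alleles
  expect_equal(arr$baf, b_true / 2)

  # copy-number ladder: n = 1, 3, 4 via meiotic and mitotic changes
  tri <- assemble_embryo(
    simulate_meiosis(mo, map, nondisjunction = "MI", seed = 26),
    simulate_meiosis(fa, map, seed = 27), map, n_cells = 1)
  arr3 <- render_array(tri, map, noise = noise_config())
  expect_true(all(abs(arr3$logr - log2(3 / 2)) < 1e-12))
  expect_true(all(arr3$baf %in% c(0, 1 / 3, 2 / 3, 1)))

  tet <- assemble_embryo(
    simulate_meiosis(mo, map, nondisjunction = "MI", seed = 26),
    simulate_meiosis(fa, map, nondisjunction = "MII", seed = 27), map,
    n_cells = 1)
  arr4 <- render_array(tet, map, noise = noise_config())
  expect_true(all(arr4$logr == 1))
  expect_true(all(arr4$baf %in% c(0, 0.25, 0.5, 0.75, 1)))

  mono <- assemble_embryo(simulate_meiosis(mo, map, omit_chroms = "1",
                                           seed = 28),
                          simulate_meiosis(fa, map, seed = 29), map,
                          n_cells = 1)
  arrm <- render_array(mono, map, noise = noise_config())
  expect_true(all(arrm$logr == -1))
  expect_true(all(arrm$baf %in% c(0, 1)))

  # total allele drop-out yields NC
  gone <- render_array(emb, map, noise = noise_config(ado_rate = 1),
                       seed = 30)
  expect_true(all(gone$gtype == "NC"))
  expect_true(all(is.na(gone$baf)))
})

test_that("biopsy BAF is the allele-count-weighted mean over cells", {
  map <- build_snp_map(c("1" = 30e6), n_snps = 200, seed = 31)
  mo <- simulate_founder(map, seed = 32)
  fa <- simulate_founder(map, seed = 33)
  # cell 2 loses the paternal chromosome: mixture of disomic + monosomic
  plan <- list(list(type = "whole_loss", chrom = "1", copy = 2L, cells = 2L))
  emb <- assemble_embryo(simulate_meiosis(mo, map, seed = 34),
                         simulate_meiosis(fa, map, seed = 35), map,
                         mitotic_plan = plan, n_cells = 2)
  pool <- render_array(emb, map, noise = noise_config())
  c1 <- render_array(emb, map, cells = 1, noise = noise_config())
  c2 <- render_array(emb, map, cells = 2, noise = noise_config())
  expected <- (2 * c1$baf + 1 * c2$baf) / 3
  expect_equal(pool$baf, expected)
  expect_true(all(pool$logr == log2(1.5 / 2)))
})

test_that("rendering is deterministic for a fixed seed", {
  map <- tiny_map(n = 300, seed = 36)
  mo <- simulate_founder(map, seed = 37)
  fa <- simulate_founder(map, seed = 38)
  emb <- assemble_embryo(simulate_meiosis(mo, map, seed = 39),
                         simulate_meiosis(fa, map, seed = 40), map,
                         n_cells = 3)
  nz <- noise_config(ado_rate = 0.2, miscall_rate = 0.01,
                     missing_rate = 0.3, baf_sd = 0.05, logr_sd = 0.15)
  expect_identical(render_array(emb, map, noise = nz, seed = 41),
                   render_array(emb, map, noise = nz, seed = 41))
})

test_that("noise configuration validates rates", {
  expect_error(noise_config(ado_rate = 1.2), "rates")
  expect_error(noise_config(baf_sd = -1), "SDs")
})
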