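test_that("signature table carries the exact expected measurement values", {
  tab <- signature_table()
  pick <- function(m1, m2, p1, p2)
    tab[tab$m1 == m1 & tab$m2 == m2 & tab$p1 == p1 & tab$p2 == p2, ]
  # biparental disomy: LogR 0, subtrack distance 0.5
  dis <- pick(1, 0, 1, 0)
  expect_equal(dis$logr, 0, tolerance = 1e-12)
  expect_equal(abs(dis$mat_P1 - dis$mat_P2), 0.5, tolerance = 1e-12)
  # monosomy / trisomy / tetrasomy LogR ladder
  expect_equal(pick(0, 0, 1, 0)$logr, -1, tolerance = 1e-12)
  expect_equal(pick(1, 1, 1, 0)$logr, log2(3 / 2), tolerance = 1e-12)
  expect_equal(pick(2, 0, 1, 1)$logr, 1, tolerance = 1e-12)
  # reachable subtrack level sets
  lv <- function(n) sort(unique(round(
    unlist(tab[tab$n == n, c("mat_P1", "mat_P2", "pat_P1", "pat_P2")]), 12)))
  expect_equal(lv(1), c(0, 1), tolerance = 1e-12)
  expect_equal(lv(3), c(0, 1 / 3, 2 / 3, 1), tolerance = 1e-12)
  expect_equal(lv(4), c(0, 1 / 4, 1 / 2, 3 / 4, 1), tolerance = 1e-12)
})

test_that("classifier recovers every generating configuration exactly", {
  tab <- signature_table()
  for (p in 0:4) for (m1 in 0:4) for (m2 in 0:4) {
    n <- p + m1 + m2
    if (n < 1 || n > 4) next
    call <- classify_segment(logr_mean = log2(n / 2),
                             mat_means = c(m1 / n, m2 / n),
                             pat_means = c(p / n, 0), table = tab)
    expect_equal(c(call$m1, call$m2, call$p1, call$p2), c(m1, m2, p, 0))
    expect_false(call$mosaic_flag)
    expect_lt(call$fit_distance, 1e-12)
  }
})

test_that("a 50% disomy/monosomy mixture is called mosaic at the right fraction", {
  # closed-form mixture observables: mean copies 1.5, allele-weighted tracks
  phi <- 0.5
  nbar <- 2 * (1 - phi) + 1 * phi
  obs_logr <- log2(nbar / 2)
  obs_mat <- c((1 - phi) * 1 / nbar, 0)      # maternal copy lost in mosaic
  obs_pat <- c(1 / nbar, 0)
  call <- classify_segment(obs_logr, obs_mat, obs_pat)
  expect_true(call$mosaic_flag)
  expect_identical(call$state, "mosaic_maternal_loss")
  expect_equal(call$mosaic_fraction, 0.5, tolerance = 0.05)

  # independent grid-search oracle over the aberrant fraction
  tab <- signature_table()
  dis <- tab[tab$m1 == 1 & tab$m2 == 0 & tab$p1 == 1 & tab$p2 == 0, ]
  ab <- tab[tab$m1 == 0 & tab$m2 == 0 & tab$p1 == 1 & tab$p2 == 0, ]
  grid <- seq(0, 1, by = 0.001)
  d <- vapply(grid, function(f) {
    nb <- 2 * (1 - f) + 1 * f
    e <- c(log2(nb / 2), (1 - f) / nb, 0, 1 / nb, 0)
    sqrt(sum((e - c(obs_logr, obs_mat, obs_pat))^2))
  }, 0)
  expect_equal(call$mosaic_fraction, grid[which.min(d)], tolerance = 1e-3)
})

test_that("pure noise-free signatures never trigger the mosaic path", {
  call <- classify_segment(0, c(0.5, 0), c(0.5, 0))
  expect_identical(call$state, "disomy")
  call2 <- classify_segment(-1, c(0, 0), c(0.99, 0.01))
  expect_identical(call2$state, "maternal_loss")
  expect_equal(c(call2$maternal_copies, call2$paternal_copies), c(0, 1))
})

test_that("LogR segmentation localises whole and partial losses", {
  map <- build_snp_map(two_chrom_karyotype(), n_snps = 2000, seed = 95)
  mo <- simulate_founder(map, seed = 96)
  fa <- simulate_founder(map, seed = 97)
  # chromosome 2 monosomic, chromosome 1 disomic, noise-free
  emb <- assemble_embryo(simulate_meiosis(mo, map, omit_chroms = "2",
                                          seed = 98),
                         simulate_meiosis(fa, map, seed = 99), map,
                         n_cells = 1)
  arr <- render_array(emb, map, noise = noise_config())
  seg <- segment_logr(arr, map)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$mean_logr[seg$chrom == "1"], 0)
  expect_equal(seg$mean_logr[seg$chrom == "2"], -1)

  # half-chromosome segmental loss: breakpoint within 5 SNPs of truth
  idx2 <- which(map$chrom == "2")
  cut <- map$pos_bp[idx2[length(idx2) %/% 2]]
  plan <- list(list(type = "seg_loss", chrom = "2", copy = 2L, cells = 1L,
                    start_bp = cut + 1, end_bp = 50e6))
  emb2 <- assemble_embryo(simulate_meiosis(mo, map, seed = 100),
                          simulate_meiosis(fa, map, seed = 101), map,
                          mitotic_plan = plan, n_cells = 1)
  arr2 <- render_array(emb2, map,
                       noise = noise_config(logr_sd = 0.15), seed = 102)
  seg2 <- segment_logr(arr2, map)
  s2 <- seg2[seg2$chrom == "2", ]
  expect_equal(nrow(s2), 2)
  k <- which(map$pos_bp[idx2] == s2$end_bp[1])
  expect_lte(abs(k - length(idx2) %/% 2), 5)
})

test_that("genome-wide ploidy patterns are labelled by the rules", {
  mk_calls <- function(m, p, m1 = NULL, m2 = NULL) {
    chroms <- c(as.character(1:31), "X")
    data.frame(chrom = chroms, state = "x",
               m1 = m1 %||% m, m2 = m2 %||% 0,
               p1 = p, p2 = 0,
               maternal_copies = m, paternal_copies = p,
               mosaic_flag = FALSE, stringsAsFactors = FALSE)
  }
  # uniform maternal trisomy with heterodisomy -> meiotic digyny
  tri_het <- mk_calls(2, 1, m1 = 1, m2 = 1)
  expect_identical(call_genome_ploidy(tri_het)$genome,
                   "digynic_triploid_meiotic")
  # same without any heterodisomic region -> mitotic digyny
  tri_iso <- mk_calls(2, 1, m1 = 2, m2 = 0)
  expect_identical(call_genome_ploidy(tri_iso)$genome,
                   "digynic_triploid_mitotic")
  expect_identical(call_genome_ploidy(mk_calls(1, 2))$genome,
                   "diandric_triploid")
  expect_identical(call_genome_ploidy(mk_calls(1, 0))$genome,
                   "gynogenetic_haploid")
  expect_identical(call_genome_ploidy(mk_calls(0, 1))$genome,
                   "androgenetic_haploid")
  expect_identical(call_genome_ploidy(mk_calls(2, 0, m1 = 2))$genome,
                   "gw_maternal_UPD")
  expect_identical(call_genome_ploidy(mk_calls(1, 1))$genome,
                   "biparental_diploid")
  # mixed non-uniform aberrations -> complex
  cx <- mk_calls(1, 1)
  cx$maternal_copies[1:16] <- 2
  cx$paternal_copies[17:24] <- 0
  expect_identical(call_genome_ploidy(cx)$genome, "complex")
  # insufficient coverage -> undetermined
  und <- mk_calls(1, 1)
  und$state <- "undetermined"
  und$maternal_copies <- NA_integer_
  expect_identical(call_genome_ploidy(und)$genome, "undetermined")
})

test_that("sex follows X copy number and parental origin", {
  mk <- function(m, p) list(chrom = "X", maternal_copies = m,
                            paternal_copies = p, mosaic_flag = FALSE)
  expect_identical(determine_sex(mk(1, 0)), "male")
  expect_identical(determine_sex(mk(1, 1)), "female")
  expect_identical(determine_sex(mk(2, 1)), "undetermined")
  expect_identical(determine_sex(mk(2, 0)), "undetermined")
  expect_identical(determine_sex(NULL), "undetermined")
})

test_that("event origin is read from cross-sample concordance", {
  chroms <- as.character(1:31)
  base <- data.frame(chrom = chroms, state = "disomy",
                     stringsAsFactors = FALSE)
  with_ev <- function(ch, st) { x <- base; x$state[match(ch, x$chrom)] <- st; x }

  # biopsy + blastocyst share a maternal loss -> meiotic;
  # biopsy-only trisomy -> low-grade mosaic
  bio <- with_ev(c("28", "17"), c("maternal_loss", "maternal_gain"))
  bla <- with_ev("28", "maternal_loss")
  ev <- classify_event_origin(list(biopsy = bio, blastocyst = bla),
                              roles = c("biopsy", "blastocyst"))
  expect_identical(ev$origin[ev$chrom == "28"], "meiotic")
  expect_identical(ev$origin[ev$chrom == "17"], "low_grade_mosaic")

  # blastomere set: shared loss meiotic, subset event mitotic
  b1 <- with_ev(c("9", "13"), c("maternal_loss", "paternal_loss"))
  b2 <- with_ev("9", "maternal_loss")
  b3 <- with_ev("9", "maternal_loss")
  ev2 <- classify_event_origin(list(bl1 = b1, bl2 = b2, bl3 = b3),
                               roles = rep("blastomere", 3))
  expect_identical(ev2$origin[ev2$chrom == "9"], "meiotic")
  expect_identical(ev2$origin[ev2$chrom == "13"], "mitotic")

  # single sample: undetermined
  ev3 <- classify_event_origin(list(only = b1), roles = "blastomere")
  expect_true(all(ev3$origin == "undetermined"))
})

test_that("more measurement noise never improves state recovery", {
  map <- build_snp_map(n_snps = 70000, seed = 103)
  ped <- simulate_pedigree(map, seed = 104)
  phase <- phase_pedigree(ped)
  scens <- scenario_suite()
  acc <- vapply(c(1, 2, 3), function(mult) {
    set.seed(105)
    ok <- tot <- 0
    for (sc in scens) {
      sim <- simulate_embryo_scenario(ped, sc)
      nz <- noise_config(ado_rate = 0.2, missing_rate = 0.3,
                         baf_sd = 0.05 * mult, logr_sd = 0.15 * mult)
      arr <- render_array(sim$truth, map, noise = nz)
      fit <- haplarithmisis(arr, ped$mother_arr, ped$father_arr, map, phase)
      cc <- fit$chrom_calls
      for (i in seq_len(nrow(cc))) {
        ch <- cc$chrom[i]
        if (ch %in% sim$mosaic_chroms) next
        tot <- tot + 1
        ok <- ok + (!isTRUE(cc$partial[i]) &&
                      identical(cc$maternal_copies[i],
                                sim$expected_mat[[ch]]) &&
                      identical(cc$paternal_copies[i],
                                sim$expected_pat[[ch]]))
      }
    }
    ok / tot
  }, 0)
  expect_true(all(diff(acc) <= 0.005))  # non-increasing up to seed jitter
  expect_gt(acc[1], acc[3])             # strictly worse at 3x noise
})
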