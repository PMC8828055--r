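# Synthetic epigenome generator: determinism, configured structure, and
# the statistical signatures the analysis expects.

test_that("generation is byte-identical under a fixed seed", {
  cfg <- small_sim_config()
  s1 <- build_genome(cfg, seed = 5)
  s2 <- build_genome(cfg, seed = 5)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$tes, s2$tes)
  expect_identical(s1$dyads, s2$dyads)
  expect_identical(s1$truth, s2$truth)
  expect_identical(simulate_methylome(s1, "wt", 3),
                   simulate_methylome(s2, "wt", 3))
  expect_identical(simulate_srna(s1, "h1", 3), simulate_srna(s2, "h1", 3))
  expect_identical(simulate_chip(s1, "H1", "wt", 3),
                   simulate_chip(s2, "H1", "wt", 3))
  # a different seed changes the data
  expect_false(identical(s1$genome, build_genome(cfg, seed = 6)$genome))
})

test_that("TE placement is non-overlapping and class GC gap is realized", {
  sim <- cached_small_sim()
  tes <- sim$tes[order(sim$tes$start), ]
  expect_true(all(tes$start[-1] >= tes$end[-nrow(tes)]))
  comp <- sequence_composition(tes, sim$genome)
  cls <- sim$truth$te_class[tes$id]
  gap <- mean(comp$gc[cls == "CMT"]) - mean(comp$gc[cls == "DRM"])
  cfg <- sim$cfg
  expect_lt(abs(gap - (cfg$gc_class$CMT["mean"] - cfg$gc_class$DRM["mean"])),
            0.02)
  expect_error(build_genome(sim_config(genome_bp = 1e5), seed = 1),
               "cannot be placed")
})

test_that("dyad spacing matches the configured repeat length", {
  sim <- cached_small_sim()
  for (g in c("wt", "h1")) {
    dy <- sim$dyads[[g]]
    sp <- unlist(lapply(split(dy$start, dy$te_id), diff))
    expect_gt(length(sp), 300)
    expect_lt(abs(mean(sp) - sim$cfg$nrl[[g]]), 2)
  }
})

test_that("methylome sampling reproduces the configured probabilities", {
  cfg <- small_sim_config()
  # pin two probabilities to make the checks sharp
  cfg$meth_prob$wt$background["CHH"] <- 0      # error-rate floor
  cfg$meth_prob$wt$CMT["CG"] <- 0.8
  cfg$bs_coverage <- 30
  sim <- build_genome(cfg, seed = 17)
  rec <- simulate_methylome(sim, "wt", seed = 17)
  tes <- sim$tes
  cls <- sim$truth$te_class[tes$id]
  summ <- summarize_methylation(rec, tes, min_cov = 3)
  # p = 0 plus non-conversion 0.005: pooled background CHH level ~ 0.005
  bg <- feature_intervals("chr1", 0L, tes$start[order(tes$start)][1], "+",
                          "bg1")
  sbg <- summarize_methylation(rec, bg, min_cov = 1)
  n_reads <- sbg$reads_meth_CHH + sbg$reads_unmeth_CHH
  se <- sqrt(0.005 * 0.995 / n_reads)
  expect_lt(abs(sbg$m_CHH - 0.005), 3 * se)
  # p = 0.8 CG at CMT-like TEs, coverage 30: level within 0.02
  cmt_cg <- summ$m_CG[cls == "CMT" & summ$sites_CG >= 150]
  expect_gt(length(cmt_cg), 0)
  expect_true(all(abs(cmt_cg - (0.8 + 0.2 * 0.005)) < 0.02))
})

test_that("cmt2 abolishes mCHH at CMT-like TEs only", {
  sim <- cached_small_sim()
  rec <- simulate_methylome(sim, "cmt2", seed = 23)
  summ <- summarize_methylation(rec, sim$tes)
  cls <- sim$truth$te_class[sim$tes$id]
  expect_true(all(summ$m_CHH[cls == "CMT"] < 0.02))
  expect_true(all(summ$m_CHH[cls == "DRM"] > 0.05))
})

test_that("unknown genotypes and marks are rejected with the available list", {
  sim <- cached_small_sim()
  expect_error(simulate_methylome(sim, "nope"), "available:.*wt")
  expect_error(simulate_srna(sim, "nope"), "available")
  expect_error(simulate_chip(sim, "H3K27me3"), "available")
})

test_that("sRNA relocates from DRM-like to CMT-like TEs in h1", {
  sim <- cached_small_sim()
  r_wt <- simulate_srna(sim, "wt", seed = 41)
  r_h1 <- simulate_srna(sim, "h1", seed = 42)
  cls <- sim$truth$te_class[sim$tes$id]
  k_wt <- srna_rpkm(r_wt, sim$tes, "24")
  k_h1 <- srna_rpkm(r_h1, sim$tes, "24")
  expect_gt(mean(k_wt[cls == "DRM"]), mean(k_wt[cls == "CMT"]))
  expect_gt(mean(k_h1[cls == "CMT"]) / mean(k_wt[cls == "CMT"]), 1)
  # read composition: ~5% 21-nt background
  expect_equal(mean(r_wt$length == 21), sim$cfg$frac_21nt, tolerance = 0.2)
  expect_equal(attr(r_wt, "total_18_28"), sim$cfg$srna_depth)
})

test_that("without linker bias a uniform intensity gives a flat dyad profile", {
  cfg <- small_sim_config(linker_multiplier = 1)
  # equal rates everywhere: the genome-wide intensity is uniform
  cfg$srna_rate$wt <- c(CMT = 1, DRM = 1, intermediate = 1, background = 1)
  sim <- build_genome(cfg, seed = 19)
  reads <- simulate_srna(sim, "wt", seed = 19)
  prof <- dyad_profile(reads, sim$dyads$wt, window_bp = 500L, bin_bp = 10L)
  # coefficient of variation small and acf shows no significant repeat
  expect_lt(sd(prof$mean) / mean(prof$mean), 0.2)
  a <- autocorrelate(prof$mean, max_lag = 35)
  est <- estimate_nrl(a, 10)
  # any peak must be weak compared to the phased case
  expect_true(is.na(est$nrl_bp) || est$acf_at_peak < 0.5)
})

test_that("ChIP simulation encodes the configured enrichment ratios", {
  # ratio 1 everywhere -> log2 ratio ~ 0
  cfg <- small_sim_config(
    chip_enrichment = list(default = list(
      H3K9me1 = c(CMT = 1, DRM = 1, intermediate = 1, background = 1),
      H3K9me2 = c(CMT = 1, DRM = 1, intermediate = 1, background = 1))),
    chip_noise_sd = 0, chip_depth = 3e5)
  sim <- build_genome(cfg, seed = 29)
  pair <- simulate_chip(sim, "H3K9me1", "wt", seed = 29)
  v <- chip_feature_enrichment(pair$chip, pair$input, sim$tes)
  expect_lt(max(abs(v)), 0.35)

  # ratio 4 at CMT-like TEs occupying a small genome fraction -> log2 ~ 2
  cfg2 <- sim_config(
    genome_bp = 1e6, n_te = c(CMT = 10, DRM = 20, intermediate = 5),
    te_length = list(CMT = c(1000, 2000), DRM = c(300, 600),
                     intermediate = c(500, 1000)),
    chip_enrichment = list(default = list(
      H3K9me1 = c(CMT = 4, DRM = 1, intermediate = 1, background = 1),
      H3K9me2 = c(CMT = 1, DRM = 1, intermediate = 1, background = 1))),
    chip_noise_sd = 0, chip_depth = 5e5)
  sim2 <- build_genome(cfg2, seed = 30)
  pair2 <- simulate_chip(sim2, "H3K9me1", "wt", seed = 30)
  v2 <- chip_feature_enrichment(pair2$chip, pair2$input, sim2$tes)
  cls2 <- sim2$truth$te_class[sim2$tes$id]
  expect_true(all(abs(v2[cls2 == "CMT"] - 2) < 0.3))

  # H1 increases with TE GC content (logistic link)
  simh <- cached_small_sim()
  pairh <- simulate_chip(simh, "H1", "wt", seed = 31)
  vh <- chip_feature_enrichment(pairh$chip, pairh$input, simh$tes)
  clsh <- simh$truth$te_class[simh$tes$id]
  expect_gt(mean(vh[clsh == "CMT"]), mean(vh[clsh == "DRM"]))
})

test_that("expected sRNA fold matches the measured class fold", {
  sim <- cached_small_sim()
  ef <- expected_srna_fold(sim, "wt", "h1")
  k_wt <- srna_rpkm(simulate_srna(sim, "wt", seed = 61), sim$tes, "24")
  k_h1 <- srna_rpkm(simulate_srna(sim, "h1", seed = 62), sim$tes, "24")
  g <- genotype_change(k_wt, k_h1, classes = sim$truth$te_class[sim$tes$id])
  for (cl in ef$class) {
    expect_equal(g$fold$fold[g$fold$class == cl],
                 ef$expected_fold[ef$class == cl], tolerance = 0.15)
  }
})

test_that("TE universe filter drops short elements", {
  fe <- feature_intervals("chr1", c(0L, 1000L), c(200L, 1400L), "+",
                          c("short", "long"))
  expect_equal(filter_te_universe(fe)$id, "long")
  expect_equal(nrow(filter_te_universe(fe, min_bp = 100)), 2L)
})
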