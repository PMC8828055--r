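# Metaplots, dyad-anchored profiles, autocorrelation, NRL estimation.

uniform_track <- function(L = 2000L, bin = 50L, value = 1, kind = "raw") {
  starts <- seq(0L, L - bin, by = bin)
  enrichment_track("chr1", starts, starts + bin, rep(value, length(starts)),
                   kind)
}

test_that("ends profile of a uniform signal is flat", {
  tr <- uniform_track()
  fe <- feature_intervals("chr1", c(500L, 1200L), c(800L, 1500L),
                          c("+", "-"), c("a", "b"))
  ep <- ends_profile(tr, fe, flank_bp = 200L, bin_bp = 50L)
  expect_true(all(abs(ep$mean - 1) < 1e-12))
  expect_equal(sort(unique(ep$end)), c("3p", "5p"))
  expect_equal(nrow(ep), 2 * 2 * 200 / 50)
})

test_that("rpkm cap excludes outlier bins from the metaplot mean", {
  starts <- seq(0L, 950L, by = 50L)
  vals <- rep(10, length(starts))
  vals[starts == 500L] <- 500  # outlier bin
  tr <- enrichment_track("chr1", starts, starts + 50L, vals, "rpkm")
  fe <- feature_intervals("chr1", c(500L, 500L), c(700L, 700L) + c(0L, 1L),
                          "+", c("a", "b"))
  ep <- ends_profile(tr, fe, flank_bp = 100L, bin_bp = 50L, rpkm_cap = 200)
  first_bin <- ep[ep$end == "5p" & ep$offset == 0, ]
  expect_equal(first_bin$n, 0L)  # both features' first bin excluded
  expect_true(all(ep$mean[ep$n > 0] == 10))
  # without the cap the outlier dominates
  tr_raw <- enrichment_track(tr$chrom, tr$start, tr$end, tr$value, "raw")
  ep2 <- ends_profile(tr_raw, fe, flank_bp = 100L, bin_bp = 50L)
  expect_equal(ep2[ep2$end == "5p" & ep2$offset == 0, "mean"], 500)
})

test_that("minus-strand features are flipped into 5'-to-3' orientation", {
  # signal 5 inside each TE body, 1 outside: at the 5' end, every feature
  # should show low upstream / high downstream regardless of strand
  starts <- seq(0L, 3950L, by = 50L)
  val <- rep(1, length(starts))
  val[starts >= 1000L & starts < 1300L] <- 5  # plus-strand body
  val[starts >= 2000L & starts < 2300L] <- 5  # minus-strand body
  tr <- enrichment_track("chr1", starts, starts + 50L, val, "raw")
  fe <- feature_intervals("chr1", c(1000L, 2000L), c(1300L, 2300L),
                          c("+", "-"), c("p", "m"))
  ep <- ends_profile(tr, fe, flank_bp = 200L, bin_bp = 50L)
  five <- ep[ep$end == "5p", ]
  expect_true(all(five$mean[five$offset < 0] == 1))
  expect_true(all(five$mean[five$offset >= 0] == 5))
  three <- ep[ep$end == "3p", ]
  expect_true(all(three$mean[three$offset < 0] == 5))
  expect_true(all(three$mean[three$offset >= 0] == 1))
})

test_that("dyad profile localizes reads at their 5'-end offset", {
  dyads <- feature_intervals("chr1", c(2000L, 6000L), c(2001L, 6001L), ".",
                             c("d1", "d2"))
  # every read 5' end exactly 85 bp downstream of a dyad
  reads <- sized_reads(rep("chr1", 4), c(2085L, 2085L, 6085L, 6085L),
                       c(2085L, 2085L, 6085L, 6085L) + 24L, "+")
  prof <- dyad_profile(reads, dyads, window_bp = 500L, bin_bp = 10L)
  expect_equal(prof$offset[prof$mean > 0], 80)
  # minus-strand read with the same 5' end (end - 1 = 2085)
  rm1 <- sized_reads("chr1", 2062L, 2086L, "-")
  pm <- dyad_profile(rm1, dyads, window_bp = 500L, bin_bp = 10L)
  expect_equal(pm$offset[pm$mean > 0], 80)
  # 21-nt reads are ignored but a valid normalizer remains
  r21 <- sized_reads(rep("chr1", 3), c(100L, 200L, 300L),
                     c(100L, 200L, 300L) + 21L, "+")
  p21 <- dyad_profile(r21, dyads, window_bp = 500L, bin_bp = 10L)
  expect_true(all(p21$mean == 0))
  expect_error(dyad_profile(reads, dyads[0, ], 500L, 10L), "no dyads")
})

test_that("dyad profile is translation equivariant", {
  set.seed(8)
  pos <- sample(1000:9000, 300)
  reads <- sized_reads(rep("chr1", 300), pos, pos + 24L, "+")
  dpos <- seq(1500L, 8500L, by = 180L)
  dyads <- feature_intervals("chr1", dpos, dpos + 1L, ".",
                             paste0("d", seq_along(dpos)))
  shift <- 1234L
  reads2 <- sized_reads(reads$chrom, reads$start + shift, reads$end + shift,
                        reads$strand)
  dyads2 <- feature_intervals(dyads$chrom, dyads$start + shift,
                              dyads$end + shift, ".", dyads$id)
  p1 <- dyad_profile(reads, dyads, 500L, 10L)
  p2 <- dyad_profile(reads2, dyads2, 500L, 10L)
  expect_equal(p1$mean, p2$mean)
})

test_that("autocorrelation is normalized and finds periodic structure", {
  v <- cos(2 * pi * (0:99) / 17)
  a <- autocorrelate(v, max_lag = 40)
  expect_equal(a[1], 1)
  expect_true(all(abs(a) <= 1 + 1e-12))
  # local maximum at lag 17
  expect_gt(a[18], a[17])
  expect_gt(a[18], a[19])
  expect_error(autocorrelate(rep(1, 50), 10), "zero variance")
  expect_error(autocorrelate(v, 100), "max_lag")
})

test_that("white-noise autocorrelation stays inside the 1.96/sqrt(n) band", {
  inside <- vapply(1:20, function(s) {
    set.seed(s)
    a <- autocorrelate(rnorm(200), max_lag = 20)
    mean(abs(a[-1]) < 0.2)
  }, numeric(1))
  expect_gte(mean(inside), 0.95)
})

test_that("NRL estimation finds the first significant acf peak", {
  v <- cos(2 * pi * (0:199) / 17)
  a <- autocorrelate(v, max_lag = 40)
  est <- estimate_nrl(a, bin_bp = 10)
  expect_equal(est$nrl_bp, 170)
  expect_equal(est$lag_bins, 17L)
  # flat acf -> undefined with a reason
  flat <- c(1, rep(0, 40))
  attr(flat, "n") <- 200
  est2 <- estimate_nrl(flat, bin_bp = 10)
  expect_true(is.na(est2$nrl_bp))
  expect_match(est2$reason, "no local maximum")
  expect_error(estimate_nrl(a[1:10], 10), "search range")
})

test_that("NRL recovery from simulated phased sRNA across repeat lengths", {
  cfg <- small_sim_config()
  for (R in c(160, 190)) {
    cfg$nrl["wt"] <- R
    sim <- build_genome(cfg, seed = 31)
    reads <- simulate_srna(sim, "wt", seed = 31)
    prof <- dyad_profile(reads, sim$dyads$wt, window_bp = 1000L, bin_bp = 10L)
    a <- autocorrelate(prof$mean, max_lag = 35, detrend_bins = 21)
    est <- estimate_nrl(a, 10)
    expect_false(is.na(est$nrl_bp))
    expect_lte(abs(est$nrl_bp - R), 10)
  }
})
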