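# Context assignment and weighted methylation summaries.

test_that("context assignment follows the two-downstream-base rule", {
  cases <- list(
    list(seq = "TACGA", pos = 2L, strand = "+", ctx = "CG", sub = "CG"),
    list(seq = "ACCGT", pos = 1L, strand = "+", ctx = "CHG", sub = "CCG"),
    list(seq = "ACAGT", pos = 1L, strand = "+", ctx = "CHG", sub = "CWG"),
    list(seq = "GCATA", pos = 1L, strand = "+", ctx = "CHH", sub = "nonCWA"),
    list(seq = "GCAAT", pos = 1L, strand = "+", ctx = "CHH", sub = "CWA"),
    # minus strand: G on forward is the cytosine; downstream runs leftward
    list(seq = "TCGTA", pos = 2L, strand = "-", ctx = "CG", sub = "CG"),
    list(seq = "CATGA", pos = 3L, strand = "-", ctx = "CHH", sub = "nonCWA"),
    # N or chromosome end -> undetermined
    list(seq = "ACNGT", pos = 1L, strand = "+", ctx = "undetermined",
         sub = "undetermined"),
    list(seq = "AAAAC", pos = 4L, strand = "+", ctx = "undetermined",
         sub = "undetermined")
  )
  for (cs in cases) {
    got <- assign_context(setNames(cs$seq, "chr1"), "chr1", cs$pos, cs$strand)
    expect_equal(got$context, cs$ctx, info = cs$seq)
    expect_equal(got$subcontext, cs$sub, info = cs$seq)
  }
  expect_error(
    assign_context(c(chr1 = "AAAA"), "chr1", 1L, "+"), "not a cytosine")
})

test_that("context calls agree with ambiguity-pattern counts on random sequence", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
               collapse = "")
  genome <- c(chr1 = seq)
  sites <- cytosine_sites(genome)
  plus <- sites[sites$strand == "+", ]
  d <- Biostrings::DNAString(seq)
  # Biostrings ambiguity matching is an independent counter for each motif
  # (IUPAC H = A/C/T, so CHG and CHH match exactly the context rule)
  for (motif in c("CG", "CHG", "CHH")) {
    expect_equal(sum(plus$context == motif),
                 Biostrings::countPattern(motif, d, fixed = FALSE),
                 info = motif)
  }
})

test_that("contexts partition the determinable cytosines on both strands", {
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T", "N"), 4000, replace = TRUE,
                      prob = c(.24, .24, .24, .24, .04)), collapse = "")
  sites <- cytosine_sites(c(chr1 = seq))
  det <- sites[sites$context != "undetermined", ]
  expect_equal(nrow(det),
               sum(det$context %in% c("CG", "CHG", "CHH")))
  expect_equal(sum(det$context == "CHG"),
               sum(det$subcontext %in% c("CCG", "CWG")))
  expect_equal(sum(det$context == "CHH"),
               sum(det$subcontext %in% c("CWA", "nonCWA")))
  # total cytosines = C count (plus) + G count (minus)
  v <- strsplit(seq, "")[[1]]
  expect_equal(nrow(sites), sum(v == "C") + sum(v == "G"))
})

make_records <- function(pos, meth, unmeth, context = "CHH",
                         subcontext = "nonCWA", chrom = "chr1",
                         strand = "+") {
  cytosine_records(rep(chrom, length(pos)), pos, rep(strand, length(pos)),
                   meth, unmeth, rep(context, length(pos)),
                   rep(subcontext, length(pos)))
}

test_that("weighted level pools reads over covered sites", {
  rec <- make_records(c(10L, 20L, 30L), c(2L, 0L, 3L), c(8L, 5L, 2L))
  fe <- feature_intervals("chr1", 0L, 100L, "+", "te1")
  s <- summarize_methylation(rec, fe, min_cov = 3)
  expect_equal(s$m_CHH, 5 / 20)
  expect_equal(s$sites_CHH, 3L)
  expect_equal(s$covered_CHH, 3L)
  # no CG site covered -> level undefined, not zero
  expect_true(is.na(s$m_CG))
  # CH pools CHG and CHH; here all sites are CHH
  expect_equal(s$m_CH, s$m_CHH)
  expect_equal(s$reads_meth_CHH, 5L)
  expect_equal(s$reads_unmeth_CHH, 15L)
})

test_that("level is invariant under splitting a site's reads into records", {
  whole <- make_records(10L, 6L, 4L)
  split2 <- make_records(c(10L, 10L), c(2L, 4L), c(3L, 1L))
  fe <- feature_intervals("chr1", 0L, 50L, "+", "te1")
  expect_equal(summarize_methylation(whole, fe, min_cov = 3)$m_CHH,
               summarize_methylation(split2, fe, min_cov = 3)$m_CHH)
})

test_that("mCH is the read-count-weighted combination of mCHG and mCHH", {
  rec <- rbind(make_records(c(5L, 15L), c(4L, 1L), c(6L, 9L),
                            context = "CHG", subcontext = "CWG"),
               make_records(c(25L, 35L), c(2L, 7L), c(8L, 3L)))
  fe <- feature_intervals("chr1", 0L, 100L, "+", "te1")
  s <- summarize_methylation(rec, fe, min_cov = 1)
  num <- s$reads_meth_CHG + s$reads_meth_CHH
  den <- num + s$reads_unmeth_CHG + s$reads_unmeth_CHH
  expect_equal(s$m_CH, num / den)
})

test_that("methylated-site density counts binomial-called sites per bp", {
  # 12 clearly methylated CHH sites in a 1000 bp feature -> d_CH = 0.012
  pos <- as.integer(seq(10, 980, length.out = 12))
  rec <- make_records(pos, rep(5L, 12), rep(0L, 12))
  fe <- feature_intervals("chr1", 0L, 1000L, "+", "te1")
  s <- summarize_methylation(rec, fe)
  expect_equal(s$meth_sites_CHH, 12L)
  expect_equal(s$d_CH, 0.012)
  # unmethylated sites at the error rate are not called
  rec0 <- make_records(pos, rep(0L, 12), rep(10L, 12))
  expect_equal(summarize_methylation(rec0, fe)$meth_sites_CHH, 0L)
})

test_that("features without overlapping records give an all-undefined summary", {
  rec <- make_records(10L, 3L, 3L)
  fe <- feature_intervals("chr1", c(0L, 500L), c(100L, 600L), "+",
                          c("hit", "misses"))
  s <- summarize_methylation(rec, fe)
  expect_equal(s$m_CHH, c(0.5, NA))
  expect_equal(s$sites_CHH, c(1L, 0L))
  # the 3/6 site is confidently methylated; the empty feature has d = 0
  expect_equal(s$d_CH, c(0.01, 0))
})

test_that("windowed methylation emits only covered windows", {
  rec <- make_records(c(5L, 105L), c(5L, 10L), c(5L, 0L))
  w <- genome_window_methylation(rec, 100L, 100L)
  expect_equal(nrow(w), 2L)
  expect_equal(w$level, c(0.5, 1.0))
  expect_equal(w$start, c(0L, 100L))
  empty <- genome_window_methylation(make_records(integer(), integer(),
                                                  integer()), 100L)
  expect_equal(nrow(empty), 0L)
  expect_error(genome_window_methylation(rec, 10L, 20L), "window_bp")
})
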