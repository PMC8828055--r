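# TE classification: every grouping rule of the analysis -- CMT/DRM/
# intermediate pathway classes, MET1-dependence, CLSY-cluster high/low
# groups, mCH-retention classes, threshold counts and set overlaps.

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value computed by enumerating the hypergeometric
#' distribution over all tables with the observed margins and summing the
#' probabilities of tables no more probable than the observed one
#' (relative tie tolerance 1 + 1e-7, the convention for this test).
#'
#' @param a,b,c,d Cell counts: `a`,`b` = first row (e.g. methylated /
#'   unmethylated reads in wild type), `c`,`d` = second row (mutant).
#'   Alternatively `a` may be a 2x2 matrix.
#' @return The two-sided p-value.
#' @export
fisher_exact_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a)) {
    stopifnot(all(dim(a) == c(2, 2)))
    b <- a[1, 2]; c <- a[2, 1]; d <- a[2, 2]; a <- a[1, 1]
  }
  counts <- c(a, b, c, d)
  if (any(is.na(counts)) || any(counts < 0)) {
    .stopf("table cells must be non-negative counts")
  }
  if (sum(counts) == 0) .stopf("all-zero table")
  m <- a + b           # row 1 total
  n <- c + d           # row 2 total
  k <- a + c           # column 1 total
  support <- max(0, k - n):min(m, k)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  min(p, 1)
}

# Vectorized wrapper over per-TE pooled count tables; NA where any cell is
# NA or the table is all zero.
.fisher_vec <- function(a, b, c, d) {
  n <- length(a)
  out <- rep(NA_real_, n)
  ok <- !(is.na(a) | is.na(b) | is.na(c) | is.na(d)) & (a + b + c + d) > 0
  for (i in which(ok)) out[i] <- fisher_exact_two_sided(a[i], b[i], c[i], d[i])
  out
}

#' Classify TEs by methylation-pathway dependence
#'
#' Applies the threshold-plus-Fisher rule that defines CMT- and
#' DRM-dependent TEs: among TEs longer than `length_min` with wild-type
#' mCHH above `wt_min` (strictly), a TE is CMT-dependent if its mCHH in
#' the *cmt2* mutant drops below `mut_max` with Fisher's exact test
#' p < `alpha` (pooled CHH read counts, wt vs mutant), and DRM-dependent
#' symmetrically for *drm2*. TEs passing the criterion in both mutants get
#' the dedicated `both_depleted` label and are excluded from the CMT and
#' DRM sets; everything else above the wild-type gate is `intermediate`.
#'
#' @param mchh_wt,mchh_cmt2,mchh_drm2 Per-TE weighted mCHH levels (as from
#'   [summarize_methylation()]; `NA` = undefined).
#' @param meth_wt,unmeth_wt,meth_cmt2,unmeth_cmt2,meth_drm2,unmeth_drm2
#'   Per-TE pooled CHH read counts (methylated / unmethylated) used to
#'   build the Fisher tables.
#' @param te_length TE lengths in bp; TEs of `length_min` bp or shorter are
#'   `unclassified`.
#' @param alpha Fisher significance cutoff (default 0.01, uncorrected; set
#'   `bh_correct = TRUE` for a Benjamini-Hochberg-adjusted cutoff).
#' @param wt_min Wild-type mCHH gate (default 0.02; strictly greater than).
#' @param mut_max Mutant mCHH loss threshold (default 0.02; strictly less
#'   than).
#' @param length_min Classification length gate in bp (default 200,
#'   exclusive).
#' @param bh_correct Apply Benjamini-Hochberg correction to the Fisher
#'   p-values before thresholding (default `FALSE`, matching a raw p
#'   cutoff).
#' @return A `data.frame` with columns `label` (one of `CMT`, `DRM`,
#'   `both_depleted`, `intermediate`, `unclassified`), `p_cmt2`, `p_drm2`,
#'   and `reason` (for unclassified TEs).
#' @export
classify_pathway <- function(mchh_wt, mchh_cmt2, mchh_drm2,
                             meth_wt, unmeth_wt, meth_cmt2, unmeth_cmt2,
                             meth_drm2, unmeth_drm2, te_length,
                             alpha = 0.01, wt_min = 0.02, mut_max = 0.02,
                             length_min = 200, bh_correct = FALSE) {
  n <- length(mchh_wt)
  p_cmt2 <- .fisher_vec(meth_wt, unmeth_wt, meth_cmt2, unmeth_cmt2)
  p_drm2 <- .fisher_vec(meth_wt, unmeth_wt, meth_drm2, unmeth_drm2)
  q_cmt2 <- if (bh_correct) p.adjust(p_cmt2, "BH") else p_cmt2
  q_drm2 <- if (bh_correct) p.adjust(p_drm2, "BH") else p_drm2
  label <- rep("intermediate", n)
  reason <- rep(NA_character_, n)
  cmt_hit <- !is.na(mchh_cmt2) & mchh_cmt2 < mut_max &
    !is.na(q_cmt2) & q_cmt2 < alpha
  drm_hit <- !is.na(mchh_drm2) & mchh_drm2 < mut_max &
    !is.na(q_drm2) & q_drm2 < alpha
  label[cmt_hit & !drm_hit] <- "CMT"
  label[drm_hit & !cmt_hit] <- "DRM"
  label[cmt_hit & drm_hit] <- "both_depleted"
  low_wt <- is.na(mchh_wt) | mchh_wt <= wt_min
  label[low_wt] <- "unclassified"
  reason[low_wt] <- ifelse(is.na(mchh_wt[low_wt]), "undefined_wt_level",
                           "low_wt_mchh")
  missing_mut <- !low_wt & (is.na(mchh_cmt2) | is.na(mchh_drm2))
  label[missing_mut] <- "unclassified"
  reason[missing_mut] <- "undefined_mutant_level"
  short <- te_length <= length_min
  label[short] <- "unclassified"
  reason[short] <- "short_te"
  data.frame(label = label, p_cmt2 = p_cmt2, p_drm2 = p_drm2,
             reason = reason, stringsAsFactors = FALSE)
}

#' Classify MET1 dependence of TEs
#'
#' `dependent` if wild-type mCHH >= 0.05 and *met1* mCHH < 0.02;
#' `independent` if both >= 0.05; otherwise (including TEs falling between
#' the cutoffs or with undefined levels) `unassigned`.
#'
#' @param mchh_wt,mchh_met1 Per-TE weighted mCHH levels.
#' @param wt_min Wild-type gate (default 0.05, inclusive).
#' @param dep_max Loss threshold in *met1* (default 0.02, exclusive).
#' @param indep_min Retention threshold in *met1* (default 0.05, inclusive).
#' @return Character vector in `{dependent, independent, unassigned}`.
#' @export
classify_met1_dependence <- function(mchh_wt, mchh_met1, wt_min = 0.05,
                                     dep_max = 0.02, indep_min = 0.05) {
  out <- rep("unassigned", length(mchh_wt))
  ok <- !is.na(mchh_wt) & !is.na(mchh_met1) & mchh_wt >= wt_min
  out[ok & mchh_met1 < dep_max] <- "dependent"
  out[ok & mchh_met1 >= indep_min] <- "independent"
  out
}

#' Group sRNA clusters by H3K9me and mCHH (high/low)
#'
#' First letter: H3K9me high (`H`) under the chosen scheme --
#' `me1_and_me2`: H3K9me1 > 0.5 and H3K9me2 > 0; `me2_only`: H3K9me2 > 0.
#' Second letter: `H` iff mCHH > 0.05.
#'
#' @param h3k9me1,h3k9me2,mchh Per-cluster enrichment / level values.
#' @param scheme `"me1_and_me2"` or `"me2_only"`.
#' @return Character vector of two-letter groups in `{HH, HL, LH, LL}`.
#' @export
group_clusters_HL <- function(h3k9me1, h3k9me2, mchh,
                              scheme = c("me1_and_me2", "me2_only")) {
  scheme <- match.arg(scheme)
  k9_high <- if (scheme == "me1_and_me2") {
    h3k9me1 > 0.5 & h3k9me2 > 0
  } else {
    h3k9me2 > 0
  }
  paste0(ifelse(k9_high, "H", "L"), ifelse(mchh > 0.05, "H", "L"))
}

#' Classify non-CG methylation retention between genotypes
#'
#' For features with wild-type mCH above `keep_thresh` (a precondition;
#' violating rows are an error): `kept` if the mutant value stays above
#' `keep_thresh`, `lost` if it falls below `lose_thresh`, otherwise
#' `intermediate`.
#'
#' @param mch_wt,mch_mut Per-feature mCH values (levels or densities).
#' @param keep_thresh Retention threshold (default 0.01).
#' @param lose_thresh Loss threshold (default 0.005).
#' @return Character vector in `{kept, lost, intermediate}`.
#' @export
classify_mch_retention <- function(mch_wt, mch_mut, keep_thresh = 0.01,
                                   lose_thresh = 0.005) {
  if (any(is.na(mch_wt)) || any(mch_wt <= keep_thresh)) {
    .stopf("classify_mch_retention requires wild-type mCH > %g for all rows",
           keep_thresh)
  }
  out <- rep("intermediate", length(mch_wt))
  out[mch_mut > keep_thresh] <- "kept"
  out[mch_mut < lose_thresh] <- "lost"
  out
}

#' Overlap counts between two id sets
#'
#' @param set_a,set_b Character vectors of ids (duplicates ignored).
#' @return Named integer vector `c(a_only, shared, b_only)`.
#' @export
overlap_counts <- function(set_a, set_b) {
  a <- unique(set_a)
  b <- unique(set_b)
  shared <- length(intersect(a, b))
  c(a_only = length(a) - shared, shared = shared,
    b_only = length(b) - shared)
}

#' Count features above a threshold
#'
#' @param values Per-feature values (no `NA`s).
#' @param thresh Threshold; counts values strictly greater.
#' @return Integer count.
#' @export
threshold_count <- function(values, thresh) {
  if (any(is.na(values))) .stopf("threshold_count: values must be defined")
  sum(values > thresh)
}
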