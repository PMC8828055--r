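# Synthetic epigenome generator: a seeded toy genome with TE annotations,
# nucleosome dyads, and genotype-conditioned methylomes, small RNA and
# ChIP/input read sets carrying the statistical structure the analysis
# assumes (class-specific GC, pathway-specific mCHH loss in mutants,
# sRNA relocation from AT-rich to GC-rich TEs without H1, linker-biased
# sRNA, genotype-specific nucleosome repeat length). The per-TE generating
# class, configured repeat lengths and dyad positions are emitted as ground
# truth alongside the data and are never consumed by the analysis modules.
#
# All rate and probability defaults are invented (chosen to mirror the
# qualitative genotype effects the analysis is designed to detect), not
# measured values.

.default_meth_prob <- function() {
  # per genotype x TE class: c(CG, CHG, CHH) methylation probabilities.
  # "CMT_dep" applies to the MET1-dependent subset of CMT-like TEs in
  # met1-background genotypes.
  tab <- function(...) lapply(list(...), function(x)
    setNames(x, c("CG", "CHG", "CHH")))
  list(
    wt = tab(CMT = c(.90, .45, .12), DRM = c(.55, .10, .15),
             intermediate = c(.80, .30, .10), background = c(.03, .01, .01)),
    h1 = tab(CMT = c(.90, .55, .20), DRM = c(.55, .06, .08),
             intermediate = c(.80, .35, .14), background = c(.03, .01, .01)),
    cmt2 = tab(CMT = c(.90, .45, .006), DRM = c(.55, .10, .15),
               intermediate = c(.80, .30, .06),
               background = c(.03, .01, .008)),
    drm2 = tab(CMT = c(.90, .45, .12), DRM = c(.55, .08, .006),
               intermediate = c(.80, .30, .06),
               background = c(.03, .01, .008)),
    c2c3 = tab(CMT = c(.90, .02, .006), DRM = c(.55, .08, .12),
               intermediate = c(.80, .05, .05),
               background = c(.03, .005, .008)),
    h1c2c3 = tab(CMT = c(.90, .02, .008), DRM = c(.55, .08, .12),
                 intermediate = c(.80, .05, .05),
                 background = c(.03, .005, .008)),
    met1 = tab(CMT = c(.01, .40, .10), CMT_dep = c(.01, .02, .005),
               DRM = c(.01, .08, .12), intermediate = c(.01, .25, .08),
               background = c(.01, .01, .01)),
    h1met1 = tab(CMT = c(.01, .50, .16), CMT_dep = c(.01, .02, .006),
                 DRM = c(.01, .06, .08), intermediate = c(.01, .30, .10),
                 background = c(.01, .01, .01))
  )
}

.default_srna_rate <- function() {
  # relative per-bp 24-nt sRNA intensity per genotype x class. The h1 CMT
  # rate is 5.6x the wt CMT rate: without the linker histone, sRNA
  # production relocates into the GC-rich CMT-like TEs.
  list(
    wt = c(CMT = 0.1, DRM = 8, intermediate = 3, background = 0.2),
    h1 = c(CMT = 0.56, DRM = 4.6, intermediate = 3, background = 0.2),
    cmt2 = c(CMT = 0.1, DRM = 8, intermediate = 3, background = 0.2),
    drm2 = c(CMT = 0.1, DRM = 4, intermediate = 2, background = 0.2),
    c2c3 = c(CMT = 0.1, DRM = 8, intermediate = 3, background = 0.2),
    h1c2c3 = c(CMT = 0.15, DRM = 7, intermediate = 3, background = 0.2),
    met1 = c(CMT = 0.08, CMT_dep = 0.02, DRM = 8, intermediate = 3,
             background = 0.2),
    h1met1 = c(CMT = 0.5, CMT_dep = 0.03, DRM = 5, intermediate = 3,
               background = 0.2)
  )
}

.default_chip_enrichment <- function() {
  # per mark x class read-density ratio over background; "default" applies
  # to every genotype without an explicit override. The c2c3/h1c2c3
  # overrides reduce H3K9me at CMT-like TEs (partial retention).
  list(
    default = list(
      H3K9me1 = c(CMT = 4, DRM = 1.2, intermediate = 2.2, background = 1),
      H3K9me2 = c(CMT = 3.5, DRM = 1.1, intermediate = 2, background = 1)
    ),
    c2c3 = list(
      H3K9me1 = c(CMT = 1.8, DRM = 1.1, intermediate = 1.4, background = 1),
      H3K9me2 = c(CMT = 1.6, DRM = 1.05, intermediate = 1.3, background = 1)
    ),
    h1c2c3 = list(
      H3K9me1 = c(CMT = 2.2, DRM = 1.1, intermediate = 1.5, background = 1),
      H3K9me2 = c(CMT = 1.8, DRM = 1.05, intermediate = 1.4, background = 1)
    )
  )
}

#' Configuration of the synthetic epigenome
#'
#' Returns the default simulation configuration, optionally overriding
#' individual entries. Defaults: one 2 Mb chromosome; 120 long GC-rich
#' CMT-like TEs, 150 short AT-rich DRM-like TEs, 60 intermediate TEs;
#' nucleosome repeat length 180 bp in H1-containing genotypes and 167 bp
#' without H1, with 10 bp positioning jitter; bisulfite coverage mean 12
#' with non-conversion error 0.005; 300k sRNA reads (95 percent 24-nt) with
#' a 3x linker intensity multiplier; 300k ChIP and input reads per mark;
#' H1 enrichment a logistic function of TE GC content. See
#' `.default_meth_prob`, `.default_srna_rate`, `.default_chip_enrichment`
#' in the sources for the full genotype tables (invented defaults that
#' encode the qualitative genotype effects).
#'
#' @param ... Named overrides of any configuration entry.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(...) {
  cfg <- list(
    genome_bp = 2e6,
    chrom = "chr1",
    n_te = c(CMT = 120, DRM = 150, intermediate = 60),
    te_length = list(CMT = c(1500, 4000), DRM = c(300, 800),
                     intermediate = c(500, 1500)),
    gc_class = list(CMT = c(mean = 0.42, sd = 0.05),
                    DRM = c(mean = 0.28, sd = 0.05),
                    intermediate = c(mean = 0.35, sd = 0.05)),
    gc_background = 0.32,
    min_gap = 200,
    nrl = c(wt = 180, h1 = 167, cmt2 = 180, drm2 = 180, c2c3 = 180,
            h1c2c3 = 167, met1 = 180, h1met1 = 167),
    dyad_jitter_sd = 10,
    meth_prob = .default_meth_prob(),
    met1_dependent_fraction = 0.25,
    bs_coverage = 12,
    non_conversion = 0.005,
    srna_rate = .default_srna_rate(),
    linker_multiplier = 3,
    srna_depth = 3e5,
    frac_21nt = 0.05,
    chip_enrichment = .default_chip_enrichment(),
    chip_noise_sd = 0.2,
    chip_depth = 3e5,
    chip_read_bp = 100,
    h1_logistic = c(slope = 25, midpoint = 0.35, max = 3)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    .stopf("unknown sim_config entr%s: %s", if (length(bad) > 1) "ies" else "y",
           paste(bad, collapse = ", "))
  }
  cfg[names(over)] <- over
  stopifnot(all(unlist(lapply(cfg$meth_prob, unlist)) >= 0),
            all(unlist(lapply(cfg$meth_prob, unlist)) <= 1),
            all(unlist(cfg$srna_rate) >= 0), all(cfg$nrl > 0))
  class(cfg) <- c("sim_config", "list")
  cfg
}

#' Build a synthetic genome with TE annotations and nucleosome dyads
#'
#' Draws a random genome sequence with class-specific GC content inside
#' non-overlapping TEs (GC-rich CMT-like, AT-rich DRM-like, intermediate),
#' tiles nucleosome dyads through each TE at the genotype-specific repeat
#' length with Gaussian positioning jitter, and emits the ground truth
#' (per-TE generating class, MET1-dependence flags, per-TE GC, configured
#' repeat lengths, dyad positions). Deterministic under `seed`.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @return A list of class `synthetic_epigenome`: `cfg`, `genome` (named
#'   character vector), `tes` ([feature_intervals()]), `dyads` (named list
#'   per genotype of [feature_intervals()] 1-bp anchors), `sites` (cached
#'   [cytosine_sites()] of the genome), `truth`.
#' @export
build_genome <- function(cfg = sim_config(), seed = 1) {
  .with_seed(seed, {
    classes <- rep(names(cfg$n_te), cfg$n_te)
    n <- length(classes)
    lens <- vapply(classes, function(cl) {
      r <- cfg$te_length[[cl]]
      as.integer(round(runif(1, r[1], r[2])))
    }, integer(1))
    ord <- sample.int(n)
    classes <- classes[ord]
    lens <- lens[ord]
    free <- cfg$genome_bp - sum(lens) - cfg$min_gap * (n + 1)
    if (free < 0) {
      .stopf(paste0("TEs cannot be placed without overlap; increase ",
                    "genome_bp or reduce TE number/length"))
    }
    extra <- as.vector(stats::rmultinom(1, free, rep(1, n + 1)))
    gaps <- cfg$min_gap + extra
    starts <- cumsum(gaps[seq_len(n)]) + c(0L, cumsum(lens[-n]))
    ends <- starts + lens
    ids <- sprintf("te%03d", seq_len(n))
    tes <- feature_intervals(cfg$chrom, starts, ends,
                             sample(c("+", "-"), n, replace = TRUE), ids)
    # sequence: background first, then patch in class-specific TE bodies
    gc_te <- vapply(classes, function(cl) {
      g <- cfg$gc_class[[cl]]
      min(max(rnorm(1, g["mean"], g["sd"]), 0.15), 0.65)
    }, numeric(1))
    base_prob <- function(g) c(A = (1 - g) / 2, C = g / 2, G = g / 2,
                               T = (1 - g) / 2)
    v <- sample(c("A", "C", "G", "T"), cfg$genome_bp, replace = TRUE,
                prob = base_prob(cfg$gc_background))
    for (i in seq_len(n)) {
      v[(starts[i] + 1):ends[i]] <- sample(c("A", "C", "G", "T"), lens[i],
                                           replace = TRUE,
                                           prob = base_prob(gc_te[i]))
    }
    genome <- setNames(paste(v, collapse = ""), cfg$chrom)
    # nucleosome dyads per genotype: tiled through each TE at the
    # genotype NRL with jitter, keeping a full core particle inside the TE
    dyads <- lapply(cfg$nrl, function(nrl) {
      pos <- integer(0)
      te_of <- integer(0)
      for (i in seq_len(n)) {
        p <- starts[i] + 73 + round(runif(1, 0, nrl - 1))
        ps <- integer(0)
        while (p <= ends[i] - 73) {
          ps <- c(ps, p)
          p <- p + as.integer(round(nrl + rnorm(1, 0, cfg$dyad_jitter_sd)))
        }
        pos <- c(pos, ps)
        te_of <- c(te_of, rep(i, length(ps)))
      }
      fd <- feature_intervals(cfg$chrom, pos, pos + 1L, ".",
                              sprintf("dyad%05d", seq_along(pos)))
      fd$te_id <- ids[te_of]
      fd
    })
    met1_dep <- sort(sample(ids[classes == "CMT"],
                            round(cfg$met1_dependent_fraction *
                                    sum(classes == "CMT"))))
    truth <- list(te_class = setNames(classes, ids),
                  te_gc = setNames(gc_te, ids),
                  met1_dependent = met1_dep,
                  nrl = cfg$nrl, seed = seed)
    structure(list(cfg = cfg, genome = genome, tes = tes, dyads = dyads,
                   sites = cytosine_sites(genome), truth = truth),
              class = "synthetic_epigenome")
  })
}

# TE class per genomic position/site; background where no TE overlaps.
# met1-background genotypes split CMT-like TEs into dependent/independent.
.site_class <- function(sim, chrom, pos, genotype) {
  cls <- rep("background", length(pos))
  hits <- GenomicRanges::findOverlaps(.pos_granges(chrom, pos),
                                      .as_granges(sim$tes))
  te_cls <- unname(sim$truth$te_class[sim$tes$id])
  cls[S4Vectors::queryHits(hits)] <- te_cls[S4Vectors::subjectHits(hits)]
  if (genotype %in% c("met1", "h1met1")) {
    dep_ids <- sim$truth$met1_dependent
    dep <- sim$tes$id[S4Vectors::subjectHits(hits)] %in% dep_ids &
      te_cls[S4Vectors::subjectHits(hits)] == "CMT"
    cls[S4Vectors::queryHits(hits)[dep]] <- "CMT_dep"
  }
  cls
}

#' Simulate a genotype's methylome
#'
#' Per-cytosine coverage is Poisson with the configured mean; the
#' methylated read count is binomial with probability
#' `p + (1 - p) * non_conversion`, where `p` comes from the genotype x
#' class x context probability table. Cytosines with undetermined context
#' are omitted. Deterministic under `seed`.
#'
#' @param sim A [build_genome()] object.
#' @param genotype Genotype name (must be in `cfg$meth_prob`).
#' @param seed Integer seed.
#' @return A [cytosine_records()] data.frame.
#' @export
simulate_methylome <- function(sim, genotype, seed = 1) {
  tab <- sim$cfg$meth_prob[[genotype]]
  if (is.null(tab)) {
    .stopf("unknown genotype '%s'; available: %s", genotype,
           paste(names(sim$cfg$meth_prob), collapse = ", "))
  }
  sites <- sim$sites[sim$sites$context != "undetermined", , drop = FALSE]
  cls <- .site_class(sim, sites$chrom, sites$pos, genotype)
  cls[cls == "CMT_dep" & !("CMT_dep" %in% names(tab))] <- "CMT"
  p <- mapply(function(cl, ctx) tab[[cl]][[ctx]], cls, sites$context,
              USE.NAMES = FALSE)
  p_obs <- p + (1 - p) * sim$cfg$non_conversion
  .with_seed(seed, {
    cov <- rpois(nrow(sites), sim$cfg$bs_coverage)
    meth <- rbinom(nrow(sites), cov, p_obs)
    cytosine_records(sites$chrom, sites$pos, sites$strand, meth, cov - meth,
                     sites$context, sites$subcontext)
  })
}

# Per-bp 24-nt sRNA intensity for a genotype: class x genotype base rate,
# multiplied inside nucleosome linkers (between dyad+73 and next dyad-73
# within a TE).
.srna_intensity <- function(sim, genotype) {
  cfg <- sim$cfg
  rates <- cfg$srna_rate[[genotype]]
  if (is.null(rates)) {
    .stopf("unknown genotype '%s'; available: %s", genotype,
           paste(names(cfg$srna_rate), collapse = ", "))
  }
  L <- cfg$genome_bp
  intensity <- rep(rates[["background"]], L)
  te_cls <- unname(sim$truth$te_class[sim$tes$id])
  dep_ids <- sim$truth$met1_dependent
  for (i in seq_len(nrow(sim$tes))) {
    cl <- te_cls[i]
    if (genotype %in% c("met1", "h1met1") && cl == "CMT" &&
        sim$tes$id[i] %in% dep_ids && "CMT_dep" %in% names(rates)) {
      cl <- "CMT_dep"
    }
    intensity[(sim$tes$start[i] + 1):sim$tes$end[i]] <- rates[[cl]]
  }
  dy <- sim$dyads[[genotype]]
  if (!is.null(dy) && cfg$linker_multiplier != 1) {
    for (te in split(dy$start, dy$te_id)) {
      if (length(te) < 2) next
      from <- te[-length(te)] + 74
      to <- te[-1] - 73
      ok <- to > from
      for (j in which(ok)) {
        intensity[(from[j] + 1):to[j]] <-
          intensity[(from[j] + 1):to[j]] * cfg$linker_multiplier
      }
    }
  }
  intensity
}

#' Simulate a genotype's small RNA read set
#'
#' 24-nt read 5' ends are drawn from the per-bp intensity (class x genotype
#' base rate, elevated `linker_multiplier`-fold in nucleosome linkers);
#' a configured fraction of 21-nt background reads is drawn uniformly.
#' Total depth is `cfg$srna_depth`. Deterministic under `seed`.
#'
#' @inheritParams simulate_methylome
#' @return A [sized_reads()] set (attribute `total_18_28` equals the
#'   configured depth).
#' @export
simulate_srna <- function(sim, genotype, seed = 1) {
  cfg <- sim$cfg
  intensity <- .srna_intensity(sim, genotype)
  if (sum(intensity) == 0) .stopf("zero total sRNA intensity")
  L <- cfg$genome_bp
  n24 <- round(cfg$srna_depth * (1 - cfg$frac_21nt))
  n21 <- cfg$srna_depth - n24
  .with_seed(seed, {
    p24 <- sample.int(L, n24, replace = TRUE, prob = intensity) - 1L
    p21 <- sample.int(L, n21, replace = TRUE) - 1L
    pos <- c(p24, p21)
    len <- rep(c(24L, 21L), c(n24, n21))
    strand <- sample(c("+", "-"), n24 + n21, replace = TRUE)
    # pos is the 5' end; clamp so the whole read lies on the chromosome
    pos <- pmin(pmax(pos, len), L - len - 1L)
    start <- ifelse(strand == "+", pos, pos - len + 1L)
    sized_reads(cfg$chrom, start, start + len, strand)
  })
}

#' Expected between-genotype sRNA rpkm fold change per TE class
#'
#' The fold change the generator encodes: with rpkm normalized to total
#' mapped fragments, the expected measured class fold equals the ratio of
#' per-TE intensity shares, not the naive rate-table ratio. This computes
#' the expected per-TE rpkm (up to a constant that cancels) from the
#' intensity model of each genotype and returns mean(class, b) /
#' mean(class, a), i.e. exactly what [genotype_change()] estimates from
#' reads.
#'
#' @param sim A [build_genome()] object.
#' @param genotype_a,genotype_b Reference and comparison genotypes.
#' @return A `data.frame`: `class`, `expected_fold`.
#' @export
expected_srna_fold <- function(sim, genotype_a, genotype_b) {
  ia <- .srna_intensity(sim, genotype_a)
  ib <- .srna_intensity(sim, genotype_b)
  ia <- ia / sum(ia)
  ib <- ib / sum(ib)
  lens <- sim$tes$end - sim$tes$start
  share <- function(x) vapply(seq_len(nrow(sim$tes)), function(i) {
    sum(x[(sim$tes$start[i] + 1):sim$tes$end[i]])
  }, numeric(1))
  ra <- share(ia) / lens
  rb <- share(ib) / lens
  cls <- unname(sim$truth$te_class[sim$tes$id])
  out <- data.frame(class = unique(cls), stringsAsFactors = FALSE)
  out$expected_fold <- vapply(out$class, function(k) {
    mean(rb[cls == k]) / mean(ra[cls == k])
  }, numeric(1))
  out
}

#' Simulate a ChIP/input read-set pair for a chromatin mark
#'
#' Input reads are uniform over the genome; ChIP read positions are drawn
#' from a per-bp intensity equal to the configured class enrichment ratio
#' inside TEs (with per-TE lognormal noise) and 1 in the background. For
#' H1 the per-TE ratio is a logistic function of the TE's GC content
#' (`1 + max * plogis(slope * (gc - midpoint))`), making H1 track the
#' GC dichotomy of the two TE classes. Deterministic under `seed`.
#'
#' @inheritParams simulate_methylome
#' @param mark `"H1"`, `"H3K9me1"`, or `"H3K9me2"`.
#' @return A list with [sized_reads()] elements `chip` and `input`.
#' @export
simulate_chip <- function(sim, mark, genotype = "wt", seed = 1) {
  cfg <- sim$cfg
  if (!mark %in% c("H1", "H3K9me1", "H3K9me2")) {
    .stopf("unknown mark '%s'; available: H1, H3K9me1, H3K9me2", mark)
  }
  te_cls <- unname(sim$truth$te_class[sim$tes$id])
  n <- nrow(sim$tes)
  L <- cfg$genome_bp
  rb <- cfg$chip_read_bp
  .with_seed(seed, {
    ratio <- if (mark == "H1") {
      hl <- cfg$h1_logistic
      1 + hl[["max"]] *
        plogis(hl[["slope"]] * (unname(sim$truth$te_gc[sim$tes$id]) -
                                  hl[["midpoint"]]))
    } else {
      enr <- cfg$chip_enrichment[[genotype]]
      if (is.null(enr)) enr <- cfg$chip_enrichment$default
      enr[[mark]][te_cls] * rlnorm(n, 0, cfg$chip_noise_sd)
    }
    intensity <- rep(1, L)
    for (i in seq_len(n)) {
      intensity[(sim$tes$start[i] + 1):sim$tes$end[i]] <- ratio[i]
    }
    cpos <- sample.int(L, cfg$chip_depth, replace = TRUE,
                       prob = intensity) - 1L
    ipos <- sample.int(L, cfg$chip_depth, replace = TRUE) - 1L
    clamp <- function(p) pmin(pmax(p, 0L), L - rb)
    list(
      chip = sized_reads(cfg$chrom, clamp(cpos), clamp(cpos) + rb, "."),
      input = sized_reads(cfg$chrom, clamp(ipos), clamp(ipos) + rb, ".")
    )
  })
}

#' Filter the TE universe by minimum length
#'
#' @param features A [feature_intervals()] data.frame.
#' @param min_bp Minimum element length kept (default 250).
#' @return The filtered [feature_intervals()].
#' @export
filter_te_universe <- function(features, min_bp = 250) {
  features[(features$end - features$start) >= min_bp, , drop = FALSE]
}

#' Run the pathway classification on simulated wt/cmt2/drm2 methylomes
#'
#' Simulates the three methylomes, summarizes CHH methylation over the
#' (length-filtered) TE universe and applies [classify_pathway()]. The
#' ground truth is not consulted.
#'
#' @param sim A [build_genome()] object.
#' @param seed Integer seed (per-genotype seeds are derived from it).
#' @param min_universe_bp TE universe length filter (default 250).
#' @return A `data.frame`: `id`, `label`, `p_cmt2`, `p_drm2`, `mchh_wt`,
#'   `mchh_cmt2`, `mchh_drm2`.
#' @export
sim_classify_tes <- function(sim, seed = 1, min_universe_bp = 250) {
  tes <- filter_te_universe(sim$tes, min_universe_bp)
  genos <- c("wt", "cmt2", "drm2")
  summ <- setNames(lapply(seq_along(genos), function(k) {
    summarize_methylation(simulate_methylome(sim, genos[k], seed = seed + k),
                          tes)
  }), genos)
  cls <- classify_pathway(
    mchh_wt = summ$wt$m_CHH, mchh_cmt2 = summ$cmt2$m_CHH,
    mchh_drm2 = summ$drm2$m_CHH,
    meth_wt = summ$wt$reads_meth_CHH, unmeth_wt = summ$wt$reads_unmeth_CHH,
    meth_cmt2 = summ$cmt2$reads_meth_CHH,
    unmeth_cmt2 = summ$cmt2$reads_unmeth_CHH,
    meth_drm2 = summ$drm2$reads_meth_CHH,
    unmeth_drm2 = summ$drm2$reads_unmeth_CHH,
    te_length = tes$end - tes$start)
  data.frame(id = tes$id, label = cls$label, p_cmt2 = cls$p_cmt2,
             p_drm2 = cls$p_drm2, mchh_wt = summ$wt$m_CHH,
             mchh_cmt2 = summ$cmt2$m_CHH, mchh_drm2 = summ$drm2$m_CHH,
             stringsAsFactors = FALSE)
}

#' Assemble the per-TE feature matrix from one simulated genotype
#'
#' Simulates a methylome, an sRNA read set and the three ChIP marks for
#' `genotype`, computes per-TE summaries (methylation levels/densities,
#' 24-nt sRNA rpkm, log2 ChIP/input with 25 percent input subsampling),
#' and assembles them with GC content and context-site densities via
#' [build_feature_matrix()].
#'
#' @param sim A [build_genome()] object.
#' @param seed Integer seed (sub-seeds are derived from it).
#' @param genotype Genotype to simulate (default `"wt"`).
#' @param labels Optional per-TE labels (named by id), e.g. from
#'   [sim_classify_tes()].
#' @param input_fraction Input subsampling fraction for the ChIP
#'   enrichment (default 0.25).
#' @return A feature matrix `data.frame` (see [build_feature_matrix()]).
#' @export
sim_te_matrix <- function(sim, seed = 1, genotype = "wt", labels = NULL,
                          input_fraction = 0.25) {
  tes <- filter_te_universe(sim$tes)
  meth <- summarize_methylation(simulate_methylome(sim, genotype, seed + 11),
                                tes)
  srna <- simulate_srna(sim, genotype, seed + 12)
  tracks <- list(sRNA_24 = srna_rpkm(srna, tes, "24"))
  marks <- c("H1", "H3K9me1", "H3K9me2")
  for (k in seq_along(marks)) {
    pair <- simulate_chip(sim, marks[k], genotype, seed + 12 + k)
    tracks[[marks[k]]] <- chip_feature_enrichment(
      pair$chip, pair$input, tes, input_fraction = input_fraction,
      seed = seed + 20 + k)
  }
  build_feature_matrix(tes, meth, tracks = tracks, genome = sim$genome,
                       labels = labels)
}
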