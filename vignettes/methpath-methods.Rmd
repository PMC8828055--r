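---
title: "Classifying transposable elements by methylation pathway: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying transposable elements by methylation pathway: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(methpath)
```

# The analysis

Flowering-plant genomes silence transposable elements (TEs) through two
largely separate cytosine-methylation systems. GC-rich, heterochromatic TEs
carry non-CG methylation (mCHG/mCHH, jointly mCH) maintained by
chromomethylases (CMT2/CMT3) in a feedback loop with H3K9 methylation.
Short, AT-rich euchromatic TEs are methylated by RNA-directed DNA
methylation (RdDM): 24-nt small RNAs produced from Pol IV transcripts guide
DRM2 to its targets. The linker histone H1 is enriched on GC-rich
heterochromatin, and its loss lets RdDM relocate into heterochromatic TEs,
preferentially into nucleosome linker DNA.

`methpath` implements the desk-scale statistical machinery of that
analysis:

1. **Methylation core.** Cytosine context assignment (CG / CHG / CHH with
   CCG/CWG and CWA/nonCWA subcontexts, W = A/T), weighted methylation
   levels (sum of methylated read counts over sum of total read counts
   across covered sites), and methylated-site densities (called sites per
   bp).
2. **TE pathway classification.** Among TEs longer than 200 bp with
   wild-type mCHH > 0.02, a TE is *CMT-dependent* when its mCHH falls
   below 0.02 in *cmt2* with Fisher's exact test p < 0.01 on the pooled
   CHH read counts (wild type vs mutant), *DRM-dependent* symmetrically
   for *drm2*; TEs passing both criteria form a dedicated
   `both_depleted` class, everything else above the wild-type gate is
   `intermediate`. Companion rules: MET1 dependence (wt mCHH >= 0.05;
   *met1* < 0.02 dependent, >= 0.05 independent), CLSY-cluster H/L
   grouping (H3K9me1 > 0.5 and H3K9me2 > 0, mCHH > 0.05), and mCH
   retention (keep > 0.01, lose < 0.005).
3. **Coverage tracks.** 21/24-nt small RNA rpkm normalized to the total
   18-28 nt mapped fragments, and ChIP log2(ChIP/input) with seeded
   subsampling of the input to a fraction (default 25%) of the ChIP total.
4. **Profiles and phasing.** Strand-aware ends-anchored metaplots (with
   removal of sRNA bins above 200 rpkm so a handful of extreme loci do not
   dominate the average), nucleosome-dyad-anchored 24-nt sRNA profiles in
   10-bp bins, their autocorrelation, and a nucleosome repeat length (NRL)
   estimate.
5. **Feature matrix and random forest.** Per-TE matrices of methylation
   levels/densities, ChIP enrichments, sRNA rpkm, GC content and
   context-site densities; random-forest variable importance and held-out
   prediction error for the CMT/DRM distinction.
6. **Association statistics.** GC-sorted 100-TE binning, between-genotype
   deltas and class fold changes, Pearson correlation matrices, PCA, and
   pairwise rank-sum group comparisons with BH adjustment.
7. **Synthetic epigenome.** A seeded generator producing a toy genome,
   TE annotations, nucleosome dyads, and genotype-conditioned methylomes,
   sRNA and ChIP read sets, with ground truth emitted alongside.

# Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| wild-type mCHH gate | > 0.02 | level | classification universe threshold (strict inequality) |
| mutant mCHH loss | < 0.02, p < 0.01 | level / Fisher p | pathway-dependence call; raw p cutoff, BH available off by default |
| classification length gate | > 200 | bp | short elements give unstable levels |
| TE universe filter | >= 250 | bp | annotation hygiene; both length filters coexist and are configurable |
| `min_cov` | 3 | reads | weighted levels on lower coverage are noisy |
| site-call rule | p < 0.01 vs error 0.005 | binomial | a methylated-site call aware of bisulfite non-conversion |
| rpkm normalizer | total 18-28 nt reads | count | size-selected library total |
| `rpkm_cap` | 200 | rpkm | metaplot outlier-bin removal |
| `input_fraction` | 0.25 | fraction of ChIP total | input subsampling before the log2 ratio |
| `pseudocount` | 0.5 | scaled counts | finite ratios at zero-count bins |
| dyad window / bin | ±1000 / 10 | bp | covers ~5 repeats either side at 10-bp resolution |
| NRL search range | 100-300 | bp | brackets plausible plant repeat lengths |
| train/validation split | 50/50 | fraction | stratified; assignment hashed from feature ids |
| `n_trees` | 500 | trees | stable importance at this data size |

# Design choices

**Weighted vs site-averaged levels.** Per-feature methylation is the
read-count-weighted level (Σmeth / Σtotal over covered sites), the standard
for bisulfite data because it is robust to uneven coverage; site-averaging
would overweight low-coverage sites. Symmetric CG positions are *not*
pooled across strands: each strand's cytosine is a site, matching the
granularity of per-cytosine reports.

**The Fisher table.** The 2x2 table pools methylated/unmethylated CHH read
counts across a TE's covered sites, wild type vs mutant. Pooled reads use
all the evidence a TE offers and behave sensibly for short elements;
counting sites instead would discard coverage information. The two-sided
p-value enumerates the hypergeometric distribution over the fixed margins
and sums the probabilities of tables no more probable than the observed one,
with the conventional (1 + 1e-7) relative tie tolerance — mathematically
tied tables must not drop out of the sum because their floating-point
probabilities differ in the last bit.

**Read anchoring and overlap.** sRNA reads enter dyad profiles by their 5'
end (midpoint available as an option) and enter per-feature counts under an
any-overlap rule (midpoint optional). Multi-mapped reads, when present in
the input, count once per reported alignment.

**Random forest.** The ensemble is delegated to `randomForest` (bagged
trees, per-tree bootstrap, sqrt(p) feature subsampling). The train/validation
split is decided by a seeded hash of feature ids, stratified by class, and
rows are put in a canonical id order before fitting — so reports are
identical across runs *and* across row permutations of the input. The
held-out validation error is the headline number; the out-of-bag estimate
is reported alongside.

**Autocorrelation and the NRL.** The autocorrelation uses the biased
(divide-by-n) estimator, the default of R's `acf`. The NRL estimate is the
lag of the first local acf maximum inside the search range, in units of the
profile bin (so estimates are multiples of 10 bp by default), and is left
undefined when no peak clears the 1.96/sqrt(n) white-noise band. A
dyad-anchored average over TEs that are globally sRNA-enriched relative to
their flanks carries a broad central envelope; `autocorrelate()` therefore
offers optional moving-average detrending (`detrend_bins`, default off).
Without detrending the envelope pulls the first acf peak one bin short of
the configured repeat on simulated data; with a 21-bin detrend the
estimator recovers the wild-type repeat exactly and the h1 repeat to within
one bin (167 is not representable on a 10-bp grid).

**PCA and group tests.** Columns are z-scored before PCA because the
variables mix log-ratios, proportions and densities. The significance test
behind group comparisons is the two-sided Mann-Whitney U (rank-sum),
robust for the skewed enrichment distributions involved; Welch's t is
available by flag. The reported U is oriented to the first group of each
pair. The final partial GC bin is retained, not merged.

# What the generator emulates — and what it does not

The synthetic epigenome encodes, per genotype (wt, h1, cmt2, drm2, c2c3,
h1c2c3, met1, h1met1):

- class-specific TE architecture: long GC-rich CMT-like TEs, short AT-rich
  DRM-like TEs, and intermediates, with per-TE GC drawn from overlapping
  class distributions (so GC-linked predictors are informative but not
  perfect);
- a methylation probability table per genotype x class x context, with
  bisulfite coverage Poisson(12) and non-conversion error 0.005;
- 24-nt sRNA intensity per class and genotype, with the h1 CMT-like rate
  5.6x the wild-type rate (relocation into heterochromatin) and a 3x
  multiplier in nucleosome linkers (the interval between dyad+73 and the
  next dyad−73; the 147-bp core particle defines the linker bounds, and
  the magnitude of the bias in real data is not quantified — 3 is a free
  parameter);
- nucleosome dyads tiled at repeat length 180 bp (h1-containing genotypes:
  167 bp) with 10 bp Gaussian jitter;
- ChIP enrichment ratios per mark and class, with H1 a logistic function
  of TE GC content so that H1 alone is a strong but imperfect predictor of
  the pathway classes;
- a MET1-dependent subset (25%) of CMT-like TEs that loses mCH in met1
  backgrounds.

All the rates and probabilities are invented defaults chosen once to
mirror the qualitative genotype effects; they are not measurements. Because
rpkm is depth-normalized, the class fold change a comparison recovers is
the ratio of intensity *shares*, not the naive rate ratio;
`expected_srna_fold()` computes the fold the generator actually encodes,
and the fold-recovery check compares against that.

The generator does **not** emulate: overdispersed (negative binomial)
coverage, PCR duplicates or mapping bias; TE nesting, fragmentation or
strand-asymmetric sRNA production; chromosome-scale organization
(pericentromeric gradients); mechanistic Pol IV transcription; or
population variation. Passing tests therefore demonstrate that the
statistical machinery recovers known structure from data with the assumed
sampling distributions — not that the defaults reproduce any particular
organism's measurements, which require the original sequencing data.

Problem sizes were likewise chosen once: one 2 Mb chromosome with 330 TEs
(120/150/60 per class), 300k sRNA reads and 300k ChIP reads per mark, so a
full multi-genotype pipeline run completes in well under a minute.

# Degenerate inputs and numerical conventions

- All internal coordinates are 0-based half-open; conversion happens at
  I/O boundaries only (GFF3 and cytosine reports are 1-based).
- Contexts that cannot be determined (N bases, chromosome ends) are
  excluded from all summaries; levels over zero covered sites are `NA`
  ("undefined"), never 0.
- An all-zero Fisher table, a constant profile (zero variance), an empty
  input track, and a single-class training split are errors, not silent
  results.
- bedGraph values round-trip at 6 significant digits.
- GC-sorted binning breaks ties deterministically by feature id, so bin
  means are independent of input row order.

# Known limitations

- The NRL estimator returns multiples of the profile bin width; repeats
  that are not multiples of 10 bp are recovered to the nearest bin.
- Very short linkers (repeat length near the 147-bp core) leave little
  sRNA signal to phase; below ~13 bp of linker the plain acf cannot detect
  the repeat at realistic depth and the detrended estimator becomes
  essential.
- `classify_pathway` treats mutants independently; a joint model across
  more than two mutants is out of scope.
- The Fisher p-values are raw by default (matching a stated raw cutoff);
  with many TEs, users wanting FDR control should set `bh_correct = TRUE`.
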