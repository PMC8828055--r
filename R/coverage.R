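# Coverage tracks: size-selected sRNA quantification (rpkm normalized to
# total 18-28 nt fragments) and ChIP log2(ChIP/input) enrichment with
# seeded input subsampling.

#' Construct a binned enrichment track
#'
#' @param chrom,start,end Bin coordinates (0-based half-open), sorted and
#'   non-overlapping within chromosome.
#' @param value Numeric value per bin.
#' @param value_kind One of `"raw"`, `"rpkm"`, `"log2ratio"`.
#' @return A `data.frame` of class `enrichment_track` with attribute
#'   `value_kind`.
#' @export
enrichment_track <- function(chrom, start, end, value, value_kind = "raw") {
  value_kind <- match.arg(value_kind, c("raw", "rpkm", "log2ratio"))
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), value = as.numeric(value),
                   stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    o <- order(df$chrom, df$start)
    df <- df[o, , drop = FALSE]
    rownames(df) <- NULL
    for (tc in split(df, df$chrom)) {
      if (nrow(tc) > 1 && any(tc$start[-1] < tc$end[-nrow(tc)])) {
        .stopf("track bins overlap within chromosome '%s'", tc$chrom[1])
      }
    }
  }
  attr(df, "value_kind") <- value_kind
  class(df) <- c("enrichment_track", "data.frame")
  df
}

#' Count reads overlapping features
#'
#' @param reads A [sized_reads()] data.frame.
#' @param features A [feature_intervals()] (or any interval) data.frame.
#' @param overlap_mode `"any"` counts a read if at least 1 bp intersects the
#'   feature; `"midpoint"` requires the read midpoint to fall inside.
#' @return Integer vector of counts, one per feature.
#' @export
count_read_overlaps <- function(reads, features,
                                overlap_mode = c("any", "midpoint")) {
  overlap_mode <- match.arg(overlap_mode)
  if (nrow(reads) == 0 || nrow(features) == 0) {
    return(integer(nrow(features)))
  }
  q <- if (overlap_mode == "any") {
    .as_granges(reads)
  } else {
    .pos_granges(reads$chrom, (reads$start + reads$end) %/% 2L)
  }
  GenomicRanges::countOverlaps(.as_granges(features), q)
}

#' Small RNA rpkm per feature
#'
#' Counts reads of the requested size class overlapping each feature and
#' normalizes to reads per kilobase of feature per million 18-28 nt
#' mapped fragments:
#' `rpkm = count / (length/1000) / (total_18_28/1e6)`.
#'
#' @param reads A [sized_reads()] set; its `total_18_28` attribute is the
#'   normalizer.
#' @param features A [feature_intervals()] data.frame.
#' @param size_class `"24"`, `"21"`, or `"18-28"`.
#' @param overlap_mode See [count_read_overlaps()].
#' @return Named numeric vector of rpkm (names = feature ids).
#' @export
srna_rpkm <- function(reads, features, size_class = c("24", "21", "18-28"),
                      overlap_mode = c("any", "midpoint")) {
  size_class <- match.arg(size_class)
  total <- attr(reads, "total_18_28")
  if (is.null(total)) total <- sum(reads$length >= 18 & reads$length <= 28)
  if (total == 0) .stopf("no mappable sRNA: total 18-28 nt read count is 0")
  sel <- switch(size_class,
                "24" = reads$length == 24,
                "21" = reads$length == 21,
                "18-28" = reads$length >= 18 & reads$length <= 28)
  counts <- count_read_overlaps(reads[sel, , drop = FALSE], features,
                                overlap_mode)
  rpkm <- counts / ((features$end - features$start) / 1000) / (total / 1e6)
  setNames(rpkm, features$id)
}

#' Bin reads into a genome-wide rpkm track
#'
#' @param reads A [sized_reads()] set.
#' @param bin_bp Bin width.
#' @param size_class Size class to count (see [srna_rpkm()]).
#' @param chrom_sizes Named vector of chromosome lengths; defaults to the
#'   maximum read end per chromosome.
#' @return An [enrichment_track()] with `value_kind = "rpkm"`.
#' @export
reads_to_track <- function(reads, bin_bp, size_class = c("24", "21", "18-28"),
                           chrom_sizes = NULL) {
  size_class <- match.arg(size_class)
  total <- attr(reads, "total_18_28")
  if (is.null(total) || total == 0) {
    .stopf("no mappable sRNA: total 18-28 nt read count is 0")
  }
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(reads$end, reads$chrom, max)
  }
  out <- list()
  for (ch in names(chrom_sizes)) {
    starts <- seq(0L, chrom_sizes[[ch]] - 1L, by = bin_bp)
    bins <- feature_intervals(ch, starts,
                              pmin(starts + bin_bp, chrom_sizes[[ch]]),
                              ".", paste0(ch, "_", starts))
    r <- reads[reads$chrom == ch, , drop = FALSE]
    attr(r, "total_18_28") <- total
    out[[ch]] <- data.frame(chrom = ch, start = bins$start, end = bins$end,
                            value = unname(srna_rpkm(r, bins, size_class)))
  }
  df <- do.call(rbind, out)
  enrichment_track(df$chrom, df$start, df$end, df$value, "rpkm")
}

#' ChIP log2 enrichment over input with input subsampling
#'
#' Subsamples the input counts without replacement so that the input total
#' equals `input_fraction` times the ChIP total (seeded, multivariate
#' hypergeometric across bins), depth-scales input to the ChIP total, and
#' returns `log2((chip + pseudocount) / (input_scaled + pseudocount))` per
#' bin.
#'
#' @param chip,input Non-negative integer read counts over identical bins.
#' @param bins Optional data.frame (`chrom`, `start`, `end`) describing the
#'   bins; when supplied the result is an [enrichment_track()], otherwise a
#'   numeric vector.
#' @param input_fraction Fraction of the ChIP total to which input is
#'   subsampled (0 < f <= 1; 0.25 mirrors ChIP pipelines that subsample
#'   input to 25 percent of the uniquely mapped IP reads).
#' @param pseudocount Added to both scaled counts before the ratio
#'   (default 0.5).
#' @param seed Integer seed for the subsample; same seed, same subsample.
#' @return Numeric vector (or [enrichment_track()]) of log2 ratios.
#' @export
chip_log2_ratio <- function(chip, input, bins = NULL, input_fraction = 1,
                            pseudocount = 0.5, seed = NULL) {
  if (length(chip) != length(input)) {
    .stopf("chip and input must be counts over identical bins")
  }
  if (input_fraction <= 0 || input_fraction > 1) {
    .stopf("input_fraction must be in (0, 1]")
  }
  if (sum(input) == 0) .stopf("empty input track")
  target <- round(input_fraction * sum(chip))
  if (target < 1) .stopf("input_fraction yields < 1 input read")
  if (target > sum(input)) {
    .stopf("input has too few reads (%d) to subsample %d", sum(input), target)
  }
  sub <- if (target == sum(input)) {
    input
  } else {
    .with_seed(seed, {
      drawn <- sample(rep.int(seq_along(input), input), target)
      tabulate(drawn, nbins = length(input))
    })
  }
  scale <- sum(chip) / sum(sub)
  value <- log2((chip + pseudocount) / (sub * scale + pseudocount))
  if (is.null(bins)) return(value)
  enrichment_track(bins$chrom, bins$start, bins$end, value, "log2ratio")
}

#' Per-feature ChIP log2 enrichment
#'
#' Convenience wrapper: counts ChIP and input reads per feature and applies
#' [chip_log2_ratio()] with the feature set as bins.
#'
#' @param chip,input [sized_reads()] sets.
#' @param features A [feature_intervals()] data.frame.
#' @inheritParams chip_log2_ratio
#' @param overlap_mode See [count_read_overlaps()].
#' @return Named numeric vector of log2 ratios (names = feature ids).
#' @export
chip_feature_enrichment <- function(chip, input, features,
                                    input_fraction = 1, pseudocount = 0.5,
                                    seed = NULL, overlap_mode = "any") {
  cc <- count_read_overlaps(chip, features, overlap_mode)
  ic <- count_read_overlaps(input, features, overlap_mode)
  # subsampling fraction refers to library totals, not in-feature counts
  chip_total <- nrow(chip)
  input_total <- nrow(input)
  target <- round(input_fraction * chip_total)
  if (target < 1) .stopf("input_fraction yields < 1 input read")
  if (target > input_total) {
    .stopf("input has too few reads (%d) to subsample %d", input_total, target)
  }
  ic_sub <- if (target == input_total) {
    ic
  } else {
    .with_seed(seed, {
      keep <- sample.int(input_total, target)
      count_read_overlaps(input[keep, , drop = FALSE], features, overlap_mode)
    })
  }
  scale <- chip_total / target
  value <- log2((cc + pseudocount) / (ic_sub * scale + pseudocount))
  setNames(value, features$id)
}
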