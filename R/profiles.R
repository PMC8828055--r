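# Ends-anchored metaplots, nucleosome-dyad-anchored sRNA profiles, their
# autocorrelation, and the nucleosome repeat length (NRL) estimate.

#' Ends-anchored metaplot of a binned signal
#'
#' Lays out fixed bins from `-flank_bp` to `+flank_bp` around each
#' feature's 5' and 3' ends in strand orientation (minus-strand features
#' are flipped), takes the overlap-weighted mean of the track within each
#' bin, and averages per offset over features. For rpkm tracks, bins with
#' value above `rpkm_cap` are excluded from the average so a handful of
#' extreme loci do not dominate it.
#'
#' @param track An [enrichment_track()] (binned values).
#' @param features A [feature_intervals()] data.frame; features shorter
#'   than one bin are skipped (count reported via attribute `"skipped"`).
#' @param flank_bp Extent of the profile either side of each end (multiple
#'   of `bin_bp`).
#' @param bin_bp Profile bin width.
#' @param rpkm_cap Exclusion threshold for sRNA (rpkm) tracks
#'   (default 200); ignored for other value kinds.
#' @return A `data.frame` with `end` (`"5p"`/`"3p"`), `offset` (bp of bin
#'   start relative to the anchor), `mean`, `n` (features contributing).
#' @export
ends_profile <- function(track, features, flank_bp, bin_bp,
                         rpkm_cap = 200) {
  if (flank_bp %% bin_bp != 0) .stopf("flank_bp must be a multiple of bin_bp")
  apply_cap <- identical(attr(track, "value_kind"), "rpkm")
  min_len <- bin_bp
  keep <- (features$end - features$start) >= min_len
  skipped <- sum(!keep)
  features <- features[keep, , drop = FALSE]
  if (nrow(features) == 0) .stopf("no feature is at least one bin long")
  offs <- seq(-flank_bp, flank_bp - bin_bp, by = bin_bp)
  n_off <- length(offs)
  nf <- nrow(features)
  minus <- features$strand == "-"
  anchor5 <- ifelse(minus, features$end, features$start)
  anchor3 <- ifelse(minus, features$start, features$end)
  # genomic start of the bin at each (feature, offset, end) combination;
  # on the minus strand increasing offset runs leftward
  grid <- expand.grid(fi = seq_len(nf), oi = seq_len(n_off),
                      which_end = c("5p", "3p"), stringsAsFactors = FALSE)
  o <- offs[grid$oi]
  anc <- ifelse(grid$which_end == "5p", anchor5[grid$fi], anchor3[grid$fi])
  m <- minus[grid$fi]
  gstart <- ifelse(m, anc - o - bin_bp, anc + o)
  q <- GenomicRanges::GRanges(features$chrom[grid$fi],
                              IRanges::IRanges(gstart + 1L, width = bin_bp))
  s <- .as_granges(track)
  hits <- GenomicRanges::findOverlaps(q, s)
  ov <- IRanges::width(IRanges::pintersect(
    IRanges::ranges(q)[S4Vectors::queryHits(hits)],
    IRanges::ranges(s)[S4Vectors::subjectHits(hits)]))
  dt <- data.table::data.table(
    qi = S4Vectors::queryHits(hits),
    w = ov,
    v = track$value[S4Vectors::subjectHits(hits)]
  )
  val <- dt[, .(value = sum(w * v) / sum(w)), by = qi]
  grid$value <- NA_real_
  grid$value[val$qi] <- val$value
  if (apply_cap) grid$value[!is.na(grid$value) & grid$value > rpkm_cap] <- NA
  gdt <- data.table::as.data.table(grid)
  res <- gdt[, .(mean = mean(value, na.rm = TRUE), n = sum(!is.na(value))),
             by = .(which_end, oi)]
  out <- data.frame(end = res$which_end, offset = offs[res$oi],
                    mean = ifelse(res$n > 0, res$mean, NA_real_), n = res$n,
                    stringsAsFactors = FALSE)
  out <- out[order(out$end, out$offset), ]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Dyad-anchored small RNA profile
#'
#' Counts 24-nt read 5' ends per `bin_bp` bin in a window around each
#' nucleosome dyad, normalizes to rpkm (per kb of bin per million 18-28 nt
#' fragments), and averages over dyads.
#'
#' @param reads A [sized_reads()] set; only 24-nt reads are used, and the
#'   `total_18_28` attribute is the rpkm normalizer.
#' @param dyads A [feature_intervals()] data.frame of 1-bp dyad positions.
#' @param window_bp Half-window around the dyad (multiple of `bin_bp`;
#'   default 1000).
#' @param bin_bp Bin width (default 10).
#' @param anchor Read anchoring: `"five_prime"` (default) or `"midpoint"`.
#' @return A `data.frame` of class `phasing_profile` with `offset` (bp of
#'   bin start relative to dyad) and `mean` (mean rpkm over dyads);
#'   attribute `n_anchors`.
#' @export
dyad_profile <- function(reads, dyads, window_bp = 1000, bin_bp = 10,
                         anchor = c("five_prime", "midpoint")) {
  anchor <- match.arg(anchor)
  if (nrow(dyads) == 0) .stopf("no dyads supplied")
  if (window_bp %% bin_bp != 0) {
    .stopf("window_bp must be a multiple of bin_bp")
  }
  total <- attr(reads, "total_18_28")
  if (is.null(total) || total == 0) {
    .stopf("no mappable sRNA: total 18-28 nt read count is 0")
  }
  r <- reads[reads$length == 24, , drop = FALSE]
  offs <- seq(-window_bp, window_bp - bin_bp, by = bin_bp)
  n_bins <- length(offs)
  counts <- numeric(n_bins)
  if (nrow(r) > 0) {
    pos <- if (anchor == "five_prime") {
      ifelse(r$strand == "-", r$end - 1L, r$start)
    } else {
      (r$start + r$end) %/% 2L
    }
    win <- GenomicRanges::GRanges(
      dyads$chrom, IRanges::IRanges(dyads$start - window_bp + 1L,
                                    dyads$start + window_bp))
    hits <- GenomicRanges::findOverlaps(.pos_granges(r$chrom, pos), win)
    if (length(hits) > 0) {
      rel <- pos[S4Vectors::queryHits(hits)] -
        dyads$start[S4Vectors::subjectHits(hits)]
      bin <- (rel + window_bp) %/% bin_bp + 1L
      counts <- tabulate(bin, nbins = n_bins)
    }
  }
  mean_count <- counts / nrow(dyads)
  rpkm <- mean_count / (bin_bp / 1000) / (total / 1e6)
  out <- data.frame(offset = offs, mean = rpkm)
  attr(out, "n_anchors") <- nrow(dyads)
  class(out) <- c("phasing_profile", "data.frame")
  out
}

#' Sample autocorrelation of a profile
#'
#' Mean-centered autocorrelation normalized so lag 0 equals 1 (biased
#' estimator: autocovariances divided by the series length, the default of
#' R's `acf`).
#'
#' @param v Numeric vector (e.g. a dyad-anchored profile), longer than
#'   `max_lag`; must not be constant.
#' @param max_lag Largest lag (in bins) to compute.
#' @param detrend_bins Optional centered moving-average window (in bins,
#'   odd) subtracted from the profile before the autocorrelation; 0 (the
#'   default) computes the plain acf. Detrending isolates short-period
#'   structure when the profile carries a broad enrichment envelope (e.g.
#'   dyad-anchored averages over elements that are globally enriched
#'   relative to their flanks).
#' @return Numeric vector of autocorrelations at lags `0..max_lag`, with
#'   attribute `n` = the length of the (possibly trimmed) series.
#' @export
autocorrelate <- function(v, max_lag, detrend_bins = 0) {
  if (detrend_bins > 0) {
    if (detrend_bins %% 2 == 0) detrend_bins <- detrend_bins + 1
    sm <- stats::filter(v, rep(1 / detrend_bins, detrend_bins), sides = 2)
    v <- as.numeric(v - sm)
    v <- v[!is.na(v)]
  }
  if (max_lag < 1 || length(v) <= max_lag) {
    .stopf("need length(v) > max_lag >= 1")
  }
  if (var(v) == 0) .stopf("zero variance: profile is constant")
  a <- acf(v, lag.max = max_lag, plot = FALSE, demean = TRUE)
  out <- as.numeric(a$acf)
  attr(out, "n") <- length(v)
  out
}

#' Estimate the nucleosome repeat length from an autocorrelation
#'
#' Returns the lag of the first local maximum of the autocorrelation within
#' the search range, converted to bp. A maximum that does not exceed the
#' white-noise band (`1.96 / sqrt(n)`, `n` = profile length) leaves the
#' estimate undefined.
#'
#' @param acf_values Output of [autocorrelate()] (lags `0..L`).
#' @param bin_bp Width in bp of one profile bin (one lag unit).
#' @param search_range_bp Two-element range (bp) in which to look for the
#'   repeat (default `c(100, 300)`).
#' @param noise_band Significance band; defaults to `1.96/sqrt(n)` using
#'   the `n` attribute of `acf_values`.
#' @return A list: `nrl_bp` (the estimate, or `NA`), `lag_bins`,
#'   `acf_at_peak`, `reason` (when undefined).
#' @export
estimate_nrl <- function(acf_values, bin_bp, search_range_bp = c(100, 300),
                         noise_band = NULL) {
  lags <- seq_along(acf_values) - 1L
  lo <- ceiling(search_range_bp[1] / bin_bp)
  hi <- floor(search_range_bp[2] / bin_bp)
  if (hi + 1 > max(lags)) {
    .stopf("autocorrelation covers lags up to %d bp; search range needs %d",
           max(lags) * bin_bp, (hi + 1) * bin_bp)
  }
  if (is.null(noise_band)) {
    n <- attr(acf_values, "n")
    noise_band <- if (is.null(n)) 0 else 1.96 / sqrt(n)
  }
  a <- as.numeric(acf_values)
  cand <- lo:hi
  is_max <- vapply(cand, function(k) {
    a[k + 1] > a[k] && a[k + 1] >= a[k + 2]
  }, logical(1))
  peaks <- cand[is_max & a[cand + 1] > noise_band]
  if (length(peaks) == 0) {
    return(list(nrl_bp = NA_real_, lag_bins = NA_integer_,
                acf_at_peak = NA_real_,
                reason = "no local maximum above the noise band"))
  }
  k <- peaks[1]
  list(nrl_bp = k * bin_bp, lag_bins = k, acf_at_peak = a[k + 1],
       reason = NULL)
}
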