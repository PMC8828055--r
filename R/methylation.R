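# Methylation core: cytosine context assignment, weighted methylation
# levels, and methylated-site densities per annotation and genomic window.
#
# Context vocabulary (H = A/T/C, W = A/T), read in strand orientation from
# the cytosine and its two downstream bases:
#   CG   : C followed by G
#   CHG  : C-H-G; subcontexts CCG (H = C) and CWG (H = A/T)
#   CHH  : C-H-H; subcontexts CWA (C-W-A) and nonCWA (the rest)

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# Vectorized rule on the two downstream bases (already in strand
# orientation). Returns list(context, subcontext); "undetermined" where a
# base is N or missing (off chromosome end).
.context_from_downstream <- function(b1, b2) {
  h <- c("A", "C", "T")
  w <- c("A", "T")
  context <- rep("undetermined", length(b1))
  subcontext <- rep("undetermined", length(b1))
  cg <- !is.na(b1) & b1 == "G"
  context[cg] <- "CG"
  subcontext[cg] <- "CG"
  ok2 <- !is.na(b1) & !is.na(b2)
  chg <- ok2 & b1 %in% h & b2 == "G"
  context[chg] <- "CHG"
  subcontext[chg & b1 == "C"] <- "CCG"
  subcontext[chg & b1 %in% w] <- "CWG"
  chh <- ok2 & b1 %in% h & b2 %in% h
  context[chh] <- "CHH"
  cwa <- chh & b1 %in% w & b2 == "A"
  subcontext[cwa] <- "CWA"
  subcontext[chh & !cwa] <- "nonCWA"
  list(context = context, subcontext = subcontext)
}

#' Assign cytosine sequence context
#'
#' Determines the CG/CHG/CHH context (and CCG/CWG/CWA/nonCWA subcontext)
#' of cytosines from the genome sequence, reading the two downstream bases
#' in strand orientation. Positions whose downstream bases run off the
#' chromosome end or contain N get context `"undetermined"` and are
#' excluded from all summaries.
#'
#' @param genome Named character vector of chromosome sequences (uppercase).
#' @param chrom,pos,strand Vectors locating the cytosines (0-based `pos`).
#'   The base at `pos` must be `C` on `+` (or `G` on the forward strand for
#'   a `-` strand cytosine).
#' @return A `data.frame` with columns `context` and `subcontext`.
#' @export
assign_context <- function(genome, chrom, pos, strand) {
  n <- length(pos)
  stopifnot(length(chrom) == n, length(strand) == n)
  b0 <- b1 <- b2 <- rep(NA_character_, n)
  for (ch in unique(chrom)) {
    if (!ch %in% names(genome)) .stopf("chromosome '%s' not in genome", ch)
    s <- genome[[ch]]
    len <- nchar(s)
    i <- which(chrom == ch)
    p <- pos[i]
    if (any(p < 0 | p >= len)) .stopf("position outside chromosome '%s'", ch)
    plus <- strand[i] == "+"
    # forward-strand characters at pos, pos+1, pos+2 (plus) or
    # pos, pos-1, pos-2 complemented (minus)
    ip <- i[plus]; im <- i[!plus]
    if (length(ip) > 0) {
      pp <- p[plus]
      b0[ip] <- substring(s, pp + 1, pp + 1)
      b1[ip] <- ifelse(pp + 1 < len, substring(s, pp + 2, pp + 2), NA)
      b2[ip] <- ifelse(pp + 2 < len, substring(s, pp + 3, pp + 3), NA)
    }
    if (length(im) > 0) {
      pm <- p[!plus]
      cmp <- function(x) unname(.COMPLEMENT[x])
      b0[im] <- cmp(substring(s, pm + 1, pm + 1))
      b1[im] <- ifelse(pm - 1 >= 0, cmp(substring(s, pm, pm)), NA)
      b2[im] <- ifelse(pm - 2 >= 0, cmp(substring(s, pm - 1, pm - 1)), NA)
    }
  }
  if (any(b0 != "C", na.rm = TRUE)) {
    .stopf("base at position %d is not a cytosine on the requested strand",
           pos[which(b0 != "C")[1]])
  }
  b1[!is.na(b1) & b1 == "N"] <- NA
  b2[!is.na(b2) & b2 == "N"] <- NA
  res <- .context_from_downstream(b1, b2)
  data.frame(context = res$context, subcontext = res$subcontext,
             stringsAsFactors = FALSE)
}

#' Enumerate all cytosines of a genome with their contexts
#'
#' Both strands are scanned (a forward-strand `G` is a minus-strand
#' cytosine). Symmetric CG positions are not pooled: each strand's cytosine
#' is its own site.
#'
#' @param genome Named character vector of chromosome sequences.
#' @return A `data.frame` with `chrom`, `pos` (0-based), `strand`,
#'   `context`, `subcontext`; positions with undetermined context are
#'   retained and flagged as such.
#' @export
cytosine_sites <- function(genome) {
  out <- vector("list", length(genome))
  for (k in seq_along(genome)) {
    ch <- names(genome)[k]
    v <- strsplit(genome[[k]], "", fixed = TRUE)[[1]]
    n <- length(v)
    # plus strand: C positions, downstream = next two forward bases
    pp <- which(v == "C")
    b1p <- ifelse(pp < n, v[pmin(pp + 1, n)], NA)
    b2p <- ifelse(pp + 1 < n, v[pmin(pp + 2, n)], NA)
    # minus strand: G positions, downstream = previous two bases complemented
    pm <- which(v == "G")
    b1m <- ifelse(pm > 1, unname(.COMPLEMENT[v[pmax(pm - 1, 1)]]), NA)
    b2m <- ifelse(pm > 2, unname(.COMPLEMENT[v[pmax(pm - 2, 1)]]), NA)
    b1 <- c(b1p, b1m); b2 <- c(b2p, b2m)
    b1[!is.na(b1) & b1 == "N"] <- NA
    b2[!is.na(b2) & b2 == "N"] <- NA
    ctx <- .context_from_downstream(b1, b2)
    out[[k]] <- data.frame(
      chrom = ch,
      pos = c(pp, pm) - 1L,
      strand = rep(c("+", "-"), c(length(pp), length(pm))),
      context = ctx$context, subcontext = ctx$subcontext,
      stringsAsFactors = FALSE
    )
  }
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

# One-sided binomial p-value for a methylated-site call against the
# bisulfite non-conversion error rate: P(X >= k | n, error_rate).
.site_call_p <- function(meth, cov, error_rate) {
  pbinom(meth - 1, cov, error_rate, lower.tail = FALSE)
}

#' Summarize methylation over features
#'
#' Computes, per feature and context (CG, CHG, CHH, and pooled CH =
#' CHG + CHH): the weighted methylation level (sum of methylated read
#' counts over sum of total read counts, across sites with coverage >=
#' `min_cov`), site counts, covered-site counts, methylated-site counts,
#' and the methylated-site density (methylated sites per bp of the
#' feature). A site is called methylated when its coverage is at least
#' `min_cov` and a one-sided binomial test of the methylated count against
#' the non-conversion `error_rate` gives p < `alpha`. Contexts with no
#' covered site have level `NA` (undefined, distinct from 0).
#'
#' @param records A [cytosine_records()] data.frame.
#' @param features A [feature_intervals()] data.frame.
#' @param min_cov Minimum coverage for a site to enter the weighted level
#'   (default 3).
#' @param error_rate Assumed bisulfite non-conversion rate (default 0.005).
#' @param alpha Site-call significance threshold (default 0.01).
#' @return A `data.frame`, one row per feature, with columns `id`,
#'   `length`, and for each context `c` in CG/CHG/CHH/CH: `m_c`
#'   (weighted level), `sites_c`, `covered_c`, `meth_sites_c`, `d_c`
#'   (density per bp), and the pooled read counts over covered sites
#'   `reads_meth_c` / `reads_unmeth_c` (the cells of between-genotype
#'   Fisher tables).
#' @export
summarize_methylation <- function(records, features, min_cov = 3,
                                  error_rate = 0.005, alpha = 0.01) {
  contexts <- c("CG", "CHG", "CHH", "CH")
  base <- data.table::data.table(id = features$id,
                                 length = features$end - features$start)
  empty_cols <- function(dt) {
    for (ctx in contexts) {
      dt[, paste0("m_", ctx) := NA_real_]
      dt[, paste0("sites_", ctx) := 0L]
      dt[, paste0("covered_", ctx) := 0L]
      dt[, paste0("meth_sites_", ctx) := 0L]
      dt[, paste0("d_", ctx) := 0]
      dt[, paste0("reads_meth_", ctx) := 0L]
      dt[, paste0("reads_unmeth_", ctx) := 0L]
    }
    dt
  }
  if (nrow(records) == 0 || nrow(features) == 0) {
    return(as.data.frame(empty_cols(base)))
  }
  hits <- GenomicRanges::findOverlaps(
    .pos_granges(records$chrom, records$pos), .as_granges(features))
  if (length(hits) == 0) return(as.data.frame(empty_cols(base)))
  dt <- data.table::data.table(
    fi = S4Vectors::subjectHits(hits),
    context = records$context[S4Vectors::queryHits(hits)],
    meth = records$count_meth[S4Vectors::queryHits(hits)],
    unmeth = records$count_unmeth[S4Vectors::queryHits(hits)]
  )
  dt <- dt[context %in% c("CG", "CHG", "CHH")]
  # pooled non-CG context rows
  dt <- rbind(dt, dt[context %in% c("CHG", "CHH")][, context := "CH"])
  dt[, cov := meth + unmeth]
  dt[, covered := cov >= min_cov]
  dt[, called := covered & .site_call_p(meth, cov, error_rate) < alpha]
  agg <- dt[, .(
    sites = .N,
    covered = sum(covered),
    sum_meth = sum(meth[covered]),
    sum_total = sum(cov[covered]),
    meth_sites = sum(called)
  ), by = .(fi, context)]
  agg[, m := ifelse(sum_total > 0, sum_meth / sum_total, NA_real_)]
  res <- empty_cols(base)
  for (ctx in contexts) {
    a <- agg[context == ctx]
    if (nrow(a) == 0) next
    data.table::set(res, i = a$fi, j = paste0("m_", ctx), value = a$m)
    data.table::set(res, i = a$fi, j = paste0("sites_", ctx),
                    value = as.integer(a$sites))
    data.table::set(res, i = a$fi, j = paste0("covered_", ctx),
                    value = as.integer(a$covered))
    data.table::set(res, i = a$fi, j = paste0("meth_sites_", ctx),
                    value = as.integer(a$meth_sites))
    data.table::set(res, i = a$fi, j = paste0("d_", ctx),
                    value = a$meth_sites / res$length[a$fi])
    data.table::set(res, i = a$fi, j = paste0("reads_meth_", ctx),
                    value = as.integer(a$sum_meth))
    data.table::set(res, i = a$fi, j = paste0("reads_unmeth_", ctx),
                    value = as.integer(a$sum_total - a$sum_meth))
  }
  as.data.frame(res)
}

#' Weighted methylation level in sliding genomic windows
#'
#' @param records A [cytosine_records()] data.frame.
#' @param window_bp Window width in bp.
#' @param step_bp Step between window starts (<= `window_bp`).
#' @param min_cov Minimum site coverage (default 1).
#' @return A `data.frame` (`chrom`, `start`, `end`, `context`, `level`);
#'   windows with no covered site are omitted.
#' @export
genome_window_methylation <- function(records, window_bp, step_bp = window_bp,
                                      min_cov = 1) {
  if (window_bp < step_bp || step_bp < 1) {
    .stopf("need window_bp >= step_bp >= 1")
  }
  if (nrow(records) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      level = numeric()))
  }
  dt <- data.table::as.data.table(records)
  dt <- dt[context %in% c("CG", "CHG", "CHH")]
  dt[, cov := count_meth + count_unmeth]
  dt <- dt[cov >= min_cov]
  out <- list()
  for (ch in unique(dt$chrom)) {
    d <- dt[chrom == ch]
    max_pos <- max(d$pos)
    starts <- seq(0L, max_pos, by = step_bp)
    win <- GenomicRanges::GRanges(ch, IRanges::IRanges(starts + 1L,
                                                       width = window_bp))
    hits <- GenomicRanges::findOverlaps(.pos_granges(d$chrom, d$pos), win)
    if (length(hits) == 0) next
    h <- data.table::data.table(
      wi = S4Vectors::subjectHits(hits),
      context = d$context[S4Vectors::queryHits(hits)],
      meth = d$count_meth[S4Vectors::queryHits(hits)],
      cov = d$cov[S4Vectors::queryHits(hits)]
    )
    agg <- h[, .(level = sum(meth) / sum(cov)), by = .(wi, context)]
    out[[ch]] <- data.frame(chrom = ch, start = starts[agg$wi],
                            end = starts[agg$wi] + window_bp,
                            context = agg$context, level = agg$level,
                            stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      level = numeric()))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$context, res$start), ]
}
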