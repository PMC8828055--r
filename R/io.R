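# I/O module: readers and writers for the standard formats the pipeline
# touches. All internal coordinates are 0-based half-open; conversion to and
# from 1-based formats (GFF3, cytosine reports) happens here only.

#' Construct a set of feature intervals
#'
#' The central annotation container: one row per genomic feature (TE, gene,
#' sRNA cluster, nucleosome dyad) with 0-based half-open coordinates.
#'
#' @param chrom Chromosome names.
#' @param start 0-based inclusive start positions.
#' @param end 0-based exclusive end positions.
#' @param strand Strand, one of `"+"`, `"-"`, `"."`.
#' @param id Unique feature identifiers.
#' @param feature_class Optional class label (e.g. TE family or assigned
#'   pathway class); `NA` if absent.
#' @return A `data.frame` of class `feature_intervals` with columns
#'   `chrom`, `start`, `end`, `strand`, `id`, `feature_class`.
#' @export
feature_intervals <- function(chrom, start, end, strand = ".", id,
                              feature_class = NA_character_) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = rep_len(as.character(strand), n),
    id = as.character(id),
    feature_class = rep_len(as.character(feature_class), n),
    stringsAsFactors = FALSE
  )
  if (any(df$start >= df$end)) {
    .stopf("feature interval(s) with start >= end: %s",
           paste(utils::head(df$id[df$start >= df$end], 5), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-", "."))) {
    .stopf("strand must be one of '+', '-', '.'")
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup) > 0) {
    .stopf("duplicate feature id(s): %s",
           paste(unique(utils::head(dup, 5)), collapse = ", "))
  }
  class(df) <- c("feature_intervals", "data.frame")
  df
}

#' Read feature annotations from BED6 or GFF3
#'
#' BED coordinates pass through unchanged (they are already 0-based
#' half-open); GFF3 1-based inclusive coordinates are converted. GFF3
#' parsing is delegated to [rtracklayer::import()]; feature ids are taken
#' from the `ID` attribute (falling back to `Name`, then to
#' `<type>_<row>`), and `feature_class` from the `type` column.
#'
#' @param path Path to a `.bed`, `.gff`, or `.gff3` file. Format is chosen
#'   by extension; anything not ending in gff/gff3 is parsed as BED.
#' @return A [feature_intervals()] data.frame.
#' @export
read_features <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    gr <- rtracklayer::import(path, format = "gff3")
    if (length(gr) == 0) {
      return(feature_intervals(character(), integer(), integer(),
                               character(), character()))
    }
    mc <- S4Vectors::mcols(gr)
    id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
    if ("Name" %in% names(mc)) {
      nm <- as.character(mc$Name)
      id <- ifelse(is.na(id) | id == "", nm, id)
    }
    fallback <- paste0(as.character(mc$type), "_", seq_along(gr))
    id <- ifelse(is.na(id) | id == "", fallback, id)
    return(feature_intervals(
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
      id = id,
      feature_class = as.character(mc$type)
    ))
  }
  .read_bed6(path)
}

# Validating BED6 reader: the error contract (line-numbered parse errors,
# duplicate-id detection) is part of the module surface.
.read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines)]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(feature_intervals(character(), integer(), integer(),
                             character(), character()))
  }
  fields <- strsplit(lines, "[ \t]+")
  n <- lengths(fields)
  bad <- which(n < 6)
  if (length(bad) > 0) {
    .stopf("malformed BED6 line %d: expected >= 6 fields, got %d",
           bad[1], n[bad[1]])
  }
  chrom <- vapply(fields, `[[`, "", 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  id <- vapply(fields, `[[`, "", 4)
  strand <- vapply(fields, `[[`, "", 6)
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    .stopf("malformed BED6 line %d: non-numeric coordinates", bad[1])
  }
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad) > 0) {
    .stopf("malformed BED6 line %d: invalid strand '%s'",
           bad[1], strand[bad[1]])
  }
  feature_intervals(chrom, start, end, strand, id)
}

#' Write feature intervals as BED6
#'
#' @param features A [feature_intervals()] data.frame.
#' @param path Output path.
#' @export
write_features <- function(features, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", features$chrom,
                     features$start, features$end, features$id,
                     features$strand), path)
  invisible(path)
}

#' Read a per-cytosine methylation report
#'
#' Expects a 7-column TSV: chrom, pos (1-based), strand, methylated read
#' count, unmethylated read count, context, trinucleotide context (in
#' strand orientation). The context is recomputed from the trinucleotide
#' and checked against the stated context; disagreement is a validation
#' error.
#'
#' @param path Path to the TSV (no header).
#' @return A `data.frame` of class `cytosine_records` with columns `chrom`,
#'   `pos` (0-based), `strand`, `context`, `subcontext`, `count_meth`,
#'   `count_unmeth`.
#' @export
read_cytosine_report <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "pos", "strand",
                                        "count_meth", "count_unmeth",
                                        "context", "tricontext"),
                          colClasses = c("character", "integer", "character",
                                         "integer", "integer", "character",
                                         "character"))
  if (any(df$count_meth < 0 | df$count_unmeth < 0)) {
    .stopf("negative read count at row(s): %s",
           paste(utils::head(which(df$count_meth < 0 | df$count_unmeth < 0), 10),
                 collapse = ", "))
  }
  b1 <- substr(df$tricontext, 2, 2)
  b2 <- substr(df$tricontext, 3, 3)
  ctx <- .context_from_downstream(b1, b2)
  bad <- which(ctx$context != df$context)
  if (length(bad) > 0) {
    .stopf("context/tricontext mismatch at row(s): %s",
           paste(utils::head(bad, 10), collapse = ", "))
  }
  cytosine_records(df$chrom, df$pos - 1L, df$strand, df$count_meth,
                   df$count_unmeth, context = ctx$context,
                   subcontext = ctx$subcontext)
}

#' Construct a set of per-cytosine records
#'
#' @param chrom,pos,strand Position of the cytosine (0-based, strand of the
#'   cytosine itself).
#' @param count_meth,count_unmeth Read counts supporting methylated /
#'   unmethylated state.
#' @param context `CG`, `CHG`, `CHH` (or `undetermined`).
#' @param subcontext `CG`, `CCG`, `CWG`, `CWA`, `nonCWA` (or
#'   `undetermined`).
#' @return A `data.frame` of class `cytosine_records`.
#' @export
cytosine_records <- function(chrom, pos, strand, count_meth, count_unmeth,
                             context, subcontext) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand),
                   context = as.character(context),
                   subcontext = as.character(subcontext),
                   count_meth = as.integer(count_meth),
                   count_unmeth = as.integer(count_unmeth),
                   stringsAsFactors = FALSE)
  if (any(df$count_meth < 0 | df$count_unmeth < 0)) {
    .stopf("read counts must be non-negative")
  }
  class(df) <- c("cytosine_records", "data.frame")
  df
}

#' Write a binned track as bedGraph
#'
#' Values are written with 6 significant digits; [read_bedgraph()]
#' round-trips the file exactly at that precision.
#'
#' @param track An [enrichment_track()] (or data.frame with `chrom`,
#'   `start`, `end`, `value`).
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  .check_cols(track, c("chrom", "start", "end", "value"), "track")
  if (nrow(track) > 0) {
    o <- order(track$chrom, track$start)
    if (!identical(o, seq_len(nrow(track)))) {
      .stopf("bedGraph bins must be sorted by chrom, start")
    }
    by_chrom <- split(track, track$chrom)
    for (tc in by_chrom) {
      if (nrow(tc) > 1 && any(tc$start[-1] < tc$end[-nrow(tc)])) {
        .stopf("bedGraph bins must be non-overlapping")
      }
    }
  }
  writeLines(sprintf("%s\t%d\t%d\t%s", track$chrom, track$start, track$end,
                     sprintf("%.6g", track$value)), path)
  invisible(path)
}

#' Read a 4-column bedGraph
#'
#' @param path Path to the bedGraph file.
#' @param value_kind Tag for the values (`"raw"`, `"rpkm"`, `"log2ratio"`).
#' @return An [enrichment_track()].
#' @export
read_bedgraph <- function(path, value_kind = "raw") {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(enrichment_track(character(), integer(), integer(), numeric(),
                            value_kind))
  }
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "integer", "integer",
                                         "numeric"))
  enrichment_track(df$chrom, df$start, df$end, df$value, value_kind)
}

#' Read size-selected small RNA reads from BED
#'
#' Read length is taken as `end - start`. The returned object carries the
#' total count of 18-28 nt reads (the rpkm normalizer) as attribute
#' `total_18_28`.
#'
#' @param path BED file of aligned read intervals (>= 3 columns; strand
#'   taken from column 6 when present).
#' @return A `data.frame` of class `sized_reads` with columns `chrom`,
#'   `start`, `end`, `strand`, `length`.
#' @export
read_sized_reads <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) {
    return(sized_reads(character(), integer(), integer(), character()))
  }
  fields <- strsplit(lines, "[ \t]+")
  chrom <- vapply(fields, `[[`, "", 1)
  start <- as.integer(vapply(fields, `[[`, "", 2))
  end <- as.integer(vapply(fields, `[[`, "", 3))
  strand <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else ".", "")
  sized_reads(chrom, start, end, strand)
}

#' Construct a size-selected read set
#'
#' @param chrom,start,end,strand Aligned read intervals (0-based half-open).
#' @return `sized_reads` data.frame with a `length` column and attribute
#'   `total_18_28` (count of reads of length 18-28 nt).
#' @export
sized_reads <- function(chrom, start, end, strand = ".") {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end),
                   strand = rep_len(as.character(strand), length(chrom)),
                   stringsAsFactors = FALSE)
  df$length <- df$end - df$start
  if (any(df$length <= 0)) {
    .stopf("zero- or negative-length read interval(s) at row(s): %s",
           paste(utils::head(which(df$length <= 0), 10), collapse = ", "))
  }
  attr(df, "total_18_28") <- sum(df$length >= 18 & df$length <= 28)
  class(df) <- c("sized_reads", "data.frame")
  df
}

#' Write a read set as BED6
#' @param reads A [sized_reads()] data.frame.
#' @param path Output path.
#' @export
write_sized_reads <- function(reads, path) {
  writeLines(sprintf("%s\t%d\t%d\tread_%d\t0\t%s", reads$chrom, reads$start,
                     reads$end, seq_len(nrow(reads)), reads$strand), path)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(out))
  out
}

#' Write a genome FASTA
#' @param genome Named character vector of chromosome sequences.
#' @param path Output path.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
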