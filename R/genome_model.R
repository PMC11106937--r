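#' Construct a genome layout
#'
#' A genome layout is the coordinate system every stage of the pipeline
#' validates against: an ordered table of chromosome names and lengths.
#' All coordinates in the package are 1-based and inclusive at both ends
#' (the GTF/GFF convention); BED exports convert on write.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer-ish vector of positive chromosome lengths (bp).
#' @return A `data.frame` with columns `chrom`, `length`, of class
#'   `genome_layout`.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e7, 5e6))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != base::length(length)) {
    stop("chrom and length must have equal length")
  }
  if (anyDuplicated(chrom)) {
    stop("duplicate chromosome names: ",
         paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  }
  if (any(is.na(length)) || any(length < 1) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  out <- data.frame(chrom = chrom, length = length,
                    stringsAsFactors = FALSE)
  class(out) <- c("genome_layout", "data.frame")
  out
}

#' Read a genome layout from a TSV or FASTA index
#'
#' Accepts either a two-column headerless/headered TSV (`chrom`, `length`)
#' or a samtools `.fai` index, from which the first two columns are used.
#'
#' @param path Path to the layout file.
#' @return A `genome_layout`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome layout file not found: ", path)
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  # a header line, if present, is detected by a non-numeric second field
  if (nrow(tab) > 0 && is.na(suppressWarnings(as.numeric(tab[[2]][1])))) {
    tab <- tab[-1, , drop = FALSE]
  }
  if (ncol(tab) < 2 || nrow(tab) == 0) {
    stop("genome layout needs at least two columns (chrom, length): ", path)
  }
  genome_layout(tab[[1]], as.numeric(tab[[2]]))
}

#' Write a genome layout as a two-column TSV
#'
#' @param layout A `genome_layout`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(layout, path) {
  utils::write.table(as.data.frame(layout)[, c("chrom", "length")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

chrom_length <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) {
    stop("chromosome(s) not in layout: ",
         paste(unique(chrom[is.na(i)]), collapse = ", "))
  }
  layout$length[i]
}

#' Test whether two genomic intervals overlap
#'
#' Closed-interval overlap: intervals on the same chromosome sharing at
#' least one base. Adjacency (end + 1 == start) does not count. Vectorised
#' over its arguments.
#'
#' @param chrom_a,start_a,end_a First interval(s).
#' @param chrom_b,start_b,end_b Second interval(s).
#' @return Logical vector.
#' @examples
#' intervals_overlap("chr1", 100, 200, "chr1", 200, 300)  # TRUE, 1 bp
#' intervals_overlap("chr1", 100, 200, "chr1", 201, 300)  # FALSE
#' @export
intervals_overlap <- function(chrom_a, start_a, end_a,
                              chrom_b, start_b, end_b) {
  chrom_a == chrom_b &
    pmax(start_a, start_b) <= pmin(end_a, end_b)
}

overlap_width <- function(start_a, end_a, start_b, end_b) {
  pmin(end_a, end_b) - pmax(start_a, start_b) + 1
}

#' Flanking span of a set of intervals on one chromosome
#'
#' The span is the interval from the smallest start to the largest end —
#' the "flanking region" used to define the extent of a confirmed
#' selective sweep from its member intervals.
#'
#' @param chrom Chromosome of each interval (must all be equal).
#' @param start,end Interval coordinates.
#' @return A one-row `data.frame` with `chrom`, `start`, `end`.
#' @export
interval_span <- function(chrom, start, end) {
  if (length(chrom) == 0) stop("cannot span an empty interval set")
  if (length(unique(chrom)) != 1) {
    stop("malformed cluster: intervals span multiple chromosomes (",
         paste(unique(chrom), collapse = ", "), ")")
  }
  data.frame(chrom = chrom[1], start = min(start), end = max(end),
             stringsAsFactors = FALSE)
}

#' Clamp intervals to chromosome bounds
#'
#' Floors starts at 1 and caps ends at the chromosome length. Idempotent.
#'
#' @param intervals A `data.frame` with `chrom`, `start`, `end`.
#' @param layout A `genome_layout`; every `chrom` must be present.
#' @return The intervals with coordinates clamped.
#' @export
clamp_intervals <- function(intervals, layout) {
  len <- chrom_length(layout, intervals$chrom)
  intervals$start <- pmax(1, intervals$start)
  intervals$end <- pmin(len, intervals$end)
  intervals
}

# validate a chrom/start/end frame against a layout; returns character()
# when clean, otherwise messages indexed by `where` labels
validate_intervals <- function(intervals, layout, where = NULL) {
  msgs <- character(0)
  lab <- if (is.null(where)) seq_len(nrow(intervals)) else where
  bad_chrom <- !(intervals$chrom %in% layout$chrom)
  if (any(bad_chrom)) {
    msgs <- c(msgs, paste0("row ", lab[bad_chrom], ": chromosome '",
                           intervals$chrom[bad_chrom], "' not in layout"))
  }
  ok <- !bad_chrom
  bad_order <- ok & (intervals$start > intervals$end)
  if (any(bad_order)) {
    msgs <- c(msgs, paste0("row ", lab[bad_order], ": start (",
                           intervals$start[bad_order], ") > end (",
                           intervals$end[bad_order], ")"))
  }
  if (any(ok)) {
    len <- rep(NA_real_, nrow(intervals))
    len[ok] <- chrom_length(layout, intervals$chrom[ok])
    oob <- ok & (intervals$start < 1 | intervals$end > len)
    if (any(oob)) {
      msgs <- c(msgs, paste0("row ", lab[oob],
                             ": interval outside chromosome bounds"))
    }
  }
  msgs
}

# GRanges view of a chrom/start/end data.frame (internal; 1-based inclusive
# on both sides, matching GRanges semantics directly)
as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start, end = df$end)
  )
}
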