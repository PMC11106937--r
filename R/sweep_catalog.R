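#' Expand a single-marker sweep report to a flanked window
#'
#' Studies that report a sweep as one marker coordinate are converted to an
#' interval extending `flank` bp downstream and upstream of the marker
#' (default 250 kb each side), clamped to the chromosome.
#'
#' @param marker_pos Marker coordinate(s), bp.
#' @param chrom Chromosome name(s).
#' @param flank Flank size in bp on each side (default 250000).
#' @param layout A `genome_layout`.
#' @return `data.frame` with `chrom`, `start`, `end`; always contains the
#'   marker position, width at most `2 * flank + 1`.
#' @examples
#' lay <- genome_layout("chr1", 1e7)
#' expand_marker(1e6, "chr1", layout = lay)  # 750000..1250000
#' @export
expand_marker <- function(marker_pos, chrom, flank = 250000, layout) {
  len <- chrom_length(layout, chrom)
  if (any(marker_pos < 1 | marker_pos > len)) {
    bad <- which(marker_pos < 1 | marker_pos > len)
    stop("marker position outside chromosome: ",
         paste0(chrom[pmin(bad, length(chrom))], ":", marker_pos[bad],
                collapse = ", "))
  }
  clamp_intervals(
    data.frame(chrom = chrom, start = marker_pos - flank,
               end = marker_pos + flank, stringsAsFactors = FALSE),
    layout
  )
}

STUDY_CLASSES <- c("production", "adaptation")

#' Read and normalise a per-study sweep table
#'
#' The table is a TSV with header columns `study_id`, `study_class`,
#' `chrom` and either `start`/`end` (interval reports) or `marker_pos`
#' (single-marker reports; expanded by `flank` each side). A row may fill
#' either coordinate style; rows with both are treated as intervals.
#' Duplicate identical intervals within one study are collapsed to one
#' record (study support downstream is counted over distinct studies, so
#' duplicates cannot change results).
#'
#' @param path Path to the sweep TSV.
#' @param layout A `genome_layout`; all records are validated against it.
#' @param flank Marker expansion flank, bp (default 250000).
#' @param lenient If `TRUE`, rows on chromosomes absent from the layout are
#'   skipped with a warning instead of erroring.
#' @return A sweep catalog: `list(studies = <data.frame>, sweeps =
#'   <data.frame>)` of class `sweep_catalog`. `studies` has `study_id`,
#'   `study_class`; `sweeps` has `sweep_id`, `study_id`, `study_class`,
#'   `chrom`, `start`, `end`, `source_kind`.
#' @export
read_sweep_table <- function(path, layout, flank = 250000, lenient = FALSE) {
  if (!file.exists(path)) stop("sweep table not found: ", path)
  tab <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("study_id", "study_class", "chrom")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("sweep table missing column(s): ", paste(miss, collapse = ", "))
  }
  has_iv <- all(c("start", "end") %in% names(tab))
  has_mk <- "marker_pos" %in% names(tab)
  if (!has_iv && !has_mk) {
    stop("sweep table needs either start/end or marker_pos columns")
  }
  line <- seq_len(nrow(tab)) + 1L  # +1 for the header line

  bad_class <- !(tab$study_class %in% STUDY_CLASSES)
  if (any(bad_class)) {
    stop("line ", line[bad_class][1], ": unknown study_class '",
         tab$study_class[bad_class][1], "' (expected ",
         paste(STUDY_CLASSES, collapse = " or "), ")")
  }

  if (lenient) {
    off <- !(tab$chrom %in% layout$chrom)
    if (any(off)) {
      warning(sum(off), " row(s) on chromosomes absent from layout skipped")
      tab <- tab[!off, , drop = FALSE]
      line <- line[!off]
    }
  }

  is_marker <- if (has_mk) {
    !is.na(tab$marker_pos) & (!has_iv | is.na(tab$start) | is.na(tab$end))
  } else rep(FALSE, nrow(tab))

  sweeps <- data.frame(
    study_id = as.character(tab$study_id),
    study_class = tab$study_class,
    chrom = as.character(tab$chrom),
    start = NA_real_, end = NA_real_,
    source_kind = ifelse(is_marker, "marker", "interval"),
    stringsAsFactors = FALSE
  )
  if (any(!is_marker)) {
    if (!has_iv) stop("rows without marker_pos need start/end columns")
    sweeps$start[!is_marker] <- as.numeric(tab$start[!is_marker])
    sweeps$end[!is_marker] <- as.numeric(tab$end[!is_marker])
    rev_iv <- !is_marker & !is.na(sweeps$start) & !is.na(sweeps$end) &
      sweeps$start > sweeps$end
    if (any(rev_iv)) {
      stop("line ", line[rev_iv][1], ": start (", sweeps$start[rev_iv][1],
           ") > end (", sweeps$end[rev_iv][1], ")")
    }
  }
  if (any(is_marker)) {
    exp <- expand_marker(as.numeric(tab$marker_pos[is_marker]),
                         sweeps$chrom[is_marker], flank = flank,
                         layout = layout)
    sweeps$start[is_marker] <- exp$start
    sweeps$end[is_marker] <- exp$end
  }
  if (anyNA(sweeps$start) || anyNA(sweeps$end)) {
    bad <- which(is.na(sweeps$start) | is.na(sweeps$end))
    stop("line ", line[bad][1], ": no usable coordinates")
  }

  msgs <- validate_intervals(sweeps, layout, where = paste0("line ", line))
  if (length(msgs)) stop("invalid sweep record(s):\n  ",
                         paste(msgs, collapse = "\n  "))

  # deduplicate identical intervals within a study
  key <- paste(sweeps$study_id, sweeps$chrom, sweeps$start, sweeps$end)
  sweeps <- sweeps[!duplicated(key), , drop = FALSE]

  o <- order(match(sweeps$chrom, layout$chrom), sweeps$start, sweeps$end,
             sweeps$study_id)
  sweeps <- sweeps[o, , drop = FALSE]
  sweeps$sweep_id <- sprintf("SW%05d", seq_len(nrow(sweeps)))
  sweeps <- sweeps[, c("sweep_id", "study_id", "study_class", "chrom",
                       "start", "end", "source_kind")]
  rownames(sweeps) <- NULL

  studies <- unique(sweeps[, c("study_id", "study_class")])
  dup <- studies$study_id[duplicated(studies$study_id)]
  if (length(dup)) {
    stop("study id(s) with conflicting class labels: ",
         paste(unique(dup), collapse = ", "))
  }
  studies <- studies[order(studies$study_id), , drop = FALSE]
  rownames(studies) <- NULL

  structure(list(studies = studies, sweeps = sweeps, layout = layout),
            class = "sweep_catalog")
}

#' Write a normalised sweep catalog
#'
#' Emits the catalog as a 1-based inclusive TSV and, optionally, a 0-based
#' half-open BED with `study_id` in the name field.
#'
#' @param catalog A `sweep_catalog`.
#' @param tsv_path Output TSV path.
#' @param bed_path Optional output BED path.
#' @return `tsv_path`, invisibly.
#' @export
write_sweep_catalog <- function(catalog, tsv_path, bed_path = NULL) {
  utils::write.table(catalog$sweeps, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = catalog$sweeps$chrom,
                      start = catalog$sweeps$start - 1,
                      end = catalog$sweeps$end,
                      name = paste0(catalog$sweeps$sweep_id, "|",
                                    catalog$sweeps$study_id, "|",
                                    catalog$sweeps$study_class))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}

#' @export
print.sweep_catalog <- function(x, ...) {
  cat("sweep catalog:", nrow(x$sweeps), "sweeps from",
      nrow(x$studies), "studies (",
      sum(x$studies$study_class == "production"), "production /",
      sum(x$studies$study_class == "adaptation"), "adaptation )\n")
  invisible(x)
}
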