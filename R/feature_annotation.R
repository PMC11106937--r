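#' Read gene models from a GTF file
#'
#' One gene model per distinct `gene_id`. When the file carries explicit
#' `gene` feature rows those are used directly; for gene ids present only
#' through transcripts/exons the gene interval is the span (min start, max
#' end) of all its features.
#'
#' @param path GTF path.
#' @return `data.frame` with `gene_id`, `symbol`, `chrom`, `start`, `end`,
#'   `biotype`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF not found: ", path)
  if (file.size(path) == 0 ||
      !any(!startsWith(readLines(path, warn = FALSE), "#"))) {
    warning("GTF is empty: ", path)
    return(data.frame(gene_id = character(0), symbol = character(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), biotype = character(0),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  meta <- S4Vectors::mcols(gr)
  if (!"gene_id" %in% names(meta)) {
    stop("GTF has no gene_id attribute: ", path)
  }
  df <- data.frame(
    type = as.character(meta$type),
    gene_id = as.character(meta$gene_id),
    symbol = if ("gene_name" %in% names(meta)) {
      as.character(meta$gene_name)
    } else NA_character_,
    biotype = if ("gene_biotype" %in% names(meta)) {
      as.character(meta$gene_biotype)
    } else NA_character_,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  if (anyNA(df$gene_id)) stop("GTF rows without gene_id: ", path)
  parts <- split(df, df$gene_id)
  rows <- lapply(parts, function(p) {
    g <- p[p$type == "gene", , drop = FALSE]
    if (nrow(g) == 0) {
      sp <- interval_span(p$chrom, p$start, p$end)
      g <- p[1, , drop = FALSE]
      g$start <- sp$start; g$end <- sp$end
    } else {
      g <- g[1, , drop = FALSE]
    }
    g
  })
  out <- do.call(rbind, rows)
  out <- out[, c("gene_id", "symbol", "chrom", "start", "end", "biotype")]
  out$symbol[is.na(out$symbol)] <- out$gene_id[is.na(out$symbol)]
  out <- out[order(out$chrom, out$start, out$end, out$gene_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read QTL records from a QTLdb-style GFF3 file
#'
#' Expects one QTL per row with the trait name in the `Name` attribute and
#' the trait class in `trait_type` (vocabulary preserved verbatim, no
#' recoding). Rows lacking a trait name or usable coordinates are skipped
#' with a warning; the number skipped is kept in the `n_skipped`
#' attribute.
#'
#' @param path GFF3 path.
#' @return `data.frame` with `qtl_id`, `trait_name`, `qtl_type`, `chrom`,
#'   `start`, `end` and attribute `n_skipped`.
#' @export
read_qtl_gff <- function(path) {
  if (!file.exists(path)) stop("QTL GFF not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  nm <- if ("Name" %in% names(meta)) as.character(meta$Name)
        else rep(NA_character_, length(gr))
  ty <- if ("trait_type" %in% names(meta)) as.character(meta$trait_type)
        else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(meta) && !anyNA(meta$ID)) {
    as.character(meta$ID)
  } else sprintf("QTL%05d", seq_along(gr))
  out <- data.frame(
    qtl_id = id, trait_name = nm, qtl_type = ty,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
  bad <- is.na(out$trait_name) | out$trait_name == "" |
    is.na(out$start) | is.na(out$end) | out$end < out$start
  if (any(bad)) {
    warning(sum(bad), " QTL row(s) lacking trait name or coordinates skipped")
    out <- out[!bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Overlap features with CSS flanking intervals
#'
#' Emits every (CSS, feature) pair whose intervals share at least
#' `min_overlap_bp` bases (closed-interval, any overlap qualifies by
#' default — no containment requirement). Lookup is indexed via an
#' interval join; on any fixture it equals a brute-force all-pairs scan.
#'
#' @param css CSS table (`css_id`, `chrom`, `start`, `end`).
#' @param features Feature table: genes (with `gene_id`) or QTL (with
#'   `qtl_id`), each with `chrom`, `start`, `end`.
#' @param feature_kind `"gene"` or `"qtl"`.
#' @param min_overlap_bp Minimum shared bases (default 1).
#' @return `data.frame` with `css_id`, `feature_id`, `feature_kind`,
#'   `overlap_bp`.
#' @export
annotate_features <- function(css, features,
                              feature_kind = c("gene", "qtl"),
                              min_overlap_bp = 1) {
  feature_kind <- match.arg(feature_kind)
  id_col <- if (feature_kind == "gene") "gene_id" else "qtl_id"
  if (!id_col %in% names(features)) {
    stop("features lack column ", id_col)
  }
  empty <- data.frame(css_id = character(0), feature_id = character(0),
                      feature_kind = character(0), overlap_bp = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(css) == 0 || nrow(features) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(as_granges(css), as_granges(features),
                                      minoverlap = min_overlap_bp)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  if (length(qi) == 0) return(empty)
  out <- data.frame(
    css_id = css$css_id[qi],
    feature_id = features[[id_col]][si],
    feature_kind = feature_kind,
    overlap_bp = overlap_width(css$start[qi], css$end[qi],
                               features$start[si], features$end[si]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$css_id, out$feature_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise QTL type composition of annotated overlaps
#'
#' @param overlaps QTL overlaps from [annotate_features()].
#' @param qtl QTL record table (for `qtl_id` to `qtl_type` lookup).
#' @return `data.frame` with `qtl_type`, `count`, `percentage`
#'   (percentages sum to 100 up to rounding).
#' @export
summarize_qtl_types <- function(overlaps, qtl) {
  if (nrow(overlaps) == 0) {
    return(data.frame(qtl_type = character(0), count = integer(0),
                      percentage = numeric(0), stringsAsFactors = FALSE))
  }
  ty <- qtl$qtl_type[match(overlaps$feature_id, qtl$qtl_id)]
  tab <- sort(table(ty), decreasing = TRUE)
  data.frame(qtl_type = names(tab), count = as.integer(tab),
             percentage = round(100 * as.integer(tab) / sum(tab), 2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Partition annotated genes by CSS class
#'
#' Splits the union of genes annotated within production and adaptation
#' CSS into three disjoint sets: production-only, adaptation-only, and
#' shared.
#'
#' @param overlaps_prod Gene overlaps for prodCSS (or a character vector
#'   of gene ids).
#' @param overlaps_adap Gene overlaps for adapCSS (or a character vector).
#' @return `list(prod_only =, adap_only =, shared =)` of sorted gene id
#'   vectors.
#' @export
partition_genes <- function(overlaps_prod, overlaps_adap) {
  ids <- function(x) {
    if (is.data.frame(x)) unique(x$feature_id) else unique(as.character(x))
  }
  p <- ids(overlaps_prod); a <- ids(overlaps_adap)
  list(prod_only = sort(setdiff(p, a)),
       adap_only = sort(setdiff(a, p)),
       shared = sort(intersect(p, a)))
}
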