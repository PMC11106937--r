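#' Cluster overlapping sweeps across studies
#'
#' Sweeps reported by different studies are merged into clusters when they
#' overlap within the same genomic region. The default is single-linkage:
#' clusters are the connected components of the pairwise-overlap graph per
#' chromosome, so a chain A-B, B-C joins all three even if A and C are
#' disjoint. `linkage = "common"` is a stricter sensitivity mode requiring
#' every member to overlap the running common intersection.
#'
#' @param catalog A `sweep_catalog`.
#' @param min_overlap_bp Minimum shared bases for two sweeps to be linked
#'   (default 1: any closed-interval overlap).
#' @param linkage `"single"` (connected components, default) or `"common"`
#'   (all members share an interval).
#' @return `data.frame` mapping every sweep to exactly one cluster:
#'   columns `sweep_id`, `cluster_id`, `chrom`.
#' @export
cluster_sweeps <- function(catalog, min_overlap_bp = 1,
                           linkage = c("single", "common")) {
  linkage <- match.arg(linkage)
  if (min_overlap_bp < 1) stop("min_overlap_bp must be >= 1")
  sw <- catalog$sweeps
  if (nrow(sw) == 0) {
    return(data.frame(sweep_id = character(0), cluster_id = character(0),
                      chrom = character(0), stringsAsFactors = FALSE))
  }
  o <- order(sw$chrom, sw$start, sw$end, sw$sweep_id)
  sw <- sw[o, , drop = FALSE]
  cluster <- integer(nrow(sw))
  cur <- 0L
  # sweep-line: intervals sorted by start; for intervals, single-linkage
  # components are maximal runs where each interval overlaps the running
  # cluster by >= min_overlap_bp
  cur_chrom <- ""
  cur_end <- -Inf       # max end (single) or min end (common)
  cur_start <- -Inf     # max start of members (common linkage only)
  for (i in seq_len(nrow(sw))) {
    s <- sw$start[i]; e <- sw$end[i]; ch <- sw$chrom[i]
    linked <- if (ch != cur_chrom) FALSE
    else if (linkage == "single") (min(e, cur_end) - s + 1) >= min_overlap_bp
    else (min(e, cur_end) - max(s, cur_start) + 1) >= min_overlap_bp
    if (!linked) {
      cur <- cur + 1L
      cur_chrom <- ch
      cur_end <- e
      cur_start <- s
    } else if (linkage == "single") {
      cur_end <- max(cur_end, e)
    } else {
      cur_end <- min(cur_end, e)
      cur_start <- max(cur_start, s)
    }
    cluster[i] <- cur
  }
  out <- data.frame(sweep_id = sw$sweep_id,
                    cluster_id = sprintf("CL%05d", cluster),
                    chrom = sw$chrom, stringsAsFactors = FALSE)
  out[match(catalog$sweeps$sweep_id, out$sweep_id), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Call confirmed selective sweeps (CSS) from sweep clusters
#'
#' A cluster becomes a confirmed selective sweep when it is supported by at
#' least `min_studies` distinct studies (study count, not sweep count). The
#' CSS flanking interval spans from the smallest start to the largest end
#' of its member sweeps. Clusters below the support threshold are dropped
#' but counted in the `dropped_clusters` attribute.
#'
#' @param clusters Output of [cluster_sweeps()].
#' @param catalog The `sweep_catalog` the clusters came from.
#' @param min_studies Minimum number of distinct supporting studies
#'   (default 3).
#' @return `data.frame` with one row per CSS: `css_id`, `chrom`, `start`,
#'   `end`, `n_sweeps`, `n_studies`, `member_sweeps`, `supporting_studies`
#'   (both `;`-joined), plus attribute `dropped_clusters` (count of
#'   clusters failing the threshold).
#' @export
call_css <- function(clusters, catalog, min_studies = 3) {
  sw <- catalog$sweeps
  m <- merge(clusters, sw, by = "sweep_id")
  empty <- data.frame(css_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      n_sweeps = integer(0), n_studies = integer(0),
                      member_sweeps = character(0),
                      supporting_studies = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(m) == 0) {
    attr(empty, "dropped_clusters") <- 0L
    return(empty)
  }
  parts <- split(m, m$cluster_id)
  rows <- lapply(parts, function(p) {
    studies <- sort(unique(p$study_id))
    sp <- interval_span(p$chrom.x, p$start, p$end)
    data.frame(chrom = sp$chrom, start = sp$start, end = sp$end,
               n_sweeps = nrow(p), n_studies = length(studies),
               member_sweeps = paste(sort(p$sweep_id), collapse = ";"),
               supporting_studies = paste(studies, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  css <- do.call(rbind, rows)
  dropped <- sum(css$n_studies < min_studies)
  css <- css[css$n_studies >= min_studies, , drop = FALSE]
  if (nrow(css)) {
    o <- order(match(css$chrom, catalog$layout$chrom), css$start, css$end)
    css <- css[o, , drop = FALSE]
    css <- cbind(css_id = sprintf("CSS%04d", seq_len(nrow(css))), css,
                 stringsAsFactors = FALSE)
  } else {
    css <- empty
  }
  rownames(css) <- NULL
  attr(css, "dropped_clusters") <- dropped
  css
}

#' Classify CSS as production or adaptation by supporting-class proportions
#'
#' For each CSS the proportion of production and adaptation support is
#' computed over the chosen basis (distinct supporting studies by default,
#' or member sweeps). A CSS with production fraction strictly above
#' `prod_threshold` is a `prodCSS`; one with adaptation fraction strictly
#' above `adap_threshold` is an `adapCSS`; anything else is
#' `unclassified`. The two fractions always sum to 1.
#'
#' @param css CSS table from [call_css()].
#' @param catalog The `sweep_catalog`.
#' @param prod_threshold Production fraction threshold, strict `>`
#'   (default 0.60).
#' @param adap_threshold Adaptation fraction threshold, strict `>`
#'   (default 0.70).
#' @param basis Count classes over `"studies"` (distinct studies, default)
#'   or `"sweeps"` (member sweep records).
#' @return The CSS table with `prod_fraction`, `adap_fraction`,
#'   `classification` columns added.
#' @export
classify_css <- function(css, catalog, prod_threshold = 0.60,
                         adap_threshold = 0.70,
                         basis = c("studies", "sweeps")) {
  basis <- match.arg(basis)
  for (th in c(prod_threshold, adap_threshold)) {
    if (!is.numeric(th) || th <= 0 || th > 1) {
      stop("classification thresholds must lie in (0, 1]")
    }
  }
  class_of_study <- stats::setNames(catalog$studies$study_class,
                                    catalog$studies$study_id)
  class_of_sweep <- stats::setNames(catalog$sweeps$study_class,
                                    catalog$sweeps$sweep_id)
  frac <- vapply(seq_len(nrow(css)), function(i) {
    cls <- if (basis == "studies") {
      class_of_study[strsplit(css$supporting_studies[i], ";", fixed = TRUE)[[1]]]
    } else {
      class_of_sweep[strsplit(css$member_sweeps[i], ";", fixed = TRUE)[[1]]]
    }
    mean(cls == "production")
  }, numeric(1))
  css$prod_fraction <- frac
  css$adap_fraction <- 1 - frac
  css$classification <- ifelse(
    css$prod_fraction > prod_threshold, "prodCSS",
    ifelse(css$adap_fraction > adap_threshold, "adapCSS", "unclassified")
  )
  if (nrow(css) == 0) css$classification <- character(0)
  css
}

#' CSS counts under every basis and threshold configuration
#'
#' The classification rule is stated ambiguously in its source material
#' (study- vs sweep-level proportions; 60/70 vs 60/60 thresholds), so the
#' counts are reported under all four combinations, making the
#' configuration that matches an external reference identifiable.
#'
#' @param clusters Output of [cluster_sweeps()].
#' @param catalog A `sweep_catalog`.
#' @param min_studies Minimum supporting studies (default 3).
#' @return `data.frame` with one row per configuration: `basis`,
#'   `prod_threshold`, `adap_threshold`, `n_css`, `n_prodcss`,
#'   `n_adapcss`, `n_unclassified`.
#' @export
css_count_grid <- function(clusters, catalog, min_studies = 3) {
  css <- call_css(clusters, catalog, min_studies = min_studies)
  grid <- expand.grid(basis = c("studies", "sweeps"),
                      adap_threshold = c(0.70, 0.60),
                      stringsAsFactors = FALSE)
  grid$prod_threshold <- 0.60
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cl <- classify_css(css, catalog, prod_threshold = grid$prod_threshold[i],
                       adap_threshold = grid$adap_threshold[i],
                       basis = grid$basis[i])
    data.frame(basis = grid$basis[i],
               prod_threshold = grid$prod_threshold[i],
               adap_threshold = grid$adap_threshold[i],
               n_css = nrow(cl),
               n_prodcss = sum(cl$classification == "prodCSS"),
               n_adapcss = sum(cl$classification == "adapCSS"),
               n_unclassified = sum(cl$classification == "unclassified"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Write classified CSS as TSV and BED
#'
#' @param css Classified CSS table.
#' @param tsv_path Output TSV (1-based inclusive, all columns).
#' @param bed_path Optional BED output (0-based half-open, classification
#'   in the name field).
#' @return `tsv_path`, invisibly.
#' @export
write_css <- function(css, tsv_path, bed_path = NULL) {
  cols <- c("css_id", "chrom", "start", "end", "n_sweeps", "n_studies",
            "prod_fraction", "adap_fraction", "classification",
            "member_sweeps", "supporting_studies")
  cols <- intersect(cols, names(css))
  utils::write.table(css[, cols, drop = FALSE], tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bed_path)) {
    bed <- data.frame(
      chrom = css$chrom, start = css$start - 1, end = css$end,
      name = if (nrow(css)) paste0(css$css_id, "|", css$classification)
             else character(0))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(tsv_path)
}

#' Read a CSS table written by [write_css()]
#'
#' @param path TSV path.
#' @return CSS `data.frame`.
#' @export
read_css <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
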