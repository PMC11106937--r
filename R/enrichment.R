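#' Exact upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` items from a
#' background of `N` of which `K` carry the property, the probability of
#' seeing `k` or more carriers. Exact (no normal approximation); this is
#' the over-representation statistic used for both QTL-trait and GO-term
#' enrichment.
#'
#' @param k Observed carriers in the selection.
#' @param K Carriers in the background.
#' @param n Selection size.
#' @param N Background size.
#' @return Probability in `[0, 1]`. Vectorised.
#' @examples
#' hypergeom_upper_tail(0, 5, 4, 20)  # 1
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | k > n | k > K | n > N | K > N
  if (any(bad)) {
    stop("invalid hypergeometric counts: need 0 <= k <= min(n, K), ",
         "n <= N, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, order-aligned with the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values in `[0, 1]`, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' QTL trait enrichment within CSS against a genome-wide background
#'
#' Each trait annotated within the CSS is tested with an exact upper-tail
#' hypergeometric over the full QTL database (the "genome-wide" universe):
#' `N` = all database records, `K` = database records of the trait, `n` =
#' distinct records annotated within CSS, `k` = annotated records of the
#' trait. A trait passes when its BH-adjusted p-value is below `alpha`
#' *and* the database holds at least `min_db_count` records for it
#' (default 2, i.e. "more than one").
#'
#' @param qtl_overlaps QTL overlaps from [annotate_features()].
#' @param qtl_db Full QTL record table (the background).
#' @param alpha FDR threshold (default 0.05).
#' @param min_db_count Minimum database records per trait (default 2).
#' @return `data.frame` with `term_id` (trait name), `k`, `n`, `K`, `N`,
#'   `p_value`, `fdr`, `passes`; one row per trait with `k >= 1`.
#' @export
qtl_enrich <- function(qtl_overlaps, qtl_db, alpha = 0.05,
                       min_db_count = 2) {
  if (nrow(qtl_db) == 0) stop("empty QTL database")
  empty <- data.frame(term_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p_value = numeric(0), fdr = numeric(0),
                      passes = logical(0), stringsAsFactors = FALSE)
  if (nrow(qtl_overlaps) == 0) return(empty)
  # counting unit: distinct database records (a record overlapping several
  # CSS counts once)
  sel_ids <- unique(qtl_overlaps$feature_id)
  sel_trait <- qtl_db$trait_name[match(sel_ids, qtl_db$qtl_id)]
  if (anyNA(sel_trait)) {
    stop("overlap feature id(s) absent from the QTL database")
  }
  N <- nrow(qtl_db)
  n <- length(sel_ids)
  k_tab <- table(sel_trait)
  K_tab <- table(qtl_db$trait_name)
  traits <- sort(names(k_tab))
  k <- as.integer(k_tab[traits])
  K <- as.integer(K_tab[traits])
  p <- hypergeom_upper_tail(k, K, n, N)
  fdr <- bh_fdr(p)
  data.frame(term_id = traits, k = k, n = n, K = K, N = N,
             p_value = p, fdr = fdr,
             passes = (fdr < alpha) & (K >= min_db_count),
             stringsAsFactors = FALSE)
}

#' GO term enrichment for a gene set
#'
#' Exact upper-tail hypergeometric per term over the gene universe. Terms
#' annotated to more than `max_term_size` universe genes are excluded
#' before testing (and hence before FDR correction) to avoid broad,
#' uninformative terms; with the default 999 only terms with fewer than
#' 1000 assigned genes are considered. Namespaces are corrected jointly.
#'
#' @param gene_set Character vector of selected genes (must be a subset of
#'   `universe`).
#' @param annotation Two-column `data.frame` (`gene_id`, `term_id`).
#' @param universe Character vector: the gene background.
#' @param alpha FDR threshold (default 0.05).
#' @param max_term_size Largest allowed universe term size (default 999).
#' @return `data.frame` with `term_id`, `k`, `n`, `K`, `N`, `p_value`,
#'   `fdr`, `passes`; one row per tested term with `k >= 1`.
#' @export
go_enrich <- function(gene_set, annotation, universe, alpha = 0.05,
                      max_term_size = 999) {
  gene_set <- unique(as.character(gene_set))
  universe <- unique(as.character(universe))
  out_of_universe <- setdiff(gene_set, universe)
  if (length(out_of_universe)) {
    stop("gene set not contained in universe: ",
         paste(utils::head(out_of_universe, 10), collapse = ", "))
  }
  empty <- data.frame(term_id = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      p_value = numeric(0), fdr = numeric(0),
                      passes = logical(0), stringsAsFactors = FALSE)
  ann <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "term_id")])
  if (nrow(ann) == 0 || length(gene_set) == 0) return(empty)
  N <- length(universe)
  n <- length(gene_set)
  K_tab <- table(ann$term_id)
  keep_terms <- names(K_tab)[as.integer(K_tab) <= max_term_size]
  sel <- ann[ann$gene_id %in% gene_set & ann$term_id %in% keep_terms, ,
             drop = FALSE]
  if (nrow(sel) == 0) return(empty)
  k_tab <- table(sel$term_id)
  terms <- sort(names(k_tab))
  k <- as.integer(k_tab[terms])
  K <- as.integer(K_tab[terms])
  p <- hypergeom_upper_tail(k, K, n, N)
  fdr <- bh_fdr(p)
  data.frame(term_id = terms, k = k, n = n, K = K, N = N,
             p_value = p, fdr = fdr, passes = fdr < alpha,
             stringsAsFactors = FALSE)
}

#' Partition two enrichment result sets into exclusive and shared terms
#'
#' Operates on the passing terms of each result set, by `term_id`.
#'
#' @param results_a,results_b Enrichment tables (with `term_id`,
#'   `passes`), or character vectors of term ids.
#' @return `list(exclusive_a =, exclusive_b =, shared =)` of sorted term
#'   ids.
#' @export
intersect_enrichments <- function(results_a, results_b) {
  ids <- function(x) {
    if (is.data.frame(x)) unique(x$term_id[x$passes])
    else unique(as.character(x))
  }
  a <- ids(results_a); b <- ids(results_b)
  list(exclusive_a = sort(setdiff(a, b)),
       exclusive_b = sort(setdiff(b, a)),
       shared = sort(intersect(a, b)))
}
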