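#' Build a bipartite gene-term network
#'
#' Undirected, unweighted graph between genes and enriched terms; one edge
#' per distinct (gene, term) pair. Nodes exist only through edges, so
#' isolated genes/terms never enter the graph.
#'
#' @param gene_term_pairs `data.frame` with columns `gene` and `term`.
#' @return An `igraph` object with vertex attributes `name` and `side`
#'   (`"gene"` or `"term"`).
#' @export
build_gene_term_network <- function(gene_term_pairs) {
  pairs <- unique(data.frame(gene = as.character(gene_term_pairs$gene),
                             term = as.character(gene_term_pairs$term),
                             stringsAsFactors = FALSE))
  if (nrow(pairs) && any(pairs$gene == pairs$term)) {
    stop("gene and term ids collide; bipartite sides must be disjoint")
  }
  g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
  igraph::V(g)$side <- ifelse(igraph::V(g)$name %in% pairs$gene,
                              "gene", "term")
  g
}

#' Betweenness centrality of every node
#'
#' For each node `v`, the sum over unordered node pairs `s != t != v` of
#' the fraction of shortest `s`-`t` paths passing through `v`. Raw
#' (unnormalised) values with endpoints excluded; disconnected pairs
#' contribute nothing.
#'
#' @param network An undirected `igraph` object.
#' @return Named numeric vector of scores.
#' @export
betweenness_scores <- function(network) {
  igraph::betweenness(network, directed = FALSE, normalized = FALSE)
}

#' Select hub nodes above a betweenness quantile
#'
#' The threshold is the linear-interpolation (type 7) sample quantile of
#' the eligible nodes' scores; hubs are the eligible nodes scoring
#' strictly above it. Eligibility is typically restricted to the gene side
#' of a bipartite network, so terms are never hubs.
#'
#' @param scores Named numeric vector from [betweenness_scores()].
#' @param quantile Quantile level (default 0.90).
#' @param eligible Character vector of node names competing for hub status
#'   (default: all scored nodes).
#' @return `list(scores =, quantile_threshold =, hubs =)` where `hubs` is
#'   a character vector.
#' @export
select_hubs <- function(scores, quantile = 0.90, eligible = names(scores)) {
  if (length(eligible) == 0) stop("empty eligible node set")
  miss <- setdiff(eligible, names(scores))
  if (length(miss)) stop("eligible node(s) without scores: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  s <- scores[eligible]
  threshold <- unname(stats::quantile(s, probs = quantile, type = 7))
  list(scores = s, quantile_threshold = threshold,
       hubs = sort(names(s)[s > threshold]))
}

#' Build a gene-QTL association network via CSS co-occurrence
#'
#' A gene is linked to an enriched QTL trait when the gene and a database
#' record of that trait are annotated within the same CSS (co-occurrence,
#' not direct gene/QTL coordinate overlap). At `level = "trait"` the edges
#' are unweighted gene-trait pairs; at `level = "type"` traits collapse to
#' their QTL type and each edge is weighted by the number of distinct
#' linked traits of that type.
#'
#' @param genes Character vector of gene ids to include (e.g. hub genes).
#' @param gene_overlaps Gene overlaps from [annotate_features()].
#' @param qtl_overlaps QTL overlaps from [annotate_features()].
#' @param qtl_db QTL record table (`qtl_id`, `trait_name`, `qtl_type`).
#' @param enriched_traits Character vector of enriched trait names; only
#'   these traits form edges.
#' @param level `"trait"` or `"type"`.
#' @return An undirected bipartite `igraph`; at `level = "type"` edges
#'   carry a `weight` attribute.
#' @export
build_gene_qtl_network <- function(genes, gene_overlaps, qtl_overlaps,
                                   qtl_db, enriched_traits,
                                   level = c("trait", "type")) {
  level <- match.arg(level)
  go <- gene_overlaps[gene_overlaps$feature_id %in% genes, , drop = FALSE]
  qo <- qtl_overlaps
  qo$trait_name <- qtl_db$trait_name[match(qo$feature_id, qtl_db$qtl_id)]
  qo$qtl_type <- qtl_db$qtl_type[match(qo$feature_id, qtl_db$qtl_id)]
  qo <- qo[qo$trait_name %in% enriched_traits, , drop = FALSE]
  linked <- merge(go[, c("css_id", "feature_id")],
                  qo[, c("css_id", "trait_name", "qtl_type")],
                  by = "css_id")
  names(linked)[names(linked) == "feature_id"] <- "gene"
  gene_trait <- unique(linked[, c("gene", "trait_name", "qtl_type")])
  if (level == "trait") {
    pairs <- unique(gene_trait[, c("gene", "trait_name")])
    g <- igraph::graph_from_data_frame(pairs, directed = FALSE)
    igraph::V(g)$side <- ifelse(igraph::V(g)$name %in% pairs$gene,
                                "gene", "trait")
    return(g)
  }
  # weight = number of distinct traits of the type linked to the gene
  if (nrow(gene_trait) == 0) {
    agg <- data.frame(gene = character(0), qtl_type = character(0),
                      weight = integer(0), stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(trait_name ~ gene + qtl_type, data = gene_trait,
                            FUN = function(x) length(unique(x)))
    names(agg)[names(agg) == "trait_name"] <- "weight"
  }
  g <- igraph::graph_from_data_frame(agg, directed = FALSE)
  igraph::V(g)$side <- ifelse(igraph::V(g)$name %in% agg$gene,
                              "gene", "type")
  g
}

#' Export a network as GraphML or an edge-list TSV
#'
#' @param network An `igraph` object.
#' @param path Output path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(network, what = "edges")
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read back a network exported with [export_network()]
#'
#' @param path File path.
#' @param format `"graphml"` or `"edgelist_tsv"`.
#' @return An `igraph` object.
#' @export
read_network <- function(path, format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    el <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(el, directed = FALSE)
  }
}
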