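#' Assemble and validate a pipeline run configuration
#'
#' Collects the input paths and every tunable threshold of the analysis.
#' Validation happens before any compute: thresholds outside their ranges
#' or missing input files fail immediately.
#'
#' @param genome,sweeps,gtf,qtl_gff,obo,gene_terms Input file paths.
#' @param min_studies Minimum distinct studies per CSS (default 3).
#' @param flank Marker expansion flank, bp (default 250000).
#' @param prod_threshold,adap_threshold Classification thresholds
#'   (defaults 0.60 / 0.70, strict `>`).
#' @param basis `"studies"` or `"sweeps"` for class fractions.
#' @param min_overlap_bp Minimum sweep overlap, bp (default 1).
#' @param alpha Enrichment FDR threshold (default 0.05).
#' @param min_db_count Minimum database records per QTL trait
#'   (default 2).
#' @param max_term_size Largest tested GO term (default 999).
#' @param wang_threshold GO reduction similarity threshold (default 0.7).
#' @param hub_quantile Betweenness hub quantile (default 0.90).
#' @return A validated `sweep_config` list.
#' @export
sweep_config <- function(genome, sweeps, gtf, qtl_gff, obo, gene_terms,
                         min_studies = 3, flank = 250000,
                         prod_threshold = 0.60, adap_threshold = 0.70,
                         basis = c("studies", "sweeps"),
                         min_overlap_bp = 1, alpha = 0.05,
                         min_db_count = 2, max_term_size = 999,
                         wang_threshold = 0.7, hub_quantile = 0.90) {
  basis <- match.arg(basis)
  cfg <- list(genome = genome, sweeps = sweeps, gtf = gtf,
              qtl_gff = qtl_gff, obo = obo, gene_terms = gene_terms,
              min_studies = min_studies, flank = flank,
              prod_threshold = prod_threshold,
              adap_threshold = adap_threshold, basis = basis,
              min_overlap_bp = min_overlap_bp, alpha = alpha,
              min_db_count = min_db_count, max_term_size = max_term_size,
              wang_threshold = wang_threshold, hub_quantile = hub_quantile)
  in_range <- function(x, lo, hi) is.numeric(x) && x >= lo && x <= hi
  if (!in_range(cfg$prod_threshold, 1e-9, 1) ||
      !in_range(cfg$adap_threshold, 1e-9, 1)) {
    stop("classification thresholds must lie in (0, 1]")
  }
  if (!in_range(cfg$alpha, 0, 1)) stop("alpha must lie in [0, 1]")
  if (!in_range(cfg$hub_quantile, 0, 1)) {
    stop("hub_quantile must lie in [0, 1]")
  }
  if (!in_range(cfg$wang_threshold, 0, 1)) {
    stop("wang_threshold must lie in [0, 1]")
  }
  if (cfg$min_studies < 1 || cfg$flank < 0 || cfg$min_overlap_bp < 1 ||
      cfg$min_db_count < 1 || cfg$max_term_size < 1) {
    stop("count/size parameters out of range")
  }
  for (f in c("genome", "sweeps", "gtf", "qtl_gff", "obo", "gene_terms")) {
    if (!file.exists(cfg[[f]])) stop("input file missing: ", cfg[[f]])
  }
  class(cfg) <- "sweep_config"
  cfg
}

#' Run the full CSS meta-analysis pipeline
#'
#' Executes every stage in order — catalog normalisation, CSS calling and
#' classification, gene/QTL annotation per CSS class, QTL-type summaries,
#' QTL and GO enrichment (the GO analysis is run separately for the genes
#' exclusive to prodCSS, exclusive to adapCSS, and shared), Wang-based GO
#' reduction, gene-term networks with betweenness hub selection, and
#' gene-QTL networks for the hubs — writing each stage's table under
#' `out_dir` plus a `manifest.json` recording the configuration and
#' per-stage counts.
#'
#' @param config A `sweep_config`.
#' @param out_dir Output directory (created if absent).
#' @return A list with every stage's in-memory result, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (!inherits(config, "sweep_config")) {
    stop("config must be built by sweep_config()")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(paste("FAILED at stage:", name), file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  layout <- stage("genome", read_genome(config$genome))
  catalog <- stage("catalog",
                   read_sweep_table(config$sweeps, layout,
                                    flank = config$flank))
  write_sweep_catalog(catalog, file.path(out_dir, "catalog.tsv"),
                      file.path(out_dir, "catalog.bed"))
  counts$n_sweeps <- nrow(catalog$sweeps)
  counts$n_studies <- nrow(catalog$studies)

  clusters <- stage("cluster",
                    cluster_sweeps(catalog,
                                   min_overlap_bp = config$min_overlap_bp))
  css <- stage("css", {
    css <- call_css(clusters, catalog, min_studies = config$min_studies)
    classify_css(css, catalog, prod_threshold = config$prod_threshold,
                 adap_threshold = config$adap_threshold,
                 basis = config$basis)
  })
  write_css(css, file.path(out_dir, "css.tsv"),
            file.path(out_dir, "css.bed"))
  grid <- css_count_grid(clusters, catalog,
                         min_studies = config$min_studies)
  utils::write.table(grid, file.path(out_dir, "css_count_grid.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$n_css <- nrow(css)
  counts$n_prodcss <- sum(css$classification == "prodCSS")
  counts$n_adapcss <- sum(css$classification == "adapCSS")

  genes <- stage("gtf", read_gtf(config$gtf))
  qtl <- stage("qtl_gff", read_qtl_gff(config$qtl_gff))
  prod_css <- css[css$classification == "prodCSS", , drop = FALSE]
  adap_css <- css[css$classification == "adapCSS", , drop = FALSE]

  ann <- stage("annotate", list(
    gene_prod = annotate_features(prod_css, genes, "gene"),
    gene_adap = annotate_features(adap_css, genes, "gene"),
    qtl_prod = annotate_features(prod_css, qtl, "qtl"),
    qtl_adap = annotate_features(adap_css, qtl, "qtl")
  ))
  for (nm in names(ann)) {
    utils::write.table(ann[[nm]],
                       file.path(out_dir, paste0("overlaps_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  qtl_types <- list(prod = summarize_qtl_types(ann$qtl_prod, qtl),
                    adap = summarize_qtl_types(ann$qtl_adap, qtl))
  utils::write.table(qtl_types$prod,
                     file.path(out_dir, "qtl_types_prod.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(qtl_types$adap,
                     file.path(out_dir, "qtl_types_adap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  gene_sets <- partition_genes(ann$gene_prod, ann$gene_adap)
  counts$n_genes_prod <- length(unique(ann$gene_prod$feature_id))
  counts$n_genes_adap <- length(unique(ann$gene_adap$feature_id))
  counts$n_genes_shared <- length(gene_sets$shared)

  enr_qtl <- stage("qtl_enrich", list(
    prod = qtl_enrich(ann$qtl_prod, qtl, alpha = config$alpha,
                      min_db_count = config$min_db_count),
    adap = qtl_enrich(ann$qtl_adap, qtl, alpha = config$alpha,
                      min_db_count = config$min_db_count)
  ))
  utils::write.table(enr_qtl$prod,
                     file.path(out_dir, "qtl_enrichment_prod.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr_qtl$adap,
                     file.path(out_dir, "qtl_enrichment_adap.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  qtl_venn <- intersect_enrichments(enr_qtl$prod, enr_qtl$adap)
  counts$n_enriched_qtl_prod <- sum(enr_qtl$prod$passes)
  counts$n_enriched_qtl_adap <- sum(enr_qtl$adap$passes)
  counts$n_enriched_qtl_shared <- length(qtl_venn$shared)

  annotation <- stage("gene_terms", utils::read.delim(
    config$gene_terms, sep = "\t", stringsAsFactors = FALSE))
  graph <- stage("obo", parse_obo(config$obo))
  universe <- genes$gene_id
  enr_go <- stage("go_enrich", lapply(gene_sets, function(gs) {
    if (length(gs) == 0) return(
      go_enrich(character(0), annotation, universe, alpha = config$alpha,
                max_term_size = config$max_term_size))
    go_enrich(gs, annotation, universe, alpha = config$alpha,
              max_term_size = config$max_term_size)
  }))
  names(enr_go) <- names(gene_sets)
  counts$n_enriched_go_prod <- sum(enr_go$prod_only$passes)
  counts$n_enriched_go_adap <- sum(enr_go$adap_only$passes)
  counts$n_enriched_go_shared_genes <- sum(enr_go$shared$passes)

  reduced <- stage("reduce_go", lapply(enr_go, function(e) {
    pass <- e[e$passes, c("term_id", "p_value"), drop = FALSE]
    reduce_terms(pass, graph, threshold = config$wang_threshold)
  }))
  for (nm in names(reduced)) {
    utils::write.table(reduced[[nm]],
                       file.path(out_dir,
                                 paste0("go_reduced_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(enr_go[[nm]],
                       file.path(out_dir,
                                 paste0("go_enrichment_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  networks <- stage("network", {
    sets <- list(prod_only = list(genes = gene_sets$prod_only,
                                  enr = enr_go$prod_only),
                 adap_only = list(genes = gene_sets$adap_only,
                                  enr = enr_go$adap_only),
                 shared = list(genes = gene_sets$shared,
                               enr = enr_go$shared))
    lapply(sets, function(x) {
      pass_terms <- x$enr$term_id[x$enr$passes]
      pairs <- annotation[annotation$gene_id %in% x$genes &
                            annotation$term_id %in% pass_terms, ,
                          drop = FALSE]
      if (nrow(pairs) == 0) {
        return(list(graph = NULL, scores = numeric(0),
                    threshold = NA_real_, hubs = character(0)))
      }
      net <- build_gene_term_network(
        data.frame(gene = pairs$gene_id, term = pairs$term_id))
      sc <- betweenness_scores(net)
      eligible <- igraph::V(net)$name[igraph::V(net)$side == "gene"]
      hub <- select_hubs(sc, quantile = config$hub_quantile,
                         eligible = eligible)
      list(graph = net, scores = sc,
           threshold = hub$quantile_threshold, hubs = hub$hubs)
    })
  })
  hub_rows <- lapply(names(networks), function(nm) {
    x <- networks[[nm]]
    if (length(x$scores) == 0) return(NULL)
    data.frame(set = nm, node = names(x$scores),
               betweenness = unname(x$scores),
               is_hub = names(x$scores) %in% x$hubs,
               threshold = x$threshold, stringsAsFactors = FALSE)
  })
  hub_tab <- do.call(rbind, hub_rows)
  if (is.null(hub_tab)) {
    hub_tab <- data.frame(set = character(0), node = character(0),
                          betweenness = numeric(0), is_hub = logical(0),
                          threshold = numeric(0))
  }
  utils::write.table(hub_tab, file.path(out_dir, "betweenness.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$n_hubs_prod <- length(networks$prod_only$hubs)
  counts$n_hubs_adap <- length(networks$adap_only$hubs)
  counts$n_hubs_shared <- length(networks$shared$hubs)

  gene_qtl <- stage("gene_qtl_network", {
    lapply(list(prod_only = list(hubs = networks$prod_only$hubs,
                                 go_ov = ann$gene_prod, qo = ann$qtl_prod,
                                 enr = enr_qtl$prod),
                adap_only = list(hubs = networks$adap_only$hubs,
                                 go_ov = ann$gene_adap, qo = ann$qtl_adap,
                                 enr = enr_qtl$adap)),
           function(x) {
             if (length(x$hubs) == 0) return(NULL)
             traits <- x$enr$term_id[x$enr$passes]
             list(trait = build_gene_qtl_network(
                    x$hubs, x$go_ov, x$qo, qtl, traits, level = "trait"),
                  type = build_gene_qtl_network(
                    x$hubs, x$go_ov, x$qo, qtl, traits, level = "type"))
           })
  })
  for (nm in names(gene_qtl)) {
    if (is.null(gene_qtl[[nm]])) next
    export_network(gene_qtl[[nm]]$trait,
                   file.path(out_dir, paste0("gene_qtl_", nm, ".graphml")),
                   "graphml")
    export_network(gene_qtl[[nm]]$type,
                   file.path(out_dir,
                             paste0("gene_qtl_type_", nm, ".tsv")),
                   "edgelist_tsv")
  }

  manifest <- list(config = unclass(config), counts = counts,
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(layout = layout, catalog = catalog, clusters = clusters,
                 css = css, grid = grid, genes = genes, qtl = qtl,
                 overlaps = ann, qtl_types = qtl_types,
                 gene_sets = gene_sets, qtl_enrichment = enr_qtl,
                 go_enrichment = enr_go, go_reduced = reduced,
                 networks = networks, gene_qtl_networks = gene_qtl,
                 counts = counts))
}

#' Summarise a completed pipeline run
#'
#' Recounts the headline numbers directly from the written tables of a
#' run directory (independently of the in-memory results).
#'
#' @param out_dir Directory written by [run_pipeline()].
#' @return Named list of counts.
#' @export
summarize_run <- function(out_dir) {
  need <- c("css.tsv", "manifest.json")
  for (f in need) {
    if (!file.exists(file.path(out_dir, f))) {
      stop("missing pipeline output: ", f)
    }
  }
  css <- read_css(file.path(out_dir, "css.tsv"))
  rd <- function(f) {
    p <- file.path(out_dir, f)
    if (file.exists(p)) utils::read.delim(p, sep = "\t",
                                          stringsAsFactors = FALSE)
    else NULL
  }
  gp <- rd("overlaps_gene_prod.tsv"); ga <- rd("overlaps_gene_adap.tsv")
  eq_p <- rd("qtl_enrichment_prod.tsv"); eq_a <- rd("qtl_enrichment_adap.tsv")
  bt <- rd("betweenness.tsv")
  shared <- if (!is.null(gp) && !is.null(ga)) {
    length(intersect(unique(gp$feature_id), unique(ga$feature_id)))
  } else 0L
  list(
    n_css = nrow(css),
    n_prodcss = sum(css$classification == "prodCSS"),
    n_adapcss = sum(css$classification == "adapCSS"),
    n_genes_prod = if (is.null(gp)) 0L else length(unique(gp$feature_id)),
    n_genes_adap = if (is.null(ga)) 0L else length(unique(ga$feature_id)),
    n_genes_shared = shared,
    n_enriched_qtl_prod = if (is.null(eq_p)) 0L else sum(eq_p$passes),
    n_enriched_qtl_adap = if (is.null(eq_a)) 0L else sum(eq_a$passes),
    n_hub_genes = if (is.null(bt)) 0L else sum(bt$is_hub)
  )
}
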