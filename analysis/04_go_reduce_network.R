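#!/usr/bin/env Rscript

# Stage 4: reduce redundant GO terms and select hub genes by network
# betweenness.
#
# Enriched GO terms that are Wang-similar (>= 0.7) under a shared direct
# parent collapse into one group carrying the smallest member p-value.
# Gene-term networks are built per gene set; hub genes are those with
# betweenness strictly above the 90% quantile of the gene side. Hubs are
# then linked to enriched QTL traits through CSS co-occurrence.

suppressMessages(library(sweepcss))

ind <- "results/simulated_input"
enr <- "results/enrichment"
out <- "results/network"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

graph <- parse_obo(file.path(ind, "go.obo"))
annotation <- read.delim(file.path(ind, "gene_terms.tsv"))
qtl <- read_qtl_gff(file.path(ind, "qtl.gff3"))

for (nm in c("prod_only", "adap_only", "shared")) {
  e <- read.delim(file.path(enr, paste0("go_enrichment_", nm, ".tsv")))
  pass <- e[e$passes, c("term_id", "p_value")]
  red <- reduce_terms(pass, graph)
  write.table(red, file.path(out, paste0("go_reduced_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(pass)) {
    cat(nm, ":", nrow(pass), "enriched terms ->", nrow(red),
        "reduced groups\n")
  }

  pairs <- annotation[annotation$term_id %in% pass$term_id, ]
  if (nrow(pairs) == 0) next
  ov_file <- file.path(enr, paste0(
    "overlaps_gene_", sub("_only", "", nm), ".tsv"))
  genes_in_class <- if (file.exists(ov_file)) {
    unique(read.delim(ov_file)$feature_id)
  } else unique(pairs$gene_id)
  pairs <- pairs[pairs$gene_id %in% genes_in_class, ]
  if (nrow(pairs) == 0) next
  net <- build_gene_term_network(
    data.frame(gene = pairs$gene_id, term = pairs$term_id))
  sc <- betweenness_scores(net)
  eligible <- igraph::V(net)$name[igraph::V(net)$side == "gene"]
  hub <- select_hubs(sc, quantile = 0.90, eligible = eligible)
  tab <- data.frame(node = names(hub$scores),
                    betweenness = unname(hub$scores),
                    is_hub = names(hub$scores) %in% hub$hubs,
                    threshold = hub$quantile_threshold)
  write.table(tab, file.path(out, paste0("betweenness_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  export_network(net, file.path(out, paste0("gene_term_", nm, ".graphml")),
                 "graphml")
  cat(nm, ": hub genes", length(hub$hubs), "of", length(eligible),
      sprintf("(threshold %.2f)\n", hub$quantile_threshold))

  # hub genes to enriched QTL traits via shared CSS
  if (length(hub$hubs) && nm != "shared") {
    cl <- sub("_only", "", nm)
    eq <- read.delim(file.path(enr, paste0("qtl_enrichment_", cl, ".tsv")))
    gov <- read.delim(file.path(enr, paste0("overlaps_gene_", cl, ".tsv")))
    qov <- read.delim(file.path(enr, paste0("overlaps_qtl_", cl, ".tsv")))
    traits <- eq$term_id[eq$passes]
    if (length(traits)) {
      gq <- build_gene_qtl_network(hub$hubs, gov, qov, qtl, traits,
                                   level = "type")
      export_network(gq, file.path(out, paste0("gene_qtl_type_", nm,
                                               ".tsv")),
                     "edgelist_tsv")
      cat("  hub-QTL network:", igraph::ecount(gq), "type-level edges\n")
    }
  }
}
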