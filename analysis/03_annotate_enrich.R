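#!/usr/bin/env Rscript

# Stage 3: annotate genes and QTL within CSS flanks and run enrichment.
#
# Genes (GTF) and QTL records (QTLdb-style GFF) overlapping each CSS
# flanking interval by >= 1 bp are annotated per CSS class. QTL traits
# are tested with an exact upper-tail hypergeometric against the whole
# database (genome-wide background); passing requires FDR < 0.05 and
# more than one database record. GO enrichment runs separately for the
# genes exclusive to prodCSS, exclusive to adapCSS, and shared, keeping
# only terms under 1000 universe genes.

suppressMessages(library(sweepcss))

ind <- "results/simulated_input"
cssd <- "results/css"
out <- "results/enrichment"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

css <- read_css(file.path(cssd, "css.tsv"))
genes <- read_gtf(file.path(ind, "genes.gtf"))
qtl <- read_qtl_gff(file.path(ind, "qtl.gff3"))
annotation <- read.delim(file.path(ind, "gene_terms.tsv"))

prod <- css[css$classification == "prodCSS", ]
adap <- css[css$classification == "adapCSS", ]

ov <- list(gene_prod = annotate_features(prod, genes, "gene"),
           gene_adap = annotate_features(adap, genes, "gene"),
           qtl_prod = annotate_features(prod, qtl, "qtl"),
           qtl_adap = annotate_features(adap, qtl, "qtl"))
for (nm in names(ov)) {
  write.table(ov[[nm]], file.path(out, paste0("overlaps_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

sets <- partition_genes(ov$gene_prod, ov$gene_adap)
cat("genes within prodCSS:", length(unique(ov$gene_prod$feature_id)),
    "| within adapCSS:", length(unique(ov$gene_adap$feature_id)),
    "| shared:", length(sets$shared), "\n")

for (cl in c("prod", "adap")) {
  ty <- summarize_qtl_types(ov[[paste0("qtl_", cl)]], qtl)
  write.table(ty, file.path(out, paste0("qtl_types_", cl, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (nrow(ty)) {
    cat("most frequent QTL class in", cl, "CSS:", ty$qtl_type[1],
        sprintf("(%.2f%%)\n", ty$percentage[1]))
  }
}

enr_qtl <- list(prod = qtl_enrich(ov$qtl_prod, qtl),
                adap = qtl_enrich(ov$qtl_adap, qtl))
venn <- intersect_enrichments(enr_qtl$prod, enr_qtl$adap)
cat("enriched QTL traits: prod", sum(enr_qtl$prod$passes),
    "| adap", sum(enr_qtl$adap$passes),
    "| shared", length(venn$shared), "\n")

enr_go <- lapply(sets, function(gs) {
  go_enrich(gs, annotation, genes$gene_id)
})
for (nm in names(enr_qtl)) {
  write.table(enr_qtl[[nm]],
              file.path(out, paste0("qtl_enrichment_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
for (nm in names(enr_go)) {
  write.table(enr_go[[nm]],
              file.path(out, paste0("go_enrichment_", nm, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat("enriched GO terms for", nm, "genes:", sum(enr_go[[nm]]$passes),
      "\n")
}
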