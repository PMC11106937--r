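# Seeded generators for every input the pipeline consumes, with planted
# ground truth for recovery testing. A single master seed is fanned out to
# per-generator streams by fixed offsets so one integer reproduces the
# whole corpus. All seeds stay below 2^31 - 1.

derive_seed <- function(seed, offset) {
  (as.integer(seed) + 7919L * as.integer(offset)) %% 2147483647L
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic genome layout
#'
#' Chromosome lengths are drawn uniformly within +/-20% of `mean_length`.
#' Deterministic per seed.
#'
#' @param n_chrom Number of chromosomes (default 3).
#' @param mean_length Mean chromosome length, bp (default 1e7).
#' @param seed Integer seed.
#' @return A `genome_layout`.
#' @export
generate_genome <- function(n_chrom = 3, mean_length = 1e7, seed = 1) {
  if (n_chrom < 1) stop("n_chrom must be >= 1")
  with_seed(derive_seed(seed, 1L), {
    len <- round(mean_length * stats::runif(n_chrom, 0.8, 1.2))
    genome_layout(paste0("chr", seq_len(n_chrom)), pmax(1, len))
  })
}

#' Plant ground-truth CSS loci on a genome
#'
#' Lays out `n_loci` non-adjacent loci (minimum separation `min_sep`, so
#' marker expansion cannot merge neighbours) and assigns each a
#' production/adaptation study-count mix drawn from a set of designs that
#' keep the implied class fractions at least 0.1 away from the 0.60/0.70
#' classification thresholds and robust to one contaminating background
#' study.
#'
#' @param layout A `genome_layout`.
#' @param n_loci Number of planted loci (default 15).
#' @param locus_width Width of each planted locus, bp (default 2e5).
#' @param min_sep Minimum separation between locus midpoints, bp
#'   (default 1.5e6).
#' @param seed Integer seed.
#' @return `data.frame` with `locus_id`, `chrom`, `start`, `end`,
#'   `n_prod_studies`, `n_adap_studies`, `intended_class`.
#' @export
make_planted_truth <- function(layout, n_loci = 15, locus_width = 2e5,
                               min_sep = 1.5e6, seed = 1) {
  designs <- data.frame(
    n_prod = c(4L, 5L, 0L, 1L, 2L),
    n_adap = c(0L, 1L, 4L, 5L, 2L),
    intended_class = c("prodCSS", "prodCSS", "adapCSS", "adapCSS",
                       "unclassified"),
    stringsAsFactors = FALSE
  )
  # capacity: midpoints on a grid of spacing min_sep, clear of chromosome
  # ends by locus_width
  slots <- lapply(seq_len(nrow(layout)), function(i) {
    lo <- locus_width; hi <- layout$length[i] - locus_width
    if (hi <= lo) return(NULL)
    mids <- seq(lo, hi, by = min_sep)
    data.frame(chrom = layout$chrom[i], mid = mids,
               stringsAsFactors = FALSE)
  })
  slots <- do.call(rbind, slots)
  if (is.null(slots) || nrow(slots) < n_loci) {
    stop("genome too small for ", n_loci, " loci at separation ", min_sep)
  }
  with_seed(derive_seed(seed, 2L), {
    pick <- slots[sort(sample.int(nrow(slots), n_loci)), , drop = FALSE]
    d <- designs[sample(rep_len(seq_len(nrow(designs)), n_loci)), ,
                 drop = FALSE]
    out <- data.frame(
      locus_id = sprintf("L%03d", seq_len(n_loci)),
      chrom = pick$chrom,
      start = round(pick$mid - locus_width / 2),
      end = round(pick$mid + locus_width / 2),
      n_prod_studies = d$n_prod,
      n_adap_studies = d$n_adap,
      intended_class = d$intended_class,
      stringsAsFactors = FALSE
    )
    rownames(out) <- NULL
    out
  })
}

#' Generate a multi-study sweep table with planted CSS loci
#'
#' Each planted locus receives sweeps from its prescribed numbers of
#' production and adaptation studies, with endpoints jittered uniformly by
#' up to `jitter` bp. Background sweeps are added at a total density of
#' `background_rate` sweeps per Mb across the whole catalog
#' (Poisson-distributed count, uniform placement, random study). A
#' `marker_fraction` share of records is emitted as single-marker reports.
#'
#' @param layout A `genome_layout`.
#' @param truth Planted truth from [make_planted_truth()].
#' @param n_prod,n_adap Numbers of production/adaptation studies
#'   (defaults 15 and 23, the catalog composition the pipeline is sized
#'   for).
#' @param background_rate Background sweeps per Mb, catalog-wide
#'   (default 0.1).
#' @param jitter Maximum endpoint jitter, bp (default 5e4).
#' @param marker_fraction Fraction of records reported as markers
#'   (default 0).
#' @param seed Integer seed.
#' @param path Optional path; when given, the table is written as TSV.
#' @return The sweep table `data.frame` (`study_id`, `study_class`,
#'   `chrom`, `start`, `end`, `marker_pos`, `origin`), invisibly carrying
#'   `path` in attribute `path` when written.
#' @export
generate_sweep_studies <- function(layout, truth, n_prod = 15, n_adap = 23,
                                   background_rate = 0.1, jitter = 5e4,
                                   marker_fraction = 0, seed = 1,
                                   path = NULL) {
  if (n_prod < 1 || n_adap < 1) stop("study counts must be positive")
  if (background_rate < 0) stop("background_rate must be >= 0")
  if (any(truth$n_prod_studies > n_prod) ||
      any(truth$n_adap_studies > n_adap)) {
    stop("planted study counts exceed available studies")
  }
  lens <- chrom_length(layout, truth$chrom)
  if (any(truth$start < 1 | truth$end > lens)) {
    stop("planted locus outside chromosome bounds")
  }
  prod_ids <- sprintf("P%02d", seq_len(n_prod))
  adap_ids <- sprintf("A%02d", seq_len(n_adap))
  with_seed(derive_seed(seed, 3L), {
    rows <- list()
    for (i in seq_len(nrow(truth))) {
      st <- c(sample(prod_ids, truth$n_prod_studies[i]),
              sample(adap_ids, truth$n_adap_studies[i]))
      cl <- c(rep("production", truth$n_prod_studies[i]),
              rep("adaptation", truth$n_adap_studies[i]))
      n <- length(st)
      if (n == 0) next
      s <- truth$start[i] + round(stats::runif(n, -jitter, jitter))
      e <- truth$end[i] + round(stats::runif(n, -jitter, jitter))
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = st, study_class = cl, chrom = truth$chrom[i],
        start = pmax(1, s), end = pmin(chrom_length(layout, truth$chrom[i]), e),
        origin = truth$locus_id[i], stringsAsFactors = FALSE
      )
    }
    genome_mb <- sum(layout$length) / 1e6
    n_bg <- stats::rpois(1, background_rate * genome_mb)
    if (n_bg > 0) {
      bg_chrom <- sample(layout$chrom, n_bg, replace = TRUE,
                         prob = layout$length)
      bg_len <- round(stats::runif(n_bg, 5e4, 3e5))
      bg_start <- vapply(seq_len(n_bg), function(j) {
        L <- chrom_length(layout, bg_chrom[j])
        sample.int(max(1, L - bg_len[j]), 1)
      }, numeric(1))
      bg_study <- sample(c(prod_ids, adap_ids), n_bg, replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        study_id = bg_study,
        study_class = ifelse(startsWith(bg_study, "P"),
                             "production", "adaptation"),
        chrom = bg_chrom, start = bg_start,
        end = pmin(chrom_length(layout, bg_chrom), bg_start + bg_len),
        origin = "background", stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    # guarantee both classes appear so the catalog always has two study
    # vocabularies represented
    tab$marker_pos <- NA_real_
    if (marker_fraction > 0 && nrow(tab) > 0) {
      as_marker <- stats::runif(nrow(tab)) < marker_fraction
      mid <- round((tab$start + tab$end) / 2)
      tab$marker_pos[as_marker] <- mid[as_marker]
      tab$start[as_marker] <- NA_real_
      tab$end[as_marker] <- NA_real_
    }
    o <- order(tab$chrom, ifelse(is.na(tab$start), tab$marker_pos,
                                 tab$start), tab$study_id)
    tab <- tab[o, , drop = FALSE]
    rownames(tab) <- NULL
    if (!is.null(path)) {
      utils::write.table(tab, path, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
    tab
  })
}

#' Generate a synthetic gene annotation GTF
#'
#' `n_genes` genes with uniform-random starts, lengths 2-50 kb (clamped to
#' chromosome bounds), written as `gene` feature rows with `gene_id`,
#' `gene_name` and `gene_biotype` attributes. Byte-identical per seed.
#'
#' @param layout A `genome_layout`.
#' @param n_genes Number of genes (default 500).
#' @param seed Integer seed.
#' @param path Output GTF path.
#' @return `path`, invisibly; the gene table as the return attribute
#'   `genes`.
#' @export
generate_gene_annotation <- function(layout, n_genes = 500, seed = 1,
                                     path) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  with_seed(derive_seed(seed, 4L), {
    chrom <- sample(layout$chrom, n_genes, replace = TRUE,
                    prob = layout$length)
    len <- round(stats::runif(n_genes, 2e3, 5e4))
    L <- chrom_length(layout, chrom)
    start <- floor(stats::runif(n_genes, 1, pmax(2, L - len)))
    end <- pmin(L, start + len)
    genes <- data.frame(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      chrom = chrom, start = start, end = end,
      stringsAsFactors = FALSE
    )
    genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ,
                   drop = FALSE]
    lines <- sprintf(
      paste0("%s\tsynthetic\tgene\t%d\t%d\t.\t+\t.\t",
             "gene_id \"%s\"; gene_name \"%s\"; gene_biotype \"protein_coding\";"),
      genes$chrom, genes$start, genes$end, genes$gene_id, genes$gene_id
    )
    writeLines(lines, path)
    out <- invisible(path)
    attr(out, "genes") <- genes
    out
  })
}

#' Generate a synthetic QTLdb-style GFF3 QTL database
#'
#' Background records are placed uniformly with traits sampled evenly from
#' `trait_catalog`. For each trait in `enriched_traits`, extra records are
#' planted uniformly inside the truth loci so that the trait's density
#' within loci is `density_multiplier` times its genome-wide background
#' density.
#'
#' @param layout A `genome_layout`.
#' @param trait_catalog `data.frame` with `trait_name`, `qtl_type`.
#' @param truth Planted truth (loci define where enrichment is planted);
#'   may be `NULL` when `enriched_traits` is empty.
#' @param enriched_traits Character vector of trait names (subset of the
#'   catalog) to plant as enriched.
#' @param density_multiplier In-locus density multiple (default 10).
#' @param n_records Background record count (default 400).
#' @param seed Integer seed.
#' @param path Output GFF3 path.
#' @return `path`, invisibly; the record table as attribute `records`.
#' @export
generate_qtl_db <- function(layout, trait_catalog, truth = NULL,
                            enriched_traits = character(0),
                            density_multiplier = 10, n_records = 400,
                            seed = 1, path) {
  if (n_records < nrow(trait_catalog)) {
    stop("n_records must be at least the trait count")
  }
  if (length(enriched_traits) &&
      !all(enriched_traits %in% trait_catalog$trait_name)) {
    stop("enriched traits must come from the trait catalog")
  }
  with_seed(derive_seed(seed, 5L), {
    qlen <- function(n) round(stats::runif(n, 1e4, 2e5))
    place_uniform <- function(n) {
      chrom <- sample(layout$chrom, n, replace = TRUE, prob = layout$length)
      len <- qlen(n)
      L <- chrom_length(layout, chrom)
      start <- floor(stats::runif(n, 1, pmax(2, L - len)))
      data.frame(chrom = chrom, start = start, end = pmin(L, start + len),
                 stringsAsFactors = FALSE)
    }
    traits <- trait_catalog$trait_name[
      rep_len(seq_len(nrow(trait_catalog)), n_records)]
    bg <- place_uniform(n_records)
    bg$trait_name <- sample(traits)  # shuffle trait-to-position pairing
    parts <- list(bg)
    if (length(enriched_traits)) {
      if (is.null(truth) || nrow(truth) == 0) {
        stop("planting enriched traits requires truth loci")
      }
      loci_bp <- sum(truth$end - truth$start + 1)
      frac <- loci_bp / sum(layout$length)
      for (tr in enriched_traits) {
        base_k <- sum(bg$trait_name == tr)
        n_extra <- max(1, round((density_multiplier - 1) * base_k * frac))
        li <- sample.int(nrow(truth), n_extra, replace = TRUE,
                         prob = truth$end - truth$start + 1)
        len <- qlen(n_extra)
        start <- floor(stats::runif(n_extra, truth$start[li],
                                    pmax(truth$start[li] + 1,
                                         truth$end[li] - len)))
        ext <- data.frame(chrom = truth$chrom[li], start = start,
                          end = pmin(chrom_length(layout, truth$chrom[li]),
                                     start + len),
                          trait_name = tr, stringsAsFactors = FALSE)
        parts[[length(parts) + 1L]] <- ext
      }
    }
    rec <- do.call(rbind, parts)
    rec$qtl_type <- trait_catalog$qtl_type[
      match(rec$trait_name, trait_catalog$trait_name)]
    rec <- rec[order(rec$chrom, rec$start, rec$trait_name), , drop = FALSE]
    rec$qtl_id <- sprintf("QTL%05d", seq_len(nrow(rec)))
    rownames(rec) <- NULL
    lines <- c("##gff-version 3",
               sprintf("%s\tQTLdb\tQTL\t%d\t%d\t.\t.\t.\tID=%s;Name=%s;trait_type=%s",
                       rec$chrom, rec$start, rec$end, rec$qtl_id,
                       gsub("[;=]", "_", rec$trait_name),
                       gsub("[;=]", "_", rec$qtl_type)))
    writeLines(lines, path)
    out <- invisible(path)
    attr(out, "records") <- rec
    out
  })
}

#' Generate a synthetic GO DAG and gene-term annotation table
#'
#' Builds an acyclic ontology of `n_terms` terms arranged in `depth`
#' levels below a single root per namespace (BP only by default): each
#' term gets one or two parents from the level above, mostly `is_a` with
#' occasional `part_of`. Genes receive random leaf-term assignments; each
#' term in `enriched_terms` is additionally assigned to
#' `target_gene_fraction` of its own random `term_scope_fraction` slice of
#' the designated `target_genes` (enriched terms in real annotation sets
#' cover different, partially overlapping gene subsets) while staying rare
#' (about 5%) in the rest of the universe.
#'
#' @param genes Character vector: the gene universe.
#' @param n_terms Number of non-root terms (default 60).
#' @param depth DAG depth below the root (default 4).
#' @param target_genes Genes forming the planted selection set.
#' @param enriched_terms Term ids (within `T0001..`) to plant; default
#'   none.
#' @param target_gene_fraction Assignment rate within a term's target
#'   slice (default 0.8).
#' @param term_scope_fraction Share of `target_genes` each enriched term
#'   can cover; 1 gives every term the whole target set (default 0.65).
#' @param background_rate Assignment rate among remaining genes
#'   (default 0.05).
#' @param seed Integer seed.
#' @param obo_path Output OBO path.
#' @param tsv_path Output gene-term TSV path.
#' @return `list(obo = obo_path, annotation = tsv_path)`, invisibly; the
#'   graph and annotation as attributes `graph` and `annotation`.
#' @export
generate_go <- function(genes, n_terms = 60, depth = 4,
                        target_genes = character(0),
                        enriched_terms = character(0),
                        target_gene_fraction = 0.8,
                        term_scope_fraction = 0.65,
                        background_rate = 0.05, seed = 1,
                        obo_path, tsv_path) {
  if (n_terms < depth) stop("need at least one term per level")
  with_seed(derive_seed(seed, 6L), {
    ids <- sprintf("T%04d", seq_len(n_terms))
    level <- sort(rep_len(seq_len(depth), n_terms))
    root <- "T0000"
    terms <- data.frame(term_id = c(root, ids),
                        name = c("root process",
                                 paste("process", seq_len(n_terms))),
                        namespace = "BP", stringsAsFactors = FALSE)
    edges <- list()
    for (i in seq_len(n_terms)) {
      pool <- if (level[i] == 1) root else ids[level == level[i] - 1]
      n_par <- min(length(pool), sample(1:2, 1, prob = c(0.7, 0.3)))
      pars <- sample(pool, n_par)
      rel <- sample(c("is_a", "part_of"), n_par, replace = TRUE,
                    prob = c(0.85, 0.15))
      edges[[i]] <- data.frame(child = ids[i], parent = pars,
                               relation = rel, stringsAsFactors = FALSE)
    }
    edges <- do.call(rbind, edges)
    graph <- term_graph(terms, edges)

    leaf_ids <- ids[level == depth]
    ann <- list()
    for (g in genes) {
      n_assign <- sample(1:4, 1)
      ann[[g]] <- data.frame(gene_id = g,
                             term_id = sample(leaf_ids,
                                              min(n_assign,
                                                  length(leaf_ids))),
                             stringsAsFactors = FALSE)
    }
    ann <- do.call(rbind, ann)
    for (tt in enriched_terms) {
      if (!tt %in% terms$term_id) stop("unknown enriched term: ", tt)
      scope <- target_genes[stats::runif(length(target_genes)) <
                              term_scope_fraction]
      hit_t <- scope[stats::runif(length(scope)) < target_gene_fraction]
      rest <- setdiff(genes, target_genes)
      hit_b <- rest[stats::runif(length(rest)) < background_rate]
      if (length(c(hit_t, hit_b))) {
        ann <- rbind(ann, data.frame(gene_id = c(hit_t, hit_b),
                                     term_id = tt,
                                     stringsAsFactors = FALSE))
      }
    }
    ann <- unique(ann)
    ann <- ann[order(ann$gene_id, ann$term_id), , drop = FALSE]
    rownames(ann) <- NULL

    write_obo(graph, obo_path)
    utils::write.table(ann, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out <- invisible(list(obo = obo_path, annotation = tsv_path))
    attr(out, "graph") <- graph
    attr(out, "annotation") <- ann
    out
  })
}

# serialize a term_graph as OBO 1.2
write_obo <- function(graph, path) {
  ns_long <- c(BP = "biological_process", MF = "molecular_function",
               CC = "cellular_component")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$terms))) {
    id <- graph$terms$term_id[i]
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    lines <- c("[Term]",
               paste0("id: ", id),
               paste0("name: ", graph$terms$name[i]),
               paste0("namespace: ", ns_long[graph$terms$namespace[i]]))
    if (nrow(e)) {
      ia <- e$parent[e$relation == "is_a"]
      po <- e$parent[e$relation == "part_of"]
      lines <- c(lines,
                 if (length(ia)) paste0("is_a: ", ia),
                 if (length(po)) paste0("relationship: part_of ", po))
    }
    writeLines(c(lines, ""), con)
  }
  invisible(path)
}

#' Default synthetic trait catalog
#'
#' Trait names grouped into the QTL classes used by sheep QTL databases.
#'
#' @param n_traits Number of traits (default 24).
#' @return `data.frame` with `trait_name`, `qtl_type`.
#' @export
default_trait_catalog <- function(n_traits = 24) {
  types <- c("Production", "Meat_and_Carcass", "Milk", "Reproduction",
             "Wool", "Health", "Exterior")
  ty <- rep_len(types, n_traits)
  data.frame(trait_name = paste0("trait_", sprintf("%02d", seq_len(n_traits))),
             qtl_type = ty, stringsAsFactors = FALSE)
}

#' Generate a complete synthetic input bundle
#'
#' Writes every file the pipeline consumes into `dir`: `genome.tsv`,
#' `sweeps.tsv`, `genes.gtf`, `qtl.gff3`, `go.obo`, `gene_terms.tsv` and
#' `truth.json` (the planted ground truth). All files are synthetic and
#' deterministic for a given `seed`.
#'
#' @param dir Output directory (created if absent).
#' @param seed Master integer seed.
#' @param n_chrom,mean_length Genome dimensions.
#' @param n_loci Planted CSS loci.
#' @param n_prod,n_adap Study counts (defaults 15 production /
#'   23 adaptation).
#' @param background_rate Background sweeps per Mb (default 0.1).
#' @param jitter Sweep endpoint jitter, bp (default 5e4).
#' @param marker_fraction Fraction of marker-style sweep reports
#'   (default 0.1).
#' @param n_genes,n_records,n_terms Annotation sizes.
#' @param n_enriched_traits Number of planted enriched traits (default 1).
#' @param n_enriched_terms Number of planted enriched GO terms
#'   (default 6; several terms over partially overlapping target slices give the
#'   gene-term network bridging genes, as in real enrichment output).
#' @return Named list of file paths plus the `truth` table, invisibly.
#' @export
simulate_bundle <- function(dir, seed = 1, n_chrom = 3, mean_length = 1e7,
                            n_loci = 15, n_prod = 15, n_adap = 23,
                            background_rate = 0.1, jitter = 5e4,
                            marker_fraction = 0.1, n_genes = 500,
                            n_records = 400, n_terms = 60,
                            n_enriched_traits = 1, n_enriched_terms = 6) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(dir, "genome.tsv"),
    sweeps = file.path(dir, "sweeps.tsv"),
    gtf = file.path(dir, "genes.gtf"),
    qtl_gff = file.path(dir, "qtl.gff3"),
    obo = file.path(dir, "go.obo"),
    gene_terms = file.path(dir, "gene_terms.tsv"),
    truth_json = file.path(dir, "truth.json")
  )
  layout <- generate_genome(n_chrom, mean_length, seed = seed)
  write_genome(layout, paths$genome)
  truth <- make_planted_truth(layout, n_loci = n_loci, seed = seed)
  generate_sweep_studies(layout, truth, n_prod = n_prod, n_adap = n_adap,
                         background_rate = background_rate,
                         jitter = jitter,
                         marker_fraction = marker_fraction, seed = seed,
                         path = paths$sweeps)
  g <- generate_gene_annotation(layout, n_genes = n_genes, seed = seed,
                                path = paths$gtf)
  genes <- attr(g, "genes")
  catalog <- default_trait_catalog()
  enriched_traits <- utils::head(catalog$trait_name, n_enriched_traits)
  generate_qtl_db(layout, catalog, truth = truth,
                  enriched_traits = enriched_traits,
                  n_records = n_records, seed = seed, path = paths$qtl_gff)
  # planted GO selection: genes inside truth loci
  hit <- GenomicRanges::findOverlaps(
    as_granges(genes), as_granges(truth))
  target_genes <- unique(genes$gene_id[S4Vectors::queryHits(hit)])
  enriched_terms <- if (n_enriched_terms > 0) {
    sprintf("T%04d", seq(n_terms, by = -1, length.out = n_enriched_terms))
  } else character(0)
  generate_go(genes$gene_id, n_terms = n_terms,
              target_genes = target_genes,
              enriched_terms = enriched_terms, seed = seed,
              obo_path = paths$obo, tsv_path = paths$gene_terms)
  truth_out <- list(loci = truth, enriched_traits = enriched_traits,
                    enriched_terms = enriched_terms,
                    target_genes = target_genes)
  jsonlite::write_json(truth_out, paths$truth_json, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(paths, list(truth = truth, layout = layout)))
}
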