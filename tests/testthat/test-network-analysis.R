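test_that("gene-term networks are bipartite with set-semantics edges", {
  pairs <- data.frame(gene = rep(c("g1", "g2", "g3"), each = 2),
                      term = rep(c("t1", "t2"), 3))
  g <- build_gene_term_network(pairs)
  expect_equal(igraph::ecount(g), 6)
  expect_equal(igraph::vcount(g), 5)
  # duplicate pair collapses to one edge
  g2 <- build_gene_term_network(rbind(pairs, pairs[1, ]))
  expect_equal(igraph::ecount(g2), 6)
  expect_setequal(igraph::V(g)$side[igraph::V(g)$name %in% pairs$gene],
                  "gene")
})

test_that("betweenness: path, star and complete-graph hand cases", {
  path3 <- build_gene_term_network(
    data.frame(gene = c("A", "C"), term = c("B", "B")))
  sc <- betweenness_scores(path3)
  expect_equal(sc[["B"]], 1)
  expect_equal(sc[["A"]], 0)
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("c", "l1", "l2", "l3")
  expect_equal(betweenness_scores(star)[["c"]], 3)
  k4 <- igraph::make_full_graph(4)
  igraph::V(k4)$name <- letters[1:4]
  expect_true(all(betweenness_scores(k4) == 0))
})

test_that("betweenness matches BFS path enumeration on random graphs", {
  set.seed(909)
  for (rep in 1:40) {
    n <- sample(5:25, 1)
    nodes <- sprintf("n%02d", seq_len(n))
    m <- sample(n:(2 * n), 1)
    edges <- unique(data.frame(
      from = nodes[sample.int(n, m, replace = TRUE)],
      to = nodes[sample.int(n, m, replace = TRUE)]))
    edges <- edges[edges$from != edges$to, , drop = FALSE]
    if (nrow(edges) == 0) next
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = nodes)
    got <- betweenness_scores(g)
    want <- oracle_betweenness(edges, nodes)
    expect_equal(got[nodes], want[nodes], tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("hub selection thresholds at the type-7 quantile, strictly above", {
  scores <- stats::setNames(as.numeric(1:10), paste0("v", 1:10))
  hub <- select_hubs(scores, quantile = 0.90)
  expect_equal(hub$quantile_threshold, 9.1)  # h = (n-1)q + 1 interpolation
  expect_equal(hub$hubs, "v10")
  # ties at the threshold are excluded (strict >)
  flat <- stats::setNames(rep(5, 8), paste0("f", 1:8))
  expect_length(select_hubs(flat)$hubs, 0)
  # q = 0: everything above the minimum
  low <- select_hubs(scores, quantile = 0)
  expect_setequal(low$hubs, paste0("v", 2:10))
  expect_error(select_hubs(scores, eligible = character(0)), "empty")
  expect_error(select_hubs(scores, eligible = "nope"), "without scores")
  # monotone: raising the quantile never adds hubs; count bounded
  set.seed(31)
  sc <- stats::setNames(runif(40), sprintf("g%02d", 1:40))
  sizes <- vapply(c(0.5, 0.7, 0.9, 0.95),
                  function(q) length(select_hubs(sc, q)$hubs), integer(1))
  expect_true(all(diff(sizes) <= 0))
  expect_lte(sizes[3], ceiling(0.10 * 40) + sum(duplicated(sc)))
})

test_that("eligibility restricts hubs to the gene side", {
  pairs <- data.frame(gene = c("g1", "g2", "g3", "g1"),
                      term = c("t1", "t1", "t2", "t2"))
  net <- build_gene_term_network(pairs)
  sc <- betweenness_scores(net)
  eligible <- igraph::V(net)$name[igraph::V(net)$side == "gene"]
  hub <- select_hubs(sc, quantile = 0.5, eligible = eligible)
  expect_true(all(hub$hubs %in% c("g1", "g2", "g3")))
})

test_that("gene-QTL networks link via CSS co-occurrence and count traits", {
  qtl_db <- data.frame(qtl_id = c("Q1", "Q2", "Q3"),
                       trait_name = c("tr_a", "tr_b", "tr_c"),
                       qtl_type = c("Health", "Health", "Milk"))
  gene_ov <- data.frame(css_id = c("C1", "C1", "C2"),
                        feature_id = c("G1", "G2", "G3"),
                        feature_kind = "gene", overlap_bp = 1)
  qtl_ov <- data.frame(css_id = c("C1", "C1", "C2"),
                       feature_id = c("Q1", "Q2", "Q3"),
                       feature_kind = "qtl", overlap_bp = 1)
  # G1 shares CSS C1 with Q1 (tr_a) and Q2 (tr_b), both Health
  tr <- build_gene_qtl_network(c("G1", "G2", "G3"), gene_ov, qtl_ov,
                               qtl_db, c("tr_a", "tr_b", "tr_c"),
                               level = "trait")
  expect_equal(igraph::ecount(tr), 5)  # G1-a, G1-b, G2-a, G2-b, G3-c
  ty <- build_gene_qtl_network(c("G1", "G2", "G3"), gene_ov, qtl_ov,
                               qtl_db, c("tr_a", "tr_b", "tr_c"),
                               level = "type")
  el <- igraph::as_data_frame(ty)
  g1h <- el[el$from == "G1" & el$to == "Health" |
              el$to == "G1" & el$from == "Health", ]
  expect_equal(g1h$weight, 2)  # two distinct Health traits
  # non-enriched traits form no edges
  only_a <- build_gene_qtl_network(c("G1", "G2", "G3"), gene_ov, qtl_ov,
                                   qtl_db, "tr_a", level = "trait")
  expect_false("tr_b" %in% igraph::V(only_a)$name)
  # weights at type level conserve distinct trait-level edges
  expect_equal(sum(el$weight), igraph::ecount(tr))
})

test_that("type-level weights equal group-by recounts on random fixtures", {
  set.seed(1010)
  for (rep in 1:10) {
    n_css <- 6; n_genes <- 8; n_qtl <- 30
    types <- c("Health", "Milk", "Wool")
    qtl_db <- data.frame(
      qtl_id = sprintf("Q%02d", 1:n_qtl),
      trait_name = sprintf("tr%02d", sample.int(12, n_qtl, replace = TRUE)),
      qtl_type = NA)
    qtl_db$qtl_type <- types[as.integer(factor(qtl_db$trait_name)) %% 3 + 1]
    gene_ov <- data.frame(
      css_id = sprintf("C%d", sample.int(n_css, 20, replace = TRUE)),
      feature_id = sprintf("G%d", sample.int(n_genes, 20, replace = TRUE)))
    qtl_ov <- data.frame(
      css_id = sprintf("C%d", sample.int(n_css, 25, replace = TRUE)),
      feature_id = sample(qtl_db$qtl_id, 25, replace = TRUE))
    genes <- unique(gene_ov$feature_id)
    enr <- unique(qtl_db$trait_name)
    tr <- build_gene_qtl_network(genes, gene_ov, qtl_ov, qtl_db, enr,
                                 level = "trait")
    ty <- build_gene_qtl_network(genes, gene_ov, qtl_ov, qtl_db, enr,
                                 level = "type")
    el_tr <- igraph::as_data_frame(tr)
    el_ty <- igraph::as_data_frame(ty)
    expect_equal(sum(el_ty$weight), nrow(el_tr))
  }
})

test_that("network exports round-trip through GraphML and edge lists", {
  pairs <- data.frame(gene = c("g1", "g2", "g3"),
                      term = c("t1", "t1", "t2"))
  net <- build_gene_term_network(pairs)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- read_network(gml, "graphml")
  expect_equal(igraph::vcount(back), 5)
  expect_setequal(igraph::V(back)$name, igraph::V(net)$name)
  el_path <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, el_path, "edgelist_tsv")
  back2 <- read_network(el_path, "edgelist_tsv")
  norm <- function(g) {
    e <- igraph::as_data_frame(g)
    sort(paste(pmin(e$from, e$to), pmax(e$from, e$to)))
  }
  expect_equal(norm(back2), norm(net))
  # empty network still serialises
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  export_network(empty, gml, "graphml")
  expect_equal(igraph::vcount(read_network(gml, "graphml")), 0)
})
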