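# Independent brute-force oracles. These deliberately avoid the code paths
# (and libraries) they are used to check.

# connected components of the pairwise-overlap graph via union-find over
# all sweep pairs
oracle_cluster <- function(sweeps, min_overlap_bp = 1) {
  n <- nrow(sweeps)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (sweeps$chrom[i] != sweeps$chrom[j]) next
        ov <- min(sweeps$end[i], sweeps$end[j]) -
          max(sweeps$start[i], sweeps$start[j]) + 1
        if (ov >= min_overlap_bp) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), sweeps$sweep_id)
}

# unnormalised betweenness by explicit enumeration of all shortest paths:
# BFS from each source, then DFS back-tracking over the shortest-path DAG
# to list every geodesic, crediting interior nodes
oracle_betweenness <- function(edges, nodes) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(edges$to[edges$from == v], edges$from[edges$to == v])
  })
  score <- stats::setNames(numeric(length(nodes)), nodes)
  bfs <- function(s) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    q <- s
    while (length(q)) {
      v <- q[1]; q <- q[-1]
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1; q <- c(q, w) }
      }
    }
    dist
  }
  all_paths <- function(s, t, dist) {
    # every geodesic from s to t, walking backwards from t
    if (is.infinite(dist[t])) return(list())
    walk <- function(v) {
      if (v == s) return(list(s))
      preds <- adj[[v]][dist[adj[[v]]] == dist[v] - 1]
      out <- list()
      for (p in preds) {
        for (pp in walk(p)) out[[length(out) + 1]] <- c(pp, v)
      }
      out
    }
    walk(t)
  }
  for (si in seq_along(nodes)) {
    s <- nodes[si]
    dist <- bfs(s)
    for (ti in seq_along(nodes)) {
      if (ti <= si) next
      t <- nodes[ti]
      paths <- all_paths(s, t, dist)
      if (!length(paths)) next
      for (p in paths) {
        interior <- setdiff(p, c(s, t))
        if (length(interior)) {
          score[interior] <- score[interior] + 1 / length(paths)
        }
      }
    }
  }
  score
}

# upper-tail hypergeometric by term-wise enumeration over the support
oracle_hyper_upper <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Wang S-values by explicit enumeration of every child->ancestor path
oracle_wang_svalues <- function(term, graph) {
  w <- graph$relation_weights
  paths_up <- function(v, acc) {
    out <- list(list(node = v, weight = acc))
    e <- graph$edges[graph$edges$child == v, , drop = FALSE]
    for (i in seq_len(nrow(e))) {
      out <- c(out, paths_up(e$parent[i], acc * w[[e$relation[i]]]))
    }
    out
  }
  all <- paths_up(term, 1)
  nodes <- vapply(all, `[[`, character(1), "node")
  wts <- vapply(all, `[[`, numeric(1), "weight")
  tapply(wts, nodes, max)
}

# a random DAG in one namespace: levelled, every non-root points to >= 1
# node of an earlier level
random_term_graph <- function(n_terms, n_levels = 3) {
  ids <- sprintf("R%03d", seq_len(n_terms))
  lev <- sort(rep_len(seq_len(n_levels), n_terms))
  edges <- list()
  for (i in which(lev > 1)) {
    pool <- ids[lev < lev[i]]
    pars <- sample(pool, min(length(pool), sample(1:2, 1)))
    edges[[length(edges) + 1]] <- data.frame(
      child = ids[i], parent = pars,
      relation = sample(c("is_a", "part_of"), length(pars), replace = TRUE),
      stringsAsFactors = FALSE)
  }
  term_graph(
    data.frame(term_id = ids, name = ids, namespace = "BP",
               stringsAsFactors = FALSE),
    if (length(edges)) do.call(rbind, edges) else
      data.frame(child = character(0), parent = character(0),
                 relation = character(0))
  )
}

# a catalog built directly from an in-memory sweep table
make_catalog <- function(sweeps, layout) {
  sweeps$sweep_id <- sprintf("SW%05d", seq_len(nrow(sweeps)))
  sweeps$source_kind <- "interval"
  studies <- unique(sweeps[, c("study_id", "study_class")])
  structure(list(studies = studies, sweeps = sweeps, layout = layout),
            class = "sweep_catalog")
}

# random sweep catalog for property tests
random_catalog <- function(n_sweeps, layout, n_studies = 6) {
  ids <- c(sprintf("P%02d", seq_len(ceiling(n_studies / 2))),
           sprintf("A%02d", seq_len(floor(n_studies / 2))))
  chrom <- sample(layout$chrom, n_sweeps, replace = TRUE)
  L <- layout$length[match(chrom, layout$chrom)]
  start <- floor(runif(n_sweeps, 1, L * 0.9))
  len <- floor(runif(n_sweeps, 1e4, L * 0.2))
  sw <- data.frame(
    study_id = sample(ids, n_sweeps, replace = TRUE),
    chrom = chrom, start = start, end = pmin(L, start + len),
    stringsAsFactors = FALSE)
  sw$study_class <- ifelse(startsWith(sw$study_id, "P"),
                           "production", "adaptation")
  make_catalog(sw, layout)
}

tiny_layout <- function() genome_layout(c("chr1", "chr2"), c(1e7, 8e6))
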