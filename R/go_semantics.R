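NAMESPACE_MAP <- c(biological_process = "BP", molecular_function = "MF",
                   cellular_component = "CC", BP = "BP", MF = "MF",
                   CC = "CC")

#' Build a GO term graph
#'
#' @param terms `data.frame` with `term_id`, `name`, `namespace` (BP, MF
#'   or CC).
#' @param edges `data.frame` with `child`, `parent`, `relation` (`is_a` or
#'   `part_of`).
#' @param relation_weights Named contribution factors in (0, 1); defaults
#'   to the canonical Wang constants `is_a = 0.8`, `part_of = 0.6`.
#' @return A `term_graph` list with `terms`, `edges`, `relation_weights`,
#'   and a child-indexed adjacency for S-value propagation.
#' @export
term_graph <- function(terms, edges,
                       relation_weights = c(is_a = 0.8, part_of = 0.6)) {
  terms$term_id <- as.character(terms$term_id)
  if (anyDuplicated(terms$term_id)) stop("duplicate term ids")
  if (!all(terms$namespace %in% c("BP", "MF", "CC"))) {
    stop("namespaces must be BP, MF or CC")
  }
  if (nrow(edges)) {
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
    miss <- setdiff(c(edges$child, edges$parent), terms$term_id)
    if (length(miss)) {
      stop("edge endpoints not in term set: ",
           paste(utils::head(miss, 5), collapse = ", "))
    }
    if (!all(edges$relation %in% names(relation_weights))) {
      stop("edge relations must be one of: ",
           paste(names(relation_weights), collapse = ", "))
    }
  }
  if (any(relation_weights <= 0 | relation_weights >= 1)) {
    stop("relation weights must lie strictly in (0, 1)")
  }
  g <- structure(list(terms = terms, edges = edges,
                      relation_weights = relation_weights),
                 class = "term_graph")
  cyc <- find_cycle_member(g)
  if (!is.null(cyc)) stop("term graph contains a cycle through ", cyc)
  g
}

# returns a member term of some cycle, or NULL if the graph is acyclic
# (Kahn's algorithm)
find_cycle_member <- function(graph) {
  ids <- graph$terms$term_id
  if (nrow(graph$edges) == 0) return(NULL)
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(graph$edges$parent)
  indeg[names(tab)] <- as.integer(tab)
  kids <- split(graph$edges$parent, graph$edges$child)
  queue <- names(indeg)[indeg == 0]
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
    for (p in kids[[v]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen < length(ids)) names(indeg)[indeg > 0][1] else NULL
}

#' Parse an OBO ontology file into a term graph
#'
#' Minimal OBO 1.2/1.4 reader: loads every `[Term]` stanza, skips obsolete
#' terms, keeps `is_a` and `relationship: part_of` edges and drops other
#' relationship types (their count is kept in the `n_dropped_edges`
#' attribute). Edges referencing missing/obsolete terms are dropped too.
#'
#' @param path OBO file path.
#' @param relation_weights Passed to [term_graph()].
#' @return A `term_graph`.
#' @export
parse_obo <- function(path, relation_weights = c(is_a = 0.8, part_of = 0.6)) {
  if (!file.exists(path)) stop("OBO file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0) stop("no [Term] stanzas in ", path)
  bounds <- c(grep("^\\[", lines), length(lines) + 1L)
  terms <- list(); edges <- list(); dropped <- 0L
  for (s in stanza_starts) {
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[s:e]
    field <- function(key) {
      hit <- grep(paste0("^", key, ": "), block, value = TRUE)
      sub(paste0("^", key, ": "), "", hit)
    }
    if (any(grepl("^is_obsolete: true", block))) next
    id <- field("id")[1]
    if (is.na(id)) next
    name <- field("name")[1]
    ns <- NAMESPACE_MAP[field("namespace")[1]]
    terms[[id]] <- data.frame(term_id = id,
                              name = if (is.na(name)) id else name,
                              namespace = if (is.na(ns)) "BP" else ns,
                              stringsAsFactors = FALSE)
    for (ia in field("is_a")) {
      parent <- sub(" *!.*$", "", ia)
      edges[[length(edges) + 1L]] <-
        data.frame(child = id, parent = parent, relation = "is_a",
                   stringsAsFactors = FALSE)
    }
    for (rel in field("relationship")) {
      rel <- sub(" *!.*$", "", rel)
      parts <- strsplit(rel, " +")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        edges[[length(edges) + 1L]] <-
          data.frame(child = id, parent = parts[2], relation = "part_of",
                     stringsAsFactors = FALSE)
      } else {
        dropped <- dropped + 1L
      }
    }
  }
  terms <- do.call(rbind, terms)
  edges <- if (length(edges)) do.call(rbind, edges) else {
    data.frame(child = character(0), parent = character(0),
               relation = character(0), stringsAsFactors = FALSE)
  }
  keep <- edges$child %in% terms$term_id & edges$parent %in% terms$term_id
  dropped <- dropped + sum(!keep)
  g <- term_graph(terms, edges[keep, , drop = FALSE],
                  relation_weights = relation_weights)
  attr(g, "n_dropped_edges") <- dropped
  g
}

#' Wang S-values of a term over its ancestors
#'
#' The semantic contribution of a term to itself is 1; walking edges
#' toward the root, each ancestor receives the maximum over paths of the
#' product of relation weights along the path (`is_a` 0.8, `part_of` 0.6
#' by default), so contributions decay with distance.
#'
#' @param term A term id present in the graph.
#' @param graph A `term_graph`.
#' @return Named numeric vector over the term and all its ancestors.
#' @export
wang_svalues <- function(term, graph) {
  if (!term %in% graph$terms$term_id) stop("unknown term: ", term)
  w <- graph$relation_weights[graph$edges$relation]
  s <- stats::setNames(1, term)
  frontier <- term
  # DAG + weights < 1 guarantee convergence of max-product relaxation
  while (length(frontier)) {
    hit <- graph$edges$child %in% frontier
    if (!any(hit)) break
    cand <- s[graph$edges$child[hit]] * w[hit]
    parents <- graph$edges$parent[hit]
    upd <- tapply(cand, parents, max)
    changed <- names(upd)[is.na(s[names(upd)]) | upd > s[names(upd)] + 1e-15]
    s[names(upd)] <- pmax(upd, s[names(upd)], na.rm = TRUE)
    frontier <- changed
  }
  s
}

#' Wang semantic similarity between two GO terms
#'
#' The similarity is the summed S-value mass on the common ancestors
#' (including the terms themselves) relative to the total semantic value
#' of both terms:
#' `sim = sum_a (S_t1(a) + S_t2(a)) / (SV(t1) + SV(t2))` over common
#' `a`, with `SV(t) = sum of all S-values of t`. Symmetric, 1 on identical
#' terms, 0 for terms with no shared ancestry.
#'
#' @param t1,t2 Term ids in the same namespace.
#' @param graph A `term_graph`.
#' @param lenient If `TRUE`, a cross-namespace pair scores 0 instead of
#'   erroring.
#' @return Similarity in `[0, 1]`.
#' @export
wang_similarity <- function(t1, t2, graph, lenient = FALSE) {
  ns <- graph$terms$namespace[match(c(t1, t2), graph$terms$term_id)]
  if (anyNA(ns)) stop("unknown term(s): ",
                      paste(c(t1, t2)[is.na(ns)], collapse = ", "))
  if (ns[1] != ns[2]) {
    if (lenient) return(0)
    stop("cross-namespace similarity is undefined (", ns[1], " vs ",
         ns[2], ")")
  }
  s1 <- wang_svalues(t1, graph)
  s2 <- wang_svalues(t2, graph)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  (sum(s1[common]) + sum(s2[common])) / (sum(s1) + sum(s2))
}

#' Reduce redundant enriched GO terms under shared parents
#'
#' Enriched terms that are pairwise similar (Wang similarity at or above
#' `threshold`) and share a direct parent are grouped; groups are the
#' connected components of the thresholded similarity graph restricted to
#' co-parented pairs, taken within one namespace at a time. Each group is
#' assigned to the direct parent shared by all members (when several
#' qualify: the one with the largest mean similarity to the members,
#' lexicographic tie-break) and carries the smallest member p-value as its
#' representative. Terms joining no group stay as their own singletons.
#'
#' @param enriched `data.frame` with `term_id`, `p_value`.
#' @param graph A `term_graph` containing all enriched terms.
#' @param threshold Pairwise similarity threshold (default 0.7).
#' @return `data.frame` with one row per group: `parent_id`,
#'   `parent_name`, `members` (`;`-joined), `n_members`,
#'   `representative_p`.
#' @export
reduce_terms <- function(enriched, graph, threshold = 0.7) {
  empty <- data.frame(parent_id = character(0), parent_name = character(0),
                      members = character(0), n_members = integer(0),
                      representative_p = numeric(0), stringsAsFactors = FALSE)
  if (nrow(enriched) == 0) return(empty)
  ids <- as.character(enriched$term_id)
  miss <- setdiff(ids, graph$terms$term_id)
  if (length(miss)) stop("enriched term(s) not in graph: ",
                         paste(miss, collapse = ", "))
  p <- stats::setNames(enriched$p_value, ids)
  ns <- graph$terms$namespace[match(ids, graph$terms$term_id)]
  parents_of <- split(graph$edges$parent, graph$edges$child)

  n <- length(ids)
  parent_comp <- seq_len(n)  # union-find over enriched terms
  find <- function(i) { while (parent_comp[i] != i) i <- parent_comp[i]; i }
  sim_cache <- matrix(NA_real_, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        if (ns[i] != ns[j]) next
        share <- length(intersect(parents_of[[ids[i]]],
                                  parents_of[[ids[j]]])) > 0
        if (!share) next
        sim <- wang_similarity(ids[i], ids[j], graph)
        sim_cache[i, j] <- sim_cache[j, i] <- sim
        if (sim >= threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent_comp[rj] <- ri
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), comp)

  rows <- lapply(groups, function(members) {
    mids <- ids[members]
    rep_p <- min(p[mids])
    if (length(members) == 1) {
      pid <- mids
    } else {
      shared_parents <- Reduce(intersect, parents_of[mids])
      if (length(shared_parents) == 0) {
        # no direct parent common to all members: keep the strongest
        # member as the representative of its own group
        pid <- mids[which.min(p[mids])]
      } else if (length(shared_parents) == 1) {
        pid <- shared_parents
      } else {
        mean_sim <- vapply(shared_parents, function(pp) {
          mean(vapply(mids, function(m) wang_similarity(m, pp, graph),
                      numeric(1)))
        }, numeric(1))
        best <- shared_parents[mean_sim == max(mean_sim)]
        pid <- sort(best)[1]
      }
    }
    data.frame(parent_id = pid,
               parent_name = graph$terms$name[match(pid, graph$terms$term_id)],
               members = paste(sort(mids), collapse = ";"),
               n_members = length(mids),
               representative_p = rep_p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$representative_p, out$parent_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
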