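# PPI post-processing: graph construction at the STRING-style confidence
# cutoff, hub scoring (Degree, Maximal Clique Centrality, Edge Percolated
# Component) and MCODE dense-module detection.

#' Build a simple undirected graph from a weighted edge list
#'
#' Edges with `combined_score >= cutoff` (inclusive) are kept; the score is
#' used only for the cutoff and the analysis graph is unweighted thereafter.
#' Endpoints of discarded edges are retained as isolated nodes.
#'
#' @param edges an `edge_list` (or data.frame with the same columns).
#' @param cutoff minimum confidence score, default 0.4.
#' @return An [igraph::igraph] simple undirected graph.
#' @export
build_graph <- function(edges, cutoff = 0.4) {
  nodes <- sort(unique(c(edges$node_a, edges$node_b)))
  keep <- edges$combined_score >= cutoff
  g <- igraph::graph_from_data_frame(
    edges[keep, c("node_a", "node_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE))
  igraph::simplify(g)
}

#' Maximal Clique Centrality
#'
#' `MCC(v)` is the sum over all maximal cliques `C` of size >= 2 containing
#' `v` of `(|C| - 1)!`. An isolated node scores 0. In a graph where a node's
#' neighbors are pairwise non-adjacent every incident edge is a maximal
#' 2-clique, so MCC reduces to the degree.
#'
#' @param graph an igraph undirected simple graph.
#' @return Named numeric vector of MCC scores, one per node.
#' @export
mcc_scores <- function(graph) {
  nodes <- igraph::V(graph)$name
  out <- setNames(numeric(length(nodes)), nodes)
  if (igraph::ecount(graph) == 0) return(out)
  cliques <- igraph::max_cliques(graph, min = 2)
  for (cl in cliques) {
    w <- factorial(length(cl) - 1)
    members <- nodes[as.integer(cl)]
    out[members] <- out[members] + w
  }
  out
}

#' Edge Percolated Component scores
#'
#' Monte-Carlo percolation: in each iteration every edge is independently
#' removed with probability `retain_threshold`; `EPC(v)` is the mean over
#' iterations of the number of other nodes left in `v`'s connected
#' component. An isolated node scores exactly 0.
#'
#' @param graph an igraph undirected simple graph.
#' @param retain_threshold per-edge removal probability, default 0.5.
#' @param n_iter Monte-Carlo iterations, default 1000.
#' @param seed integer seed.
#' @return Named numeric vector of EPC scores.
#' @export
epc_scores <- function(graph, retain_threshold = 0.5, n_iter = 1000L,
                       seed = 1L) {
  if (n_iter < 1) .stopf("epc_scores: n_iter must be >= 1")
  nodes <- igraph::V(graph)$name
  acc <- setNames(numeric(length(nodes)), nodes)
  ne <- igraph::ecount(graph)
  if (ne == 0 || length(nodes) == 0) return(acc)
  set.seed(seed)
  for (i in seq_len(n_iter)) {
    drop <- which(runif(ne) < retain_threshold)
    gs <- igraph::delete_edges(graph, drop)
    comp <- igraph::components(gs)
    acc <- acc + (comp$csize[comp$membership] - 1)
  }
  acc / n_iter
}

#' Degree, MCC and EPC hub scores with per-method ranks
#'
#' @param graph an igraph undirected simple graph.
#' @param epc_iters,epc_seed passed to [epc_scores()].
#' @return data.frame with `node`, `degree`, `mcc`, `epc` and dense ranks
#'   `rank_degree`, `rank_mcc`, `rank_epc` (1 = highest score).
#' @export
hub_scores <- function(graph, epc_iters = 1000L, epc_seed = 1L) {
  nodes <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  mcc <- mcc_scores(graph)
  epc <- epc_scores(graph, n_iter = epc_iters, seed = epc_seed)
  dense_rank <- function(x) match(-x, sort(unique(-x)))
  df <- data.frame(node = nodes, degree = unname(deg[nodes]),
                   mcc = unname(mcc[nodes]), epc = unname(epc[nodes]),
                   stringsAsFactors = FALSE)
  df$rank_degree <- dense_rank(df$degree)
  df$rank_mcc <- dense_rank(df$mcc)
  df$rank_epc <- dense_rank(df$epc)
  df[order(df$rank_mcc, df$node), , drop = FALSE]
}

.density_of <- function(graph) {
  n <- igraph::vcount(graph)
  if (n < 2) return(0)
  2 * igraph::ecount(graph) / (n * (n - 1))
}

#' MCODE dense-module detection
#'
#' Three stages. (1) Vertex weighting: each vertex with degree >=
#' `degree_cutoff` is weighted by `k * density` of the highest k-core of the
#' subgraph induced by its closed neighborhood; lower-degree vertices weigh
#' 0. (2) Complex growth: starting from the highest-weighted unvisited seed,
#' neighbors are added breadth-first (depth <= `max_depth`) when their
#' weight exceeds `seed_weight * (1 - node_score_cutoff)`; included vertices
#' are not revisited by later seeds. (3) Post-processing: with
#' `haircut = TRUE`, members of degree < 2 inside the module are removed
#' iteratively; modules whose induced subgraph contains no `k_core`-core are
#' discarded. The module score is density times member count. Ties in
#' seed selection and output order are broken lexicographically.
#'
#' @param graph an igraph undirected simple graph.
#' @param degree_cutoff,node_score_cutoff,k_core,max_depth MCODE parameters
#'   (defaults 2, 0.2, 2, 100).
#' @param haircut,fluff post-processing switches (fluff is accepted for
#'   interface completeness and must be `FALSE`; the fluff stage is not
#'   implemented).
#' @return data.frame with `rank`, `score`, `seed_node`, `size`, `members`
#'   (semicolon-joined), ordered by score descending.
#' @export
mcode <- function(graph, degree_cutoff = 2, node_score_cutoff = 0.2,
                  k_core = 2, max_depth = 100, haircut = TRUE,
                  fluff = FALSE) {
  if (fluff) .stopf("mcode: fluff stage not implemented")
  empty <- data.frame(rank = integer(0), score = numeric(0),
                      seed_node = character(0), size = integer(0),
                      members = character(0), stringsAsFactors = FALSE)
  nodes <- igraph::V(graph)$name
  if (length(nodes) == 0 || igraph::ecount(graph) == 0) return(empty)
  deg <- igraph::degree(graph)
  # stage 1: vertex weighting by highest k-core of the closed neighborhood
  weight <- setNames(numeric(length(nodes)), nodes)
  adj <- igraph::adjacent_vertices(graph, igraph::V(graph))
  for (i in seq_along(nodes)) {
    if (deg[i] < degree_cutoff) next
    nbhd <- c(i, as.integer(adj[[i]]))
    sub <- igraph::induced_subgraph(graph, nbhd)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_sub <- igraph::induced_subgraph(sub, which(core == kmax))
    weight[nodes[i]] <- kmax * .density_of(core_sub)
  }
  # stage 2: seeded complex growth
  nbrs <- lapply(adj, function(v) nodes[as.integer(v)])
  names(nbrs) <- nodes
  visited <- setNames(logical(length(nodes)), nodes)
  seeds_order <- nodes[order(-weight[nodes], nodes)]
  complexes <- list()
  for (seed in seeds_order) {
    if (visited[seed] || weight[seed] <= 0) next
    threshold <- weight[seed] * (1 - node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) > 0 && depth < max_depth) {
      nxt <- character(0)
      for (v in frontier) {
        for (u in sort(nbrs[[v]])) {
          if (!visited[u] && weight[u] > threshold) {
            visited[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1
    }
    complexes[[length(complexes) + 1]] <- list(seed = seed,
                                               members = members)
  }
  # stage 3: haircut, k-core filter, scoring
  rows <- list()
  for (cx in complexes) {
    members <- cx$members
    if (haircut) {
      repeat {
        sub <- igraph::induced_subgraph(graph, members)
        d <- igraph::degree(sub)
        low <- igraph::V(sub)$name[d < 2]
        if (length(low) == 0) break
        members <- setdiff(members, low)
        if (length(members) == 0) break
      }
    }
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(graph, members)
    if (max(igraph::coreness(sub)) < k_core) next
    score <- .density_of(sub) * length(members)
    rows[[length(rows) + 1]] <- data.frame(
      score = score, seed_node = cx$seed, size = length(members),
      members = paste(sort(members), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  res <- do.call(rbind, rows)
  res <- res[order(-res$score, res$members), , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res[, c("rank", "score", "seed_node", "size", "members")]
}

#' Top-k MCODE modules
#' @param modules output of [mcode()].
#' @param k number of modules to keep (default 5).
#' @return The first `k` rows.
#' @export
top_modules <- function(modules, k = 5) {
  modules[seq_len(min(k, nrow(modules))), , drop = FALSE]
}
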