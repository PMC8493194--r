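#' @title Reaction-graph construction and network statistics
#' @name net_analysis
#' @description CRNs are analysed as directed graphs: structures are
#'   regular nodes, 1-reactant-1-product reactions are direct edges, and any
#'   reaction touching more than two structures becomes a special reaction
#'   node with reactant -> reaction and reaction -> product edges.
NULL

#' Build the directed reaction graph of a CRN
#'
#' Node ids are canonical kernel strings (structures) and
#' `"rxn: <reaction key>"` (reaction nodes). Node kinds: `source` (initial
#' strands), `wellformed` (supplied list), `intermediary` (other
#' structures), `reaction`. Reactant multiplicity (e.g. 2X -> Y) is
#' collapsed to a single edge with a `multiplicity` attribute.
#'
#' @param crn a `dsd_crn`.
#' @param wellformed character vector of canonical kernel strings to tag as
#'   well-formed.
#' @return a directed `igraph` graph.
#' @export
build_graph <- function(crn, wellformed = character(0)) {
  kernels <- sort(names(crn$structures))
  kind <- ifelse(kernels %in% crn$initial, "source",
                 ifelse(kernels %in% wellformed, "wellformed",
                        "intermediary"))
  nodes <- data.frame(name = kernels, kind = kind,
                      stringsAsFactors = FALSE)
  from <- character(0); to <- character(0); mult <- integer(0)
  rtype <- character(0)
  for (r in crn$reactions) {
    if (length(r$reactants) == 1 && length(r$products) == 1) {
      from <- c(from, r$reactants); to <- c(to, r$products)
      mult <- c(mult, 1L); rtype <- c(rtype, r$rtype)
    } else {
      rid <- paste0("rxn: ", reaction_key(r))
      nodes <- rbind(nodes, data.frame(name = rid, kind = "reaction",
                                       stringsAsFactors = FALSE))
      for (u in unique(r$reactants)) {
        from <- c(from, u); to <- c(to, rid)
        mult <- c(mult, sum(r$reactants == u)); rtype <- c(rtype, r$rtype)
      }
      for (u in unique(r$products)) {
        from <- c(from, rid); to <- c(to, u)
        mult <- c(mult, sum(r$products == u)); rtype <- c(rtype, r$rtype)
      }
    }
  }
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  edges <- data.frame(from = from, to = to, multiplicity = mult,
                      rtype = rtype, stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    edges <- unique(edges)
    edges <- edges[order(edges$from, edges$to, edges$rtype), , drop = FALSE]
  }
  igraph::graph_from_data_frame(edges, directed = TRUE, vertices = nodes)
}

# Lexicographically smallest shortest path from `from` to `to` (vertex
# names), avoiding `avoid_nodes` and `avoid_edges` ("u\r-> v" keys).
# Returns a character vector of names, or NULL.
lex_shortest_path <- function(adj, radj, from, to, avoid_nodes = character(0),
                              avoid_edges = character(0)) {
  ekey <- function(u, v) paste(u, "\r->", v)
  ok_node <- function(v) !(v %in% avoid_nodes)
  if (!ok_node(from) || !ok_node(to)) return(NULL)
  # BFS distances to `to` on the reversed graph
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[to] <- 0
  queue <- to
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (u in radj[[v]]) {
      if (!ok_node(u) || ekey(u, v) %in% avoid_edges) next
      if (is.infinite(dist[u])) {
        dist[u] <- dist[v] + 1
        queue <- c(queue, u)
      }
    }
  }
  if (is.infinite(dist[from])) return(NULL)
  path <- from
  cur <- from
  while (cur != to) {
    nbrs <- adj[[cur]]
    nbrs <- nbrs[vapply(nbrs, function(v) {
      ok_node(v) && !(ekey(cur, v) %in% avoid_edges) &&
        is.finite(dist[v]) && dist[v] == dist[cur] - 1
    }, logical(1))]
    nbrs <- sort(nbrs)
    cur <- nbrs[1]          # lexicographic tie-break
    path <- c(path, cur)
  }
  path
}

# Yen's k shortest simple paths with deterministic (length, lexicographic)
# ordering. Returns a list of name vectors.
k_shortest_paths_lex <- function(g, from, to, k) {
  vn <- igraph::V(g)$name
  adj <- lapply(stats::setNames(vn, vn), function(v) {
    sort(igraph::V(g)$name[igraph::neighbors(g, v, mode = "out")])
  })
  radj <- lapply(stats::setNames(vn, vn), function(v) {
    sort(igraph::V(g)$name[igraph::neighbors(g, v, mode = "in")])
  })
  ekey <- function(u, v) paste(u, "\r->", v)
  first <- lex_shortest_path(adj, radj, from, to)
  if (is.null(first)) return(list())
  A <- list(first)
  path_key <- function(p) paste(p, collapse = "\r")
  B <- list()
  B_keys <- character(0)
  while (length(A) < k) {
    prev <- A[[length(A)]]
    for (i in seq_len(length(prev) - 1)) {
      root <- prev[seq_len(i)]
      avoid_edges <- character(0)
      for (p in A) {
        if (length(p) > i && identical(p[seq_len(i)], root)) {
          avoid_edges <- c(avoid_edges, ekey(p[i], p[i + 1]))
        }
      }
      avoid_nodes <- if (i > 1) root[seq_len(i - 1)] else character(0)
      spur <- lex_shortest_path(adj, radj, prev[i], to,
                                avoid_nodes, avoid_edges)
      if (is.null(spur)) next
      total <- c(root[-i], spur)
      tk <- path_key(total)
      if (tk %in% B_keys || any(vapply(A, path_key, character(1)) == tk)) {
        next
      }
      B[[length(B) + 1L]] <- total
      B_keys <- c(B_keys, tk)
    }
    if (length(B) == 0) break
    lens <- vapply(B, length, integer(1))
    keys <- vapply(B, path_key, character(1))
    ord <- order(lens, keys)
    A[[length(A) + 1L]] <- B[[ord[1]]]
    B <- B[ord[-1]]
    B_keys <- B_keys[B_keys != keys[ord[1]]]
  }
  A
}

#' Overlap network: pathways from sources to well-formed structures
#'
#' Union, over all ordered (source, well-formed) pairs, of up to `k_paths`
#' shortest simple directed paths (Yen's algorithm with deterministic
#' lexicographic tie-breaks); the result keeps exactly the nodes and edges
#' lying on those paths, with sources and well-formed nodes always
#' included. Unreachable pairs contribute nothing.
#'
#' @param g a reaction graph from [build_graph()] (node kinds tagged).
#' @param k_paths maximum simple paths per pair (default 6).
#' @return the overlap subgraph (`igraph`).
#' @export
overlap_network <- function(g, k_paths = 6L) {
  kinds <- igraph::V(g)$kind
  names(kinds) <- igraph::V(g)$name
  sources <- sort(names(kinds)[kinds == "source"])
  targets <- sort(names(kinds)[kinds == "wellformed"])
  keep_nodes <- c(sources, targets)
  keep_edges <- character(0)
  for (s in sources) {
    for (t in targets) {
      if (s == t) next
      for (p in k_shortest_paths_lex(g, s, t, k_paths)) {
        keep_nodes <- c(keep_nodes, p)
        if (length(p) > 1) {
          keep_edges <- c(keep_edges,
                          paste(p[-length(p)], "\r->", p[-1]))
        }
      }
    }
  }
  keep_nodes <- sort(unique(keep_nodes))
  keep_edges <- unique(keep_edges)
  el <- igraph::as_data_frame(g, what = "edges")
  sel <- paste(el$from, "\r->", el$to) %in% keep_edges
  nodes <- igraph::as_data_frame(g, what = "vertices")
  nodes <- nodes[nodes$name %in% keep_nodes, , drop = FALSE]
  igraph::graph_from_data_frame(el[sel, , drop = FALSE], directed = TRUE,
                                vertices = nodes)
}

#' Density and degree assortativity
#'
#' Density is m / (n (n - 1)) on the directed graph. Assortativity is the
#' Pearson correlation of total degrees across edge endpoints on the
#' undirected projection (both edge orientations counted); degenerate
#' degree sequences give NaN.
#'
#' @param g an `igraph` graph (n >= 2).
#' @return list with `density` and `assortativity`.
#' @export
density_assortativity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n >= 2)
  m <- igraph::ecount(g)
  gu <- igraph::as_undirected(g, mode = "collapse")
  deg <- igraph::degree(gu)
  el <- igraph::as_edgelist(gu, names = FALSE)
  assort <- NaN
  if (nrow(el) >= 2) {
    x <- c(deg[el[, 1]], deg[el[, 2]])
    y <- c(deg[el[, 2]], deg[el[, 1]])
    assort <- suppressWarnings(stats::cor(x, y))
    if (is.na(assort)) assort <- NaN
  }
  list(density = m / (n * (n - 1)), assortativity = assort)
}

#' Local clustering statistics
#'
#' Mean and standard deviation of the per-node local clustering coefficient
#' on the undirected projection; nodes of degree < 2 count as 0 (the usual
#' network-toolkit convention).
#'
#' @param g an `igraph` graph (n >= 3).
#' @return list with `mean` and `std`.
#' @export
clustering_stats <- function(g) {
  stopifnot(igraph::vcount(g) >= 3)
  gu <- igraph::as_undirected(g, mode = "collapse")
  cc <- igraph::transitivity(gu, type = "localundirected",
                             isolates = "zero")
  list(mean = mean(cc), std = stats::sd(cc))
}

#' Hierarchy metrics: global reaching centrality and flow hierarchy
#'
#' C_R(i) is the fraction of other nodes reachable from i;
#' GRC = sum_i (max_j C_R(j) - C_R(i)) / (n - 1). Flow hierarchy is the
#' fraction of directed edges whose endpoints lie in different strongly
#' connected components (edges on no cycle).
#'
#' @param g a directed `igraph` graph.
#' @return list with `global_reaching_centrality` and `flow_hierarchy`.
#' @export
hierarchy_metrics <- function(g) {
  n <- igraph::vcount(g)
  d <- igraph::distances(g, mode = "out")
  reach <- (rowSums(is.finite(d)) - 1) / (n - 1)
  grc <- sum(max(reach) - reach) / (n - 1)
  scc <- igraph::components(g, mode = "strong")$membership
  el <- igraph::as_edgelist(g, names = FALSE)
  fh <- if (nrow(el) == 0) NaN else mean(scc[el[, 1]] != scc[el[, 2]])
  list(global_reaching_centrality = grc, flow_hierarchy = fh)
}

#' Node, edge and eigenvector centralities
#'
#' Node and edge betweenness are shortest-path counts on the directed graph
#' (unnormalized). Eigenvector centrality is computed by (shifted) power
#' iteration on the directed adjacency matrix (tolerance 1e-8, at most 1e4
#' iterations), normalized to unit maximum; if the iteration degenerates
#' (as it typically does on reaction DAGs) the undirected projection is
#' used instead and flagged.
#'
#' @param g a directed `igraph` graph.
#' @return a list with `node_betweenness`, `edge_betweenness` (named
#'   `"from -> to"`), `eigenvector_centrality` and `eigenvector_fallback`.
#' @export
centralities <- function(g) {
  nb <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
  eb <- igraph::edge_betweenness(g, directed = TRUE)
  el <- igraph::as_edgelist(g)
  names(eb) <- paste(el[, 1], "->", el[, 2])
  power_iter <- function(A) {
    n <- nrow(A)
    x <- rep(1 / n, n)
    M <- t(A) + diag(n)   # shift preserves eigenvectors, damps oscillation
    for (it in seq_len(10000L)) {
      x2 <- as.numeric(M %*% x)
      nrm <- max(abs(x2))
      if (nrm == 0) return(NULL)
      x2 <- x2 / nrm
      if (max(abs(x2 - x)) < 1e-8) return(x2)
      x <- x2
    }
    NULL
  }
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  ev <- power_iter(A)
  fallback <- FALSE
  if (is.null(ev) || max(ev) <= 0 || any(ev < -1e-12)) {
    fallback <- TRUE
    Au <- as.matrix(igraph::as_adjacency_matrix(
      igraph::as_undirected(g, mode = "collapse")))
    ev <- power_iter(Au)
    if (is.null(ev)) ev <- rep(1, igraph::vcount(g))
  }
  ev <- ev / max(ev)
  names(ev) <- igraph::V(g)$name
  list(node_betweenness = nb, edge_betweenness = eb,
       eigenvector_centrality = ev, eigenvector_fallback = fallback)
}

#' Full network statistics bundle
#'
#' The robustness/modularity/hierarchy summary reported per reaction
#' network: size, density, assortativity, discrete power-law KS fit of the
#' degree distribution, clustering, global reaching centrality and flow
#' hierarchy.
#'
#' @param g an `igraph` graph.
#' @param bootstrap_reps bootstrap replicates for [powerlaw_ks()]; the fit
#'   is skipped (NA entries) when the graph has fewer than 10 positive
#'   degrees.
#' @param seed seed for the bootstrap.
#' @return a `graph_stats` list.
#' @export
graph_stats <- function(g, bootstrap_reps = 100L, seed = 1L) {
  da <- density_assortativity(g)
  ks <- tryCatch(powerlaw_ks(g, bootstrap_reps, seed),
                 error = function(e) list(alpha = NA_real_, xmin = NA_real_,
                                          D = NA_real_, p = NA_real_,
                                          scale_free = NA))
  cl <- if (igraph::vcount(g) >= 3) clustering_stats(g) else
    list(mean = NaN, std = NaN)
  hm <- hierarchy_metrics(g)
  structure(list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
                 density = da$density, assortativity = da$assortativity,
                 ks_powerlaw = ks, clustering = cl,
                 global_reaching_centrality = hm$global_reaching_centrality,
                 flow_hierarchy = hm$flow_hierarchy),
            class = "graph_stats")
}

#' @export
print.graph_stats <- function(x, ...) {
  cat(sprintf(paste0("<graph_stats> n=%d m=%d density=%.5g ",
                     "assortativity=%.4g\n  KS D=%.4g p=%.3g  clustering=",
                     "%.4g+-%.4g  GRC=%.4g  flow hierarchy=%.4g\n"),
              x$n_nodes, x$n_edges, x$density, x$assortativity,
              x$ks_powerlaw$D, x$ks_powerlaw$p, x$clustering$mean,
              x$clustering$std, x$global_reaching_centrality,
              x$flow_hierarchy))
  invisible(x)
}

#' Flatten graph stats to a one-row data frame
#' @param x a `graph_stats`.
#' @param name network label for the first column.
#' @return one-row data.frame in the usual reporting column order.
#' @export
graph_stats_row <- function(x, name = "network") {
  data.frame(name = name, n_nodes = x$n_nodes, n_edges = x$n_edges,
             density = x$density, assortativity = x$assortativity,
             ks_D = x$ks_powerlaw$D, ks_p = x$ks_powerlaw$p,
             clustering_mean = x$clustering$mean,
             clustering_std = x$clustering$std,
             global_reaching_centrality = x$global_reaching_centrality,
             flow_hierarchy = x$flow_hierarchy)
}

#' Export a reaction graph to GraphML or DOT
#'
#' @param g an `igraph` graph (node `kind` attributes preserved).
#' @param path output path.
#' @param format "graphml" or "dot".
#' @return invisibly `path`.
#' @export
write_reaction_graph <- function(g, path, format = c("graphml", "dot")) {
  format <- match.arg(format)
  igraph::write_graph(g, path, format = format)
  invisible(path)
}
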