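test_that("build_graph places reaction nodes only for >2-participant reactions", {
  doms <- toy_domains()
  # hairpin-only system: two 1 -> 1 reactions become direct edges
  uni <- enumerate_crn(list(c("a", "a*")), doms, fig1_params(1))
  g1 <- build_graph(uni)
  expect_equal(igraph::vcount(g1), 2L)
  expect_equal(igraph::ecount(g1), 2L)
  expect_false(any(igraph::V(g1)$kind == "reaction"))

  # Fig 1: the 2 -> 1 duplex bind gets a reaction node, with the reactant
  # multiplicity collapsed onto one annotated edge
  fig1 <- enumerate_crn(list(c("a", "a*")), doms, fig1_params())
  g <- build_graph(fig1, wellformed = "a( a*( + ) )")
  rxn <- igraph::V(g)$name[igraph::V(g)$kind == "reaction"]
  expect_equal(length(rxn), 2L)  # 2s -> d and d -> 2s
  bind_node <- rxn[grepl("bind", rxn)]
  expect_equal(igraph::degree(g, bind_node, mode = "in"), c(1L),
               ignore_attr = TRUE)
  ein <- igraph::incident(g, bind_node, mode = "in")
  expect_equal(igraph::edge_attr(g, "multiplicity", ein), 2L)
  kinds <- stats::setNames(igraph::V(g)$kind, igraph::V(g)$name)
  expect_equal(unname(kinds["a a*"]), "source")
  expect_equal(unname(kinds["a( a*( + ) )"]), "wellformed")
  expect_equal(unname(kinds["a( )"]), "intermediary")

  # empty reaction set: isolated structure nodes
  mono <- enumerate_crn(list(c("a", "b")), c(a = 10L, b = 10L),
                        fig1_params())
  g0 <- build_graph(mono)
  expect_equal(igraph::vcount(g0), 1L)
  expect_equal(igraph::ecount(g0), 0L)
})

test_that("overlap_network keeps exactly the k-shortest-path span", {
  # single chain source -> A -> target
  chain <- igraph::graph_from_data_frame(
    data.frame(from = c("s", "A"), to = c("A", "t")), directed = TRUE,
    vertices = data.frame(name = c("s", "A", "t"),
                          kind = c("source", "intermediary", "wellformed")))
  ov <- overlap_network(chain)
  expect_setequal(igraph::V(ov)$name, c("s", "A", "t"))
  expect_equal(igraph::ecount(ov), 2L)

  # diamond with two equal-length paths: k_paths = 1 keeps the
  # lexicographically smaller one
  dia <- igraph::graph_from_data_frame(
    data.frame(from = c("s", "s", "a", "b"), to = c("a", "b", "t", "t")),
    directed = TRUE,
    vertices = data.frame(name = c("s", "a", "b", "t"),
                          kind = c("source", "intermediary", "intermediary",
                                   "wellformed")))
  ov1 <- overlap_network(dia, k_paths = 1L)
  expect_setequal(igraph::V(ov1)$name, c("s", "a", "t"))
  ov2 <- overlap_network(dia, k_paths = 6L)
  expect_setequal(igraph::V(ov2)$name, c("s", "a", "b", "t"))

  # saturation: everything reachable is retained when all nodes well-formed
  doms <- toy_domains()
  fig1 <- enumerate_crn(list(c("a", "a*")), doms, fig1_params())
  g <- build_graph(fig1, wellformed = setdiff(names(fig1$structures),
                                              fig1$initial))
  ovf <- overlap_network(g, k_paths = 50L)
  expect_true(all(igraph::V(ovf)$name %in% igraph::V(g)$name))
  expect_true(all(c("a a*", "a( )", "a( a*( + ) )") %in%
                    igraph::V(ovf)$name))
  # subgraph property: every overlap edge exists in the full graph
  elo <- igraph::as_data_frame(ovf, "edges")
  elg <- igraph::as_data_frame(g, "edges")
  expect_true(all(paste(elo$from, elo$to) %in% paste(elg$from, elg$to)))
})

test_that("density reproduces the reported conventions", {
  g142 <- random_digraph(142, 271, seed = 1)
  expect_equal(round(density_assortativity(g142)$density, 5), 0.01354)
  g54 <- random_digraph(54, 118, seed = 2)
  expect_equal(round(density_assortativity(g54)$density, 5), 0.04123)
  full <- igraph::make_full_graph(5, directed = TRUE)
  igraph::V(full)$name <- paste0("v", 1:5)
  expect_equal(density_assortativity(full)$density, 1)
  star <- igraph::make_star(7, mode = "out")
  igraph::V(star)$name <- paste0("v", 1:7)
  expect_lt(density_assortativity(star)$assortativity, 0)
})

test_that("clustering_stats matches hand computation", {
  tri <- igraph::graph_from_literal(A - B, B - C, C - A)
  cs <- clustering_stats(igraph::as_directed(tri, mode = "arbitrary"))
  expect_equal(cs$mean, 1)
  expect_equal(cs$std, 0)
  star <- igraph::make_star(6, mode = "out")
  igraph::V(star)$name <- paste0("v", 1:6)
  expect_equal(clustering_stats(star)$mean, 0)
  # 4-cycle plus one chord: local coefficients (2/3, 1, 2/3, 1)
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("n1", "n2", "n3", "n4", "n1"),
               to = c("n2", "n3", "n4", "n1", "n3")), directed = TRUE)
  cs2 <- clustering_stats(g)
  expect_equal(cs2$mean, mean(c(2 / 3, 1, 2 / 3, 1)))
  expect_equal(cs2$std, stats::sd(c(2 / 3, 1, 2 / 3, 1)))
})

test_that("hierarchy metrics hit the analytic extremes", {
  star <- igraph::make_star(8, mode = "out")
  igraph::V(star)$name <- paste0("v", 1:8)
  hm <- hierarchy_metrics(star)
  expect_equal(hm$global_reaching_centrality, 1)
  cyc <- igraph::make_ring(6, directed = TRUE)
  igraph::V(cyc)$name <- paste0("v", 1:6)
  hmc <- hierarchy_metrics(cyc)
  expect_equal(hmc$global_reaching_centrality, 0)
  expect_equal(hmc$flow_hierarchy, 0)
  dag <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "a", "b"), to = c("b", "c", "c")))
  expect_equal(hierarchy_metrics(dag)$flow_hierarchy, 1)
})

test_that("centralities match the simple analytic cases", {
  path <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b"), to = c("b", "c")))
  ce <- centralities(path)
  expect_equal(unname(ce$node_betweenness[c("a", "b", "c")]), c(0, 1, 0))
  cyc <- igraph::make_ring(5, directed = TRUE)
  igraph::V(cyc)$name <- paste0("v", 1:5)
  cec <- centralities(cyc)
  expect_equal(max(cec$eigenvector_centrality) -
                 min(cec$eigenvector_centrality), 0, tolerance = 1e-6)
  # bridge between two triangles (reciprocal directed edges): the bridge
  # carries every cross-triangle shortest path
  edges <- rbind(c("a", "b"), c("b", "c"), c("c", "a"),
                 c("d", "e"), c("e", "f"), c("f", "d"),
                 c("a", "d"))
  el <- rbind(edges, edges[, 2:1])
  gt <- igraph::graph_from_data_frame(as.data.frame(el))
  ceb <- centralities(gt)
  oracle <- oracle_betweenness(gt)
  expect_equal(ceb$edge_betweenness[names(oracle$edge)], oracle$edge,
               tolerance = 1e-9)
})

test_that("metrics agree with brute-force oracles on small random digraphs", {
  for (seed in 1:4) {
    g <- random_digraph(8, 14, seed = seed)
    expect_equal(hierarchy_metrics(g)$flow_hierarchy,
                 oracle_flow_hierarchy(g))
    expect_equal(hierarchy_metrics(g)$global_reaching_centrality,
                 oracle_grc(g))
    cs <- clustering_stats(g)
    ocs <- oracle_clustering(g)
    expect_equal(cs$mean, ocs$mean, tolerance = 1e-12)
    expect_equal(cs$std, ocs$std, tolerance = 1e-12)
    ce <- centralities(g)
    ob <- oracle_betweenness(g)
    expect_equal(ce$node_betweenness[names(ob$node)], ob$node,
                 tolerance = 1e-9)
    expect_equal(ce$edge_betweenness[names(ob$edge)], ob$edge,
                 tolerance = 1e-9)
    da <- density_assortativity(g)
    expect_equal(da$density,
                 igraph::ecount(g) / (igraph::vcount(g) *
                                        (igraph::vcount(g) - 1)))
    # ranges on fuzzed graphs
    hm <- hierarchy_metrics(g)
    expect_true(da$density >= 0 && da$density <= 1)
    expect_true(hm$global_reaching_centrality >= 0 &&
                  hm$global_reaching_centrality <= 1)
    expect_true(hm$flow_hierarchy >= 0 && hm$flow_hierarchy <= 1)
    expect_true(cs$mean >= 0 && cs$mean <= 1)
  }
})

test_that("power-law fit recovers alpha and rejects degenerate sequences", {
  set.seed(42)
  k <- 1:10000
  pmf <- k^(-2.5)
  x <- sample(k, 2000, replace = TRUE, prob = pmf / sum(pmf))
  fit <- powerlaw_ks(x, bootstrap_reps = 10L, seed = 7L)
  expect_lt(abs(fit$alpha - 2.5), 0.2)
  const <- powerlaw_ks(rep(4L, 50), bootstrap_reps = 30L, seed = 1L)
  expect_false(const$scale_free)
  expect_lt(const$p, 0.1)
  expect_error(powerlaw_ks(c(1, 2, 3), bootstrap_reps = 5L), "at least 10")
  # determinism
  f1 <- powerlaw_ks(x, bootstrap_reps = 10L, seed = 7L)
  expect_identical(fit, f1)
})

test_that("an enumerated toy reaction graph is not scale-free", {
  doms <- toy_domains()
  crn <- enumerate_crn(list(c("a", "a"), c("a*", "a*")), doms,
                       enum_params(max_complex_size = 4,
                                   release_cutoff = 10))
  g <- build_graph(crn)
  fit <- powerlaw_ks(g, bootstrap_reps = 50L, seed = 3L)
  expect_false(fit$scale_free)
  gs <- graph_stats(g, bootstrap_reps = 10L, seed = 3L)
  expect_true(gs$density >= 0 && gs$density <= 1)
  expect_true(gs$flow_hierarchy >= 0 && gs$flow_hierarchy <= 1)
  row <- graph_stats_row(gs, "toy")
  expect_equal(nrow(row), 1L)
  expect_equal(row$n_nodes, igraph::vcount(g))
})

test_that("graph export writes GraphML and DOT", {
  doms <- toy_domains()
  fig1 <- enumerate_crn(list(c("a", "a*")), doms, fig1_params())
  g <- build_graph(fig1)
  f1 <- withr::local_tempfile(fileext = ".graphml")
  f2 <- withr::local_tempfile(fileext = ".dot")
  write_reaction_graph(g, f1, "graphml")
  write_reaction_graph(g, f2, "dot")
  expect_gt(file.size(f1), 0)
  expect_gt(file.size(f2), 0)
})
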