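edge_row <- function(a, b, ...) {
  scores <- list(...)
  row <- as.list(stats::setNames(rep(0, length(STRING_CHANNELS)), STRING_CHANNELS))
  row[names(scores)] <- scores
  cbind(data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE),
        as.data.frame(row))
}

test_that("STRING edge reader converts units, collapses duplicates, drops self-loops", {
  f <- tempfile()
  writeLines(c(
    "protein1\tprotein2\tneighborhood\tfusion\tcooccurence\tcoexpression\texperimental\tdatabase\ttextmining\tcombined_score",
    "B\tA\t0\t0\t0\t100\t900\t0\t0\t900",
    "A\tB\t0\t0\t0\t100\t900\t0\t0\t900",
    "C\tC\t0\t0\t0\t0\t500\t0\t0\t500",
    "A\tC\t10\t0\t0\t0\t0\t0\t990\t990"
  ), f)
  ed <- read_string_edges(f)
  expect_equal(nrow(ed), 2L)
  expect_equal(attr(ed, "n_self_loops"), 1L)
  expect_equal(ed$gene_a, c("A", "A"))
  expect_equal(ed$gene_b, c("B", "C"))
  expect_equal(ed$experimental[1], 0.9)
  expect_equal(ed$combined_score[1], 0.9)
  expect_equal(ed$textmining[2], 0.99)

  f2 <- tempfile()
  writeLines(c("protein1\tprotein2\tscore", "A\tB\t1"), f2)
  expect_error(read_string_edges(f2), "missing required columns")
})

test_that("score recombination obeys the prior-correction algebra", {
  # no allowed evidence: the prior is the floor
  none <- edge_row("A", "B", textmining = 0.99)
  expect_equal(recombine_score(none), 0.041)

  # single-channel idempotence across the score range
  for (s in c(0.45, 0.70, 0.90, 0.99)) {
    one <- edge_row("A", "B", experimental = s)
    expect_lt(abs(recombine_score(one, allowed_channels = "experimental") - s), 1e-3)
  }

  # two channels at 0.5 with zero prior: 1 - 0.5^2
  two <- edge_row("A", "B", coexpression = 0.5, experimental = 0.5)
  expect_equal(recombine_score(two, prior = 0), 0.75)

  expect_error(recombine_score(two, prior = 1), "prior")
})

test_that("recombination is monotone in allowed channels and blind to excluded ones", {
  set.seed(31)
  for (i in 1:50) {
    base <- stats::runif(7)
    names(base) <- STRING_CHANNELS
    r0 <- recombine_score(base)
    # raising an excluded channel changes nothing
    bumped <- base
    bumped["textmining"] <- min(1, base[["textmining"]] + 0.3)
    expect_equal(recombine_score(bumped), r0)
    # raising an allowed channel never lowers the score
    up <- base
    up["experimental"] <- min(1, base[["experimental"]] + 0.2)
    expect_gte(recombine_score(up), r0 - 1e-12)
  }
})

test_that("network construction keeps only high-confidence DEG-DEG edges", {
  ed <- rbind(
    edge_row("A", "B", experimental = 0.95),                 # in
    edge_row("A", "C", textmining = 0.99),                   # decoy: out
    edge_row("B", "C", experimental = 0.85),                 # below threshold
    edge_row("A", "Z", experimental = 0.99),                 # non-DEG endpoint
    edge_row("C", "D", coexpression = 0.9, experimental = 0.9) # combined in
  )
  g <- build_network(ed, deg_genes = c("A", "B", "C", "D", "E"))
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D", "E"))
  el <- igraph::as_data_frame(g)
  expect_equal(nrow(el), 2L)
  expect_true(igraph::are_adjacent(g, "A", "B"))
  expect_true(igraph::are_adjacent(g, "C", "D"))
  expect_equal(unname(igraph::degree(g)["E"]), 0)          # isolated DEG kept
  expect_error(build_network(ed, character(0)), "empty DEG list")
})

test_that("component diameters match hand examples and the exhaustive oracle", {
  path4 <- igraph::graph_from_literal(a - b, b - c, c - d)
  expect_equal(component_diameters(path4)$diameter, 3L)
  tri <- igraph::make_full_graph(3)
  expect_equal(component_diameters(tri)$diameter, 1L)

  set.seed(71)
  for (i in 1:100) {
    n <- sample(2:7, 1)
    a <- random_adjacency(n, p_edge = stats::runif(1, 0.2, 0.7))
    g <- adjacency_to_graph(a)
    got <- component_diameters(g)
    want <- brute_component_diameters(a)
    expect_setequal(got$diameter, as.integer(want$diameter))
    expect_equal(sum(got$n_nodes), n)
  }
})

test_that("max-diameter component selection prefers diameter, then size, then names", {
  # a 10-ring (diameter 5) beats a larger clique (diameter 1)
  g <- igraph::disjoint_union(igraph::make_ring(10),            # diameter 5
                              igraph::make_full_graph(12))
  igraph::V(g)$name <- c(paste0("p", 1:10), paste0("k", 1:12))
  sel <- select_max_diameter_component(g)
  expect_setequal(igraph::V(sel)$name, paste0("p", 1:10))

  # isomorphic ties resolved toward the lexicographically smaller node set
  h <- igraph::disjoint_union(igraph::make_ring(6), igraph::make_ring(6))
  igraph::V(h)$name <- c(paste0("b", 1:6), paste0("a", 1:6))
  sel2 <- select_max_diameter_component(h)
  expect_setequal(igraph::V(sel2)$name, paste0("a", 1:6))

  # single component returns itself
  single <- igraph::make_ring(4)
  igraph::V(single)$name <- paste0("x", 1:4)
  expect_setequal(igraph::V(select_max_diameter_component(single))$name,
                  paste0("x", 1:4))
})

test_that("group-node removal prunes exactly the listed genes without re-selection", {
  g <- igraph::graph_from_literal(a - b, b - c, c - d, d - e)
  same <- remove_group_nodes(g, c("zz1", "zz2"))
  expect_equal(igraph::vcount(same), 5L)
  expect_equal(igraph::graph_attr(same, "n_removed"), 0L)

  # removing the cut vertex disconnects but both halves are retained
  cut <- remove_group_nodes(g, "c")
  expect_equal(igraph::vcount(cut), 4L)
  expect_equal(igraph::components(cut)$no, 2L)
  expect_equal(igraph::graph_attr(cut, "n_removed"), 1L)
})

test_that("centrality matches hand values and the brute-force path oracle", {
  p3 <- igraph::graph_from_literal(a - b, b - c)
  c3 <- centrality(p3)
  expect_equal(c3$betweenness[c3$gene == "b"], 1.0)
  expect_equal(c3$betweenness[c3$gene != "b"], c(0, 0))

  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("l", 1:4))
  cs <- centrality(star)
  expect_equal(cs$betweenness[cs$gene == "hub"], 1.0)

  p4 <- igraph::graph_from_literal(a - b, b - c, c - d)
  c4 <- centrality(p4)
  expect_equal(c4$betweenness[c4$gene == "b"], 2 / 3)

  set.seed(93)
  for (i in 1:100) {
    n <- sample(3:7, 1)
    a <- random_adjacency(n, p_edge = stats::runif(1, 0.2, 0.8))
    g <- adjacency_to_graph(a)
    got <- centrality(g)
    want <- brute_betweenness(a)
    expect_equal(got$betweenness,
                 want[match(got$gene, paste0("v", seq_len(n)))],
                 tolerance = 1e-12)
    expect_equal(got$degree,
                 unname(rowSums(a))[match(got$gene, paste0("v", seq_len(n)))])
  }
})

test_that("hub selection applies strict thresholds and a deterministic order", {
  rec <- data.frame(
    gene = c("at_bt", "at_deg", "hub1", "hub2", "leaf"),
    degree = c(5L, 2L, 4L, 6L, 1L),
    betweenness = c(0.5, 0.9, 0.8, 0.8, 0.1)
  )
  expect_equal(select_hubs(rec), c("hub1", "hub2")[order(-rec$degree[3:4])])
  expect_equal(select_hubs(rec), c("hub2", "hub1"))  # degree breaks the tie
  expect_false("at_bt" %in% select_hubs(rec))   # betweenness == 0.5 excluded
  expect_false("at_deg" %in% select_hubs(rec))  # degree == 2 excluded
})

test_that("network summary matches hand values and brute-force clustering", {
  tri <- igraph::make_full_graph(3)
  s <- network_summary(tri)
  expect_equal(s$avg_degree, 2)
  expect_equal(s$avg_clustering, 1)

  star <- igraph::make_star(4, mode = "undirected", center = 1)
  expect_equal(network_summary(star)$avg_clustering, 0)

  set.seed(57)
  for (i in 1:50) {
    n <- sample(3:7, 1)
    a <- random_adjacency(n, p_edge = stats::runif(1, 0.2, 0.8))
    g <- adjacency_to_graph(a)
    expect_equal(network_summary(g)$avg_clustering, brute_avg_clustering(a),
                 tolerance = 1e-12)
  }

  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(network_summary(empty)$n_nodes, 0L)
})
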