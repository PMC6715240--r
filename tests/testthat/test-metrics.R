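# A layout built so that node "i" at the origin has 8 other nodes inside
# the radius-3 circle, of which the 3 adjacent ones, plus (for recall) more
# neighbours outside the circle.
pr_fixture <- function() {
  pos <- rbind(
    i = c(0, 0),
    # neighbours of i inside the circle
    n1 = c(1, 0), n2 = c(0, 1), n3 = c(-1, 0),
    # non-neighbours inside the circle
    u1 = c(2, 0), u2 = c(0, 2), u3 = c(-2, 0), u4 = c(0, -2), u5 = c(1, 1),
    # neighbours of i outside the circle
    f1 = c(10, 0), f2 = c(0, 10), f3 = c(-10, 0), f4 = c(10, 10)
  )
  g <- graph_from_pairs("i", "n1", "i", "n2", "i", "n3",
                        "i", "f1", "i", "f2", "i", "f3", "i", "f4",
                        "u1", "u2")
  g <- igraph::add_vertices(g, 3L, attr = list(name = c("u3", "u4", "u5")))
  list(layout = grid_layout(pos), network = g)
}

test_that("precision counts neighbours among circle contents", {
  fx <- pr_fixture()
  pr <- precision_recall(fx$layout, fx$network, "i", r = 3)
  expect_equal(unname(pr["P"]), 3 / 8)
})

test_that("recall counts circle neighbours among all neighbours", {
  fx <- pr_fixture()
  pr <- precision_recall(fx$layout, fx$network, "i", r = 3)
  expect_equal(unname(pr["R"]), 3 / 7)
  # a circle containing everything has full recall
  pr_all <- precision_recall(fx$layout, fx$network, "i", r = 100)
  expect_equal(unname(pr_all["R"]), 1)
})

test_that("precision/recall rejects degree-0 nodes", {
  g <- igraph::add_vertices(graph_from_pairs("a", "b"), 1L,
                            attr = list(name = "z"))
  lay <- grid_layout(rbind(a = c(0, 0), b = c(1, 0), z = c(5, 5)))
  expect_error(precision_recall(lay, g, "z", 2), "degree-0")
})

test_that("the F-measure combines precision and recall harmonically", {
  expect_equal(f_measure(3 / 8, 3 / 7, alpha = 0.5), 0.4)
  expect_equal(f_measure(1, 1), 1)
  expect_equal(f_measure(0, 1), 0)
})

test_that("a perfectly separated neighbourhood scores F = 1", {
  # star whose neighbours are the closest ring: optimal circle holds
  # exactly the neighbours
  pos <- rbind(c0 = c(0, 0), a = c(1, 0), b = c(0, 1), c = c(-1, 0),
               far1 = c(9, 9), far2 = c(9, -9))
  g <- graph_from_pairs("c0", "a", "c0", "b", "c0", "c", "far1", "far2")
  lay <- grid_layout(pos)
  d <- sqrt((pos[, 1])^2 + (pos[, 2])^2)
  fi <- f_measure(3 / 3, 3 / 3)
  expect_equal(fi, 1)
  # and the layout-level maximization finds it for node c0
  pr <- precision_recall(lay, g, "c0", r = 1)
  expect_equal(unname(pr["P"]), 1)
  expect_equal(unname(pr["R"]), 1)
})

test_that("connectivity F-measure is invariant under isometries", {
  net <- generate_modular_network(c(6, 6), 0.6, 0.1, seed = 9)
  set.seed(2)
  lay <- random_grid_layout(igraph::V(net$network)$name, 8, 8)
  f0 <- connectivity_f_measure(lay, net$network)
  expect_gte(f0, 0)
  expect_lte(f0, 1)
  # translation
  expect_equal(connectivity_f_measure(translate_layout(lay, 13, -4),
                                      net$network), f0)
  # 90-degree rotation (x, y) -> (-y, x)
  rot <- lay
  rot$pos <- cbind(x = -lay$pos[, 2], y = lay$pos[, 1])
  rownames(rot$pos) <- rownames(lay$pos)
  expect_equal(connectivity_f_measure(rot, net$network), f0)
})

test_that("relative edge length follows the bounding-box convention", {
  g <- graph_from_pairs("a", "b")
  lay <- grid_layout(rbind(a = c(0, 0), b = c(3, 0)))
  expect_equal(relative_edge_length(lay, g), 3 / (4 * 1 * 1))
  # a far-away isolated node grows the area and shrinks the value
  g2 <- igraph::add_vertices(g, 1L, attr = list(name = "z"))
  lay2 <- grid_layout(rbind(a = c(0, 0), b = c(3, 0), z = c(0, 9)))
  expect_lt(relative_edge_length(lay2, g2), relative_edge_length(lay, g))
  # translation invariance
  expect_equal(relative_edge_length(translate_layout(lay, -7, 11), g),
               relative_edge_length(lay, g))
  # edgeless network errors
  g0 <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(g0)$name <- c("a", "b")
  expect_error(relative_edge_length(lay, g0), "edge")
})

test_that("edge-edge crossings follow the open-segment rule", {
  # an X: one crossing pair
  g <- graph_from_pairs("a", "b", "c", "d")
  lay <- grid_layout(rbind(a = c(0, 0), b = c(2, 2), c = c(0, 2),
                           d = c(2, 0)))
  expect_equal(edge_edge_crossing_ratio(lay, g), 1)
  # sharing an endpoint never counts
  g2 <- graph_from_pairs("a", "b", "a", "c")
  lay2 <- grid_layout(rbind(a = c(0, 0), b = c(2, 2), c = c(2, 0)))
  expect_equal(edge_edge_crossing_ratio(lay2, g2), 0)
  # disjoint parallel segments
  lay3 <- grid_layout(rbind(a = c(0, 0), b = c(2, 0), c = c(0, 1),
                            d = c(2, 1)))
  expect_equal(edge_edge_crossing_ratio(lay3, g), 0)
  # collinear overlap counts once
  lay4 <- grid_layout(rbind(a = c(0, 0), b = c(3, 0), c = c(1, 0),
                            d = c(4, 0)))
  expect_equal(edge_edge_crossing_ratio(lay4, g), 1)
  # endpoint touching an interior point counts
  lay5 <- grid_layout(rbind(a = c(0, 0), b = c(2, 0), c = c(1, 0),
                            d = c(1, 2)))
  expect_equal(edge_edge_crossing_ratio(lay5, g), 1)
  expect_error(edge_edge_crossing_ratio(lay, graph_from_pairs("a", "b")),
               "two edges")
})

test_that("node-edge crossings respect the proximity threshold", {
  g <- graph_from_pairs("a", "b")
  # node on the segment interior counts: pairs = n*m - 2m = 1
  lay <- grid_layout(rbind(a = c(0, 0), b = c(2, 0), z = c(1, 0)))
  gz <- igraph::add_vertices(g, 1L, attr = list(name = "z"))
  expect_equal(node_edge_crossing_ratio(lay, gz), 1)
  # far-away node does not
  lay2 <- grid_layout(rbind(a = c(0, 0), b = c(2, 0), z = c(5, 5)))
  expect_equal(node_edge_crossing_ratio(lay2, gz), 0)
  # an edge's own endpoints never count even though distance is zero
  lay3 <- grid_layout(rbind(a = c(0, 0), b = c(2, 0)))
  expect_equal(node_edge_crossing_ratio(lay3, g), 0)
})

test_that("metric bundle is deterministic and translation-invariant", {
  net <- generate_modular_network(c(6, 6), 0.6, 0.1, seed = 10)
  set.seed(3)
  lay <- random_grid_layout(igraph::V(net$network)$name, 9, 9)
  m1 <- layout_metrics(lay, net$network)
  m2 <- layout_metrics(lay, net$network)
  expect_identical(m1, m2)
  m3 <- layout_metrics(translate_layout(lay, 4, 4), net$network)
  expect_equal(m1, m3)
  expect_true(all(unlist(m1[c("connectivity_f", "edge_edge_ratio",
                              "node_edge_ratio")]) >= 0))
  expect_true(all(unlist(m1[c("connectivity_f", "edge_edge_ratio",
                              "node_edge_ratio")]) <= 1))
})
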