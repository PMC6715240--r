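test_that("node weights follow the path-length scheme", {
  # path a-b-c-d-e, all one module: lengths 1, 2, >=3
  g <- graph_from_pairs("a", "b", "b", "c", "c", "d", "d", "e")
  w <- set_node_weight(g, one_module_assignment(g))
  expect_equal(w["a", "b"], 40)
  expect_equal(w["a", "c"], 0)
  expect_equal(w["a", "d"], -10)
  expect_equal(w["a", "e"], -10)
  expect_true(isSymmetric(unname(w)))
  expect_equal(unname(diag(w)), rep(0, 5))
})

test_that("unreachable pairs repel like distant pairs", {
  g <- graph_from_pairs("a", "b", "c", "d")
  w <- set_node_weight(g, one_module_assignment(g))
  expect_equal(w["a", "c"], -10)
})

test_that("inter-module adjacent pairs gain the extra weight on top", {
  g <- graph_from_pairs("a", "b", "b", "c")
  asg <- module_assignment(c(a = "A", b = "A", c = "B"))
  w <- set_node_weight(g, asg)
  expect_equal(w["a", "b"], 40)    # intra, length 1
  expect_equal(w["b", "c"], 80)    # inter, length 1: 40 base + 40 extra
  expect_equal(w["a", "c"], 0)     # inter, length 2: base only
  w0 <- set_node_weight(g, asg, extra_weight = 0)
  expect_equal(w0["b", "c"], 40)
  expect_equal(w["b", "c"] - w0["b", "c"], 40)
})

test_that("custom base weights flow through", {
  g <- path_graph_abc()
  w <- set_node_weight(g, one_module_assignment(g),
                       base_weights = c(7, 1, -2), extra_weight = 0)
  expect_equal(w["a", "b"], 7)
  expect_equal(w["a", "c"], 1)
})

test_that("node optimization stays inside regions and beats its start", {
  net <- generate_modular_network(c(8, 8), p_in = 0.7, p_out = 0.1,
                                  seed = 21)
  asg <- net$assignment
  rmod <- layout_modules(set_module_weight(
    count_intermodule_edges(net$network, asg)),
    optimizer_params(niter = 30, seed = 2))
  reg <- expand_modules(rmod, asg)
  w <- set_node_weight(net$network, asg)
  out <- optimize_nodes(net$network, w, reg, asg,
                        optimizer_params(niter = 60, seed = 3))
  # containment per node
  for (m in reg$module) {
    r <- reg[reg$module == m, ]
    p <- out$pos[asg$modules[[m]], , drop = FALSE]
    expect_true(all(p[, 1] >= r$x0 & p[, 1] <= r$x0 + r$side - 1))
    expect_true(all(p[, 2] >= r$y0 & p[, 2] <= r$y0 + r$side - 1))
  }
  # global injectivity
  expect_equal(anyDuplicated(paste(out$pos[, 1], out$pos[, 2])), 0L)
  # not worse than the seeded random initial layout it started from
  set.seed(3)
  init_pos <- out$pos
  for (m in reg$module) {
    pts <- region_points(reg, m)
    members <- asg$modules[[m]]
    init_pos[members, ] <- pts[sample.int(nrow(pts), length(members)), ]
  }
  expect_lte(layout_cost(w, out), layout_cost(w, grid_layout(init_pos)))
})

test_that("region capacity violations abort before optimization", {
  g <- graph_from_pairs("a", "b", "b", "c", "a", "c", "a", "d", "b", "d")
  asg <- one_module_assignment(g)
  reg <- data.frame(module = "M1", x0 = 0L, y0 = 0L, side = 1L)
  class(reg) <- c("module_regions", "data.frame")
  expect_error(optimize_nodes(g, set_node_weight(g, asg), reg, asg),
               "capacity")
})

test_that("two bridged single-node modules meet at facing borders", {
  g <- graph_from_pairs("a", "b")
  asg <- module_assignment(c(a = "A", b = "B"))
  rmod <- layout_modules(weight_matrix(c("A", "B"), rbind(c("A", "B", 1))),
                         optimizer_params(niter = 30, seed = 6))
  reg <- expand_modules(rmod, asg)
  w <- set_node_weight(g, asg)
  out <- optimize_nodes(g, w, reg, asg,
                        optimizer_params(niter = 40, seed = 6))
  # oracle: minimum Manhattan distance over both regions' point sets
  pa <- region_points(reg, "A")
  pb <- region_points(reg, "B")
  dmin <- min(abs(outer(pa[, 1], pb[, 1], "-")) +
                abs(outer(pa[, 2], pb[, 2], "-")))
  expect_equal(manhattan(out$pos["a", ], out$pos["b", ]), dmin)
})

test_that("the extra weight pulls bridge endpoints together", {
  d_gml <- numeric(10)
  d_rand <- numeric(10)
  for (s in 1:10) {
    fix <- bridged_two_module_network(size = 10, seed = 300 + s)
    rmod <- layout_modules(set_module_weight(
      count_intermodule_edges(fix$network, fix$assignment)),
      optimizer_params(niter = 30, seed = s))
    reg <- expand_modules(rmod, fix$assignment)
    w <- set_node_weight(fix$network, fix$assignment)
    out <- optimize_nodes(fix$network, w, reg, fix$assignment,
                          optimizer_params(niter = 150, seed = s))
    d_gml[s] <- manhattan(out$pos[fix$bridge[1], ],
                          out$pos[fix$bridge[2], ])
    # baseline: random placements of the two endpoints in their regions
    set.seed(1000 + s)
    m1 <- fix$assignment$module_of[fix$bridge[1]]
    m2 <- fix$assignment$module_of[fix$bridge[2]]
    p1 <- region_points(reg, m1)
    p2 <- region_points(reg, m2)
    d_rand[s] <- mean(vapply(1:100, function(k) {
      a <- p1[sample.int(nrow(p1), 1), ]
      b <- p2[sample.int(nrow(p2), 1), ]
      manhattan(a, b)
    }, numeric(1)))
  }
  expect_lte(mean(d_gml), mean(d_rand))
})

test_that("disabling the extra weight does not reduce edge crossings", {
  ratio_on <- numeric(10)
  ratio_off <- numeric(10)
  for (s in 1:10) {
    net <- generate_modular_network(c(10, 10), p_in = 0.5, p_out = 0.05,
                                    seed = 400 + s)
    asg <- net$assignment
    rmod <- layout_modules(set_module_weight(
      count_intermodule_edges(net$network, asg)),
      optimizer_params(niter = 30, seed = s))
    reg <- expand_modules(rmod, asg)
    for (extra in c(40, 0)) {
      w <- set_node_weight(net$network, asg, extra_weight = extra)
      out <- optimize_nodes(net$network, w, reg, asg,
                            optimizer_params(niter = 150, seed = s))
      r <- edge_edge_crossing_ratio(out, net$network)
      if (extra == 40) ratio_on[s] <- r else ratio_off[s] <- r
    }
  }
  expect_gte(mean(ratio_off), mean(ratio_on))
})
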