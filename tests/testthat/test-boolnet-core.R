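test_that("bnet parsing builds the declared network and interaction graph", {
  net <- parse_network("targets, factors\nA, B\nB, A\nC, A & B")
  expect_equal(net$nodes, c("A", "B", "C"))
  e <- interaction_edges(net)
  expect_setequal(paste(e[, 1], e[, 2]),
                  c("B A", "A B", "A C", "B C"))

  neg <- parse_network("A, !A")
  expect_equal(unname(interaction_edges(neg)[1, ]), c("A", "A"))

  expect_error(parse_network("A, B & X\nB, A"), "undeclared")
  expect_error(parse_network("A, B\nA, !B\nB, A"), "duplicate")
  expect_error(parse_network("A, B &\nB, A"), "line 1")
})

test_that("pyexpr dialect parses and both dialects round-trip rule-equivalently", {
  py <- parse_network(c("A = B and not C", "B = A or C", "C = not A"),
                      dialect = "pyexpr")
  bn <- parse_network("A, B & !C\nB, A | C\nC, !A")
  expect_equal(py$tt, bn$tt)
  expect_equal(py$inputs, bn$inputs)

  for (net in list(toy_net(), py, parse_network("A, A | !A\nB, 0"))) {
    for (d in c("bnet", "pyexpr")) {
      back <- parse_network(write_network(net, d), dialect = d)
      expect_equal(back$nodes, net$nodes)
      expect_equal(back$tt, net$tt)   # truth-table equivalence per node
    }
  }
})

test_that("synchronous update follows rules and pins override them", {
  net <- toy_net()
  expect_identical(synchronous_update(net, c(1, 0, 0)), c(0L, 1L, 0L))
  expect_identical(synchronous_update(net, c(1, 1, 1)), c(1L, 1L, 1L))
  expect_identical(synchronous_update(net, c(0, 0, 0), pins = c(C = 1)),
                   c(0L, 0L, 1L))
  expect_error(synchronous_update(net, c(1, 0)), "every node")
  expect_error(synchronous_update(net, c(1, 0, 0), pins = c(Z = 1)), "unknown")
})

test_that("exhaustive attractors match the hand-derived landscape of the toy net", {
  atts <- find_attractors_exhaustive(toy_net())
  expect_length(atts, 3)
  expect_equal(vapply(atts, `[[`, character(1), "key"),
               c("000", "010", "111"))
  expect_equal(vapply(atts, `[[`, logical(1), "is_point"),
               c(TRUE, FALSE, TRUE))
  expect_equal(vapply(atts, `[[`, numeric(1), "basin_ratio"),
               c(0.25, 0.5, 0.25))
  # cycle states follow the update map
  cyc <- atts[[2]]
  expect_identical(synchronous_update(toy_net(), cyc$states[[1]]),
                   cyc$states[[2]])
  expect_identical(synchronous_update(toy_net(), cyc$states[[2]]),
                   cyc$states[[1]])
})

test_that("negation loop yields a single cyclic attractor with basin 1", {
  atts <- find_attractors_exhaustive(parse_network("A, !A"))
  expect_length(atts, 1)
  expect_false(atts[[1]]$is_point)
  expect_equal(atts[[1]]$basin_ratio, 1)
})

test_that("pinned attractors restrict the state space", {
  atts <- find_attractors_exhaustive(toy_net(), pins = c(A = 1))
  expect_length(atts, 1)
  expect_true(atts[[1]]$is_point)
  expect_equal(atts[[1]]$key, "111")
})

test_that("exhaustive attractors agree with the trajectory-walking oracle", {
  for (net in fixture_nets(8)) {
    got <- find_attractors_exhaustive(net)
    want <- oracle_attractors(net)
    expect_length(got, length(want))
    got_keys <- lapply(got, function(a)
      sort(vapply(a$states, function(s) paste(s, collapse = ""), character(1))))
    expect_equal(got_keys, lapply(want, `[[`, "states"))
    expect_equal(vapply(got, `[[`, numeric(1), "basin_ratio"),
                 vapply(want, `[[`, numeric(1), "basin_ratio"))
  }
})

test_that("basin ratios always sum to one", {
  for (net in fixture_nets(10)) {
    for (pins in list(NULL, stats::setNames(1L, net$nodes[1]))) {
      atts <- find_attractors_exhaustive(net, pins)
      expect_equal(sum(vapply(atts, `[[`, numeric(1), "basin_ratio")), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("hierarchical fixed points equal exhaustive point attractors", {
  expect_equal(vapply(find_point_attractors_hierarchical(toy_net()),
                      function(s) paste(s, collapse = ""), character(1)),
               c("000", "111"))
  for (net in fixture_nets(25)) {
    fp <- vapply(find_point_attractors_hierarchical(net),
                 function(s) paste(s, collapse = ""), character(1))
    pa <- vapply(point_attractors(net), `[[`, character(1), "key")
    expect_identical(fp, sort(pa))
  }
  # acyclic network with pinned source: unique percolated fixed point
  chain <- parse_network("S, S\nB, S\nC, !B")
  fp <- find_point_attractors_hierarchical(chain, pins = c(S = 1))
  expect_length(fp, 1)
  expect_identical(fp[[1]], c(1L, 1L, 0L))
})

test_that("state-space limits raise typed errors", {
  net <- toy_net()
  expect_error(find_attractors_exhaustive(net, limit = 2),
               class = "dcgs_state_space_too_large")
  expect_error(find_point_attractors_hierarchical(
    parse_network("A, B\nB, A"), scc_limit = 1),
    class = "dcgs_scc_too_large")
})
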