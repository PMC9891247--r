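pin_names <- function(sets) lapply(sets, function(cs) names(cs$pins))

test_that("brute-force CK finds all minimal kernels on the toy net", {
  net <- toy_net()
  for (target in list(c(1, 1, 1), c(0, 0, 0))) {
    cks <- brute_force_ck(net, target)
    expect_equal(pin_names(cks), list("A", "B"))
    expect_equal(vapply(cks, `[[`, integer(1), "size"), c(1L, 1L))
    expect_equal(unname(cks[[1]]$pins), target[1])
  }
})

test_that("a monostable network has the empty set as its control kernel", {
  net <- parse_network("S, 0\nB, S")
  cks <- brute_force_ck(net, c(0, 0))
  expect_equal(pin_names(cks), list(character(0)))
  expect_equal(cks[[1]]$size, 0L)
})

test_that("target validation rejects non-attractors and cyclic attractors", {
  net <- toy_net()
  expect_error(brute_force_ck(net, c(1, 0, 1)),
               class = "dcgs_target_not_point")
  cyc <- find_attractors_exhaustive(net)[[2]]   # the 2-cycle
  expect_error(dcgs(net, cyc), class = "dcgs_cyclic_target")
  expect_error(brute_force_ck(net, c(1, 1, 1), pre_pins = c(A = 0)),
               class = "dcgs_target_not_point")
})

test_that("FC control pins a minimal FVS plus source nodes", {
  fcs <- fvs_control_set(toy_net(), c(1, 1, 1))
  expect_equal(pin_names(fcs), list("A", "B"))
  expect_equal(vapply(fcs, `[[`, integer(1), "size"), c(1L, 1L))

  acyc <- parse_network("S, 1\nB, S\nC, B")
  fcs <- fvs_control_set(acyc, c(1, 1, 1))
  expect_equal(pin_names(fcs), list("S"))
  expect_equal(fcs[[1]]$size, 0L)   # FVS empty; sources excluded from size
})

test_that("canalizing-set search on the toy net and size-0 success", {
  net <- toy_net()
  expect_equal(canalizing_sets_for_fvs(net, "A", c(1, 1, 1)), list("A"))
  # pre-pinned A already percolates the FVS {B}: empty canalizing set
  expect_equal(canalizing_sets_for_fvs(net, "B", c(1, 1, 1),
                                       pre_pins = c(A = 1)),
               list(character(0)))
  expect_error(canalizing_sets_for_fvs(net, "A", c(1, 1, 1),
                                       pre_pins = c(A = 0)),
               class = "dcgs_impossible_target")
})

test_that("FVS classification separates canalizing, canalized and monostable", {
  # no monostable: classification coincides with the canalizing-set search
  cl <- classify_fvs(toy_net(), "A", c(1, 1, 1))
  expect_equal(cl$canalizing, "A")
  expect_equal(cl$canalized, character(0))
  expect_equal(cl$monostable, character(0))

  # unconditional monostable node (consistent even without pinning)
  net <- mono_unconditional_net()
  atts <- find_attractors_exhaustive(net)
  expect_equal(vapply(atts, `[[`, character(1), "key"), c("001", "101"))
  expect_equal(minimal_fvs(net), list(c("A", "M")))
  cl <- classify_fvs(net, c("A", "M"), c(1, 0, 1))
  expect_equal(cl$canalizing, "A")
  expect_equal(cl$monostable, "M")
  expect_true(cl$unconditional[["M"]])

  # conditional monostable node (consistent only once A is pinned)
  net <- mono_conditional_net()
  atts <- find_attractors_exhaustive(net)
  expect_equal(vapply(atts, `[[`, character(1), "key"),
               c("001", "101", "111"))
  cl <- classify_fvs(net, c("A", "M"), c(0, 0, 1))
  expect_equal(cl$canalizing, "A")
  expect_equal(cl$monostable, "M")
  expect_false(cl$unconditional[["M"]])
})

test_that("DCGS equals brute-force CK on the toy net and pays for monostable nodes", {
  ds <- dcgs(toy_net(), c(1, 1, 1))
  expect_equal(pin_names(ds), list("A", "B"))
  expect_equal(vapply(ds, `[[`, integer(1), "size"), c(1L, 1L))

  # fully acyclic network: control set = source pins only, size 0
  acyc <- parse_network("S, 1\nB, S\nC, B")
  ds <- dcgs(acyc, c(1, 1, 1))
  expect_equal(pin_names(ds), list("S"))
  expect_equal(ds[[1]]$size, 0L)

  # monostable node M is not percolation-fixable: DCGS pins it, CK does not
  net <- mono_unconditional_net()
  ck <- brute_force_ck(net, c(1, 0, 1))
  ds <- dcgs(net, c(1, 0, 1))
  expect_equal(ck[[1]]$size, 1L)
  expect_equal(ds[[1]]$size, 2L)    # = |CK| + |monostable|
  expect_true(validate_global_stabilization(net, ds[[1]])$stabilizes)
})

test_that("DCGS on a single-SCC network equals whole-network canalizing sets", {
  net <- parse_network("A, C\nB, A\nC, B")
  target <- c(1, 1, 1)
  ds <- dcgs(net, target)
  whole <- unlist(lapply(minimal_fvs(net), function(f)
    canalizing_sets_for_fvs(net, f, target)), recursive = FALSE)
  whole <- whole[lengths(whole) == min(lengths(whole))]
  expect_setequal(vapply(pin_names(ds), paste, character(1), collapse = "|"),
                  vapply(whole, paste, character(1), collapse = "|"))
  # and it matches the CK oracle here
  expect_equal(vapply(ds, `[[`, integer(1), "size"),
               rep(brute_force_ck(net, target)[[1]]$size, length(ds)))
})

test_that("first_only returns the canonical single DCGS set", {
  ds <- dcgs(toy_net(), c(1, 1, 1), first_only = TRUE)
  expect_length(ds, 1)
  expect_equal(names(ds[[1]]$pins), "A")
})

test_that("validation reports counterexamples for insufficient pin sets", {
  net <- toy_net()
  v <- validate_global_stabilization(net, stats::setNames(integer(0),
                                                          character(0)),
                                     target = c(1, 1, 1))
  expect_false(v$stabilizes)
  expect_false(is.null(v$counterexample))
  ck <- brute_force_ck(net, c(1, 1, 1))[[1]]
  expect_true(validate_global_stabilization(net, ck)$stabilizes)
})

test_that("framework invariants hold on a small fixture batch", {
  for (net in fixture_nets(6)) {
    fvss <- minimal_fvs(net)
    for (a in point_attractors(net)) {
      t <- a$states[[1]]
      ck <- brute_force_ck(net, t)
      fc <- fvs_control_set(net, t)
      expect_lte(ck[[1]]$size, fc[[1]]$size)     # CK <= FC, universal
      for (cs in fc)                             # FC always stabilizes
        expect_true(validate_global_stabilization(net, cs)$stabilizes)
      ds <- dcgs(net, t)
      mono <- max(vapply(fvss, function(f)
        length(classify_fvs(net, f, t)$monostable), integer(1)))
      ok <- vapply(ds, function(cs)
        validate_global_stabilization(net, cs)$stabilizes, logical(1))
      if (mono == 0) expect_true(all(ok))
    }
  }
})
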