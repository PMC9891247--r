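# Shared fixtures. Small hand-built models with hand-derived dynamics,
# plus a lazily generated, cached batch of 100 biological random Boolean
# networks (the stated fixture world: n = 10, gamma = 2.5, lambda = 1.75,
# >= 2 point attractors, seeds 1..100) and a per-attractor analysis table
# reused by the acceptance suite.

# Two-node positive loop feeding an AND gate. Attractors (hand-derived):
# points 000 and 111, cycle {010, 100}; basins 2/8, 2/8, 4/8.
toy_net <- function() {
  boolean_network(c("A", "B", "C"), c(A = "B", B = "A", C = "A & B"))
}

# Unconditional-monostable analogue: A is an isolated self-loop switch
# (two point attractors differing only in A); M is an FVS node that holds
# value 0 in every attractor but is never percolation-fixed.
# Attractors (hand-derived): (A,M,B) = 001 and 101.
mono_unconditional_net <- function() {
  boolean_network(c("A", "M", "B"), c(A = "A", M = "M & B", B = "!M"))
}

# Conditional-monostable analogue: M is consistent only once A is pinned
# to 0. Attractors (hand-derived): (A,M,B) = 001, 101, 111.
mono_conditional_net <- function() {
  boolean_network(c("A", "M", "B"), c(A = "A", M = "M & B", B = "!M | A"))
}

# n/2 independent toggle pairs (a_i <-> b_i): 2^(n/2) fixed points, SCCs
# of size 2; handy for exercising limits without a large state space.
toggle_chain_net <- function(n) {
  stopifnot(n %% 2 == 0)
  nodes <- paste0(rep(c("a", "b"), n / 2), rep(seq_len(n / 2), each = 2))
  rules <- stats::setNames(nodes[order(seq_len(n) + c(1, -1))], nodes)
  boolean_network(nodes, rules)
}

fixture_cfg <- function() rbn_config()   # the stated world: all defaults

.fixture_env <- new.env(parent = emptyenv())

# First `k` fixture networks (seeds 1..k), generated once per test run.
fixture_nets <- function(k = 100L) {
  if (is.null(.fixture_env$nets)) .fixture_env$nets <- list()
  have <- length(.fixture_env$nets)
  if (have < k) {
    cfg <- fixture_cfg()
    for (i in (have + 1L):k)
      .fixture_env$nets[[i]] <- generate_biological_random_network(cfg, seed = i)
  }
  .fixture_env$nets[seq_len(k)]
}

# Per-attractor analysis over the full fixture batch: CK / FC / DCGS
# sizes, validation, CK-in-FVS inclusion and monostable statistics.
# Computed once and cached; this is the workhorse of test-acceptance.R.
fixture_analysis <- function() {
  if (!is.null(.fixture_env$analysis)) return(.fixture_env$analysis)
  nets <- fixture_nets(100L)
  rows <- list()
  for (i in seq_along(nets)) {
    net <- nets[[i]]
    fvss <- minimal_fvs(net)
    for (a in point_attractors(net)) {
      t <- a$states[[1]]
      cks <- brute_force_ck(net, t)
      fcs <- fvs_control_set(net, t)
      fc_valid <- all(vapply(fcs, function(cs)
        validate_global_stabilization(net, cs)$stabilizes, logical(1)))
      inc <- any(vapply(cks, function(ck)
        any(vapply(fvss, function(f) all(names(ck$pins) %in% f), logical(1))),
        logical(1)))
      cls <- lapply(fvss, function(f) classify_fvs(net, f, t))
      mono_max <- max(vapply(cls, function(cl)
        length(cl$monostable), integer(1)))
      ds <- dcgs(net, t)
      d_valid <- all(vapply(ds, function(cs)
        validate_global_stabilization(net, cs)$stabilizes, logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        net = i, target = a$key,
        ck_size = cks[[1]]$size, n_cks = length(cks),
        fc_size = fcs[[1]]$size, fc_valid = fc_valid,
        ck_in_fvs = inc, mono_max = mono_max,
        dcgs_size = ds[[1]]$size, dcgs_valid = d_valid,
        stringsAsFactors = FALSE)
    }
  }
  .fixture_env$analysis <- do.call(rbind, rows)
  .fixture_env$analysis
}
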