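# Independent oracles used to cross-check package operations. These
# deliberately avoid the code paths they validate: the attractor oracle
# walks trajectories one synchronous_update() step at a time with no
# successor-map machinery; the acyclicity oracle is a plain DFS; the
# determination oracle enumerates completions by evaluating the rule
# expression directly.

# Trajectory-walking attractor finder with basin counts.
# Returns list of list(states = character keys in cycle, basin_ratio).
oracle_attractors <- function(net, pins = NULL) {
  n <- length(net$nodes)
  free <- setdiff(net$nodes, names(unlist(pins)))
  m <- length(free)
  all_states <- lapply(0:(2^m - 1), function(id) {
    s <- stats::setNames(integer(n), net$nodes)
    if (length(pins)) s[names(unlist(pins))] <- as.integer(unlist(pins))
    s[free] <- bitwAnd(bitwShiftR(id, seq_len(m) - 1L), 1L)
    unname(s[net$nodes])
  })
  key <- function(s) paste(s, collapse = "")
  att_of <- character(0)     # state key -> attractor key
  cycles <- list()           # attractor key -> sorted cycle keys
  for (s0 in all_states) {
    path <- character(0)
    s <- s0
    repeat {
      k <- key(s)
      if (!is.na(att_of[k])) { hit <- att_of[k]; break }
      if (k %in% path) {      # new cycle discovered
        cyc <- path[seq(match(k, path), length(path))]
        hit <- min(cyc)
        cycles[[hit]] <- sort(cyc)
        break
      }
      path <- c(path, k)
      s <- synchronous_update(net, s, pins = pins)
    }
    att_of[path] <- hit
  }
  counts <- table(att_of[vapply(all_states, key, character(1))])
  lapply(sort(names(cycles)), function(ak)
    list(states = cycles[[ak]], basin_ratio = unname(counts[ak]) / 2^m))
}

# DFS-based cycle test on a 2-column character edge matrix after removing
# `removed` nodes. TRUE iff acyclic; self-loops count as cycles.
oracle_is_acyclic <- function(edges, nodes, removed = character(0)) {
  nodes <- setdiff(nodes, removed)
  keep <- edges[, 1] %in% nodes & edges[, 2] %in% nodes
  edges <- edges[keep, , drop = FALSE]
  if (any(edges[, 1] == edges[, 2])) return(FALSE)
  adj <- split(edges[, 2], factor(edges[, 1], levels = nodes))
  color <- stats::setNames(rep(0L, length(nodes)), nodes)  # 0 new 1 open 2 done
  has_cycle <- FALSE
  visit <- function(v) {
    color[v] <<- 1L
    for (w in adj[[v]]) {
      if (color[w] == 1L) { has_cycle <<- TRUE; return() }
      if (color[w] == 0L) visit(w)
      if (has_cycle) return()
    }
    color[v] <<- 2L
  }
  for (v in nodes) {
    if (color[v] == 0L) visit(v)
    if (has_cycle) return(FALSE)
  }
  TRUE
}

# Determination oracle: enumerate every completion of the unfixed inputs
# and evaluate the node's rule expression directly.
oracle_determined <- function(net, node, fixed) {
  j <- match(node, net$nodes)
  vars <- all.vars(net$rules[[j]])
  open <- setdiff(vars, names(fixed))
  vals <- integer(0)
  grid <- if (length(open)) expand.grid(rep(list(0:1), length(open)))
  else data.frame(row.names = 1)
  for (r in seq_len(nrow(grid))) {
    env <- as.list(fixed)
    if (length(open)) env[open] <- as.list(as.integer(grid[r, ]))
    vals <- c(vals, as.integer(as.logical(
      eval(net$rules[[j]], envir = env, enclos = baseenv()))))
  }
  if (length(unique(vals)) == 1L) vals[1] else NA_integer_
}

# Random simple digraph as an edge matrix (for structure property tests).
random_digraph <- function(n, p = 0.2) {
  nodes <- paste0("v", seq_len(n))
  pairs <- expand.grid(from = nodes, to = nodes, stringsAsFactors = FALSE)
  pick <- stats::runif(nrow(pairs)) < p
  list(nodes = nodes, edges = as.matrix(pairs[pick, , drop = FALSE]))
}

edges_to_igraph <- function(nodes, edges) {
  igraph::graph_from_data_frame(as.data.frame(edges), directed = TRUE,
                                vertices = data.frame(name = nodes))
}
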