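# Synchronous dynamics: single-step update, state transition graph over the
# free (unpinned) nodes, exhaustive attractor/basin computation and a
# hierarchical (SCC-by-SCC) fixed-point enumerator for larger models.
#
# Internal state encoding: a state of the m free nodes is an integer id in
# 0..2^m-1 with bit i (0-based) holding the value of the i-th free node in
# canonical declaration order. All user-facing states are full-length 0/1
# vectors in declaration order.

#' Synchronous update of a network state
#'
#' Every unpinned node takes the value of its Boolean rule evaluated on the
#' current state; pinned nodes keep their pinned value regardless of their
#' rule (persistent control input semantics).
#'
#' @param net a `boolean_network`
#' @param state 0/1 vector in node order (or 0/1 string)
#' @param pins optional named list/vector `node = 0/1` of persistent pins
#' @return integer 0/1 vector, the successor state
#' @export
synchronous_update <- function(net, state, pins = NULL) {
  s <- normalize_state(net, state)
  p <- normalize_pins(net, pins)
  out <- integer(length(s))
  for (j in seq_along(s)) {
    key <- sum(s[net$inputs[[j]]] * bitwShiftL(1L, seq_along(net$inputs[[j]]) - 1L))
    out[j] <- net$tt[[j]][key + 1L]
  }
  if (length(p)) out[match(names(p), net$nodes)] <- unname(p)
  out
}

# Build the synchronous successor map over free nodes under pins.
# Returns list(free = integer indices of free nodes, pins = named int,
# succ = integer vector, succ[id+1] = successor id (0-based ids)).
successor_map <- function(net, pins = NULL,
                          limit = getOption("dcgs.exhaustive_limit", 22L)) {
  p <- normalize_pins(net, pins)
  pin_idx <- match(names(p), net$nodes)
  free <- setdiff(seq_along(net$nodes), pin_idx)
  m <- length(free)
  if (m > limit)
    stop(structure(class = c("dcgs_state_space_too_large", "error", "condition"),
                   list(message = sprintf(
                     "state space 2^%d exceeds exhaustive limit of 2^%d free nodes; raise options(dcgs.exhaustive_limit=) or pin more nodes",
                     m, limit), call = NULL)))
  ids <- 0:(2^m - 1)
  pos <- integer(length(net$nodes))          # bit position of each free node
  pos[free] <- seq_len(m) - 1L
  pinval <- integer(length(net$nodes))
  pinval[pin_idx] <- unname(p)
  is_free <- rep(FALSE, length(net$nodes)); is_free[free] <- TRUE
  succ <- integer(length(ids))
  for (j in free) {
    ins <- net$inputs[[j]]
    key <- 0L
    for (i in seq_along(ins)) {
      u <- ins[i]
      bit <- if (is_free[u]) bitwAnd(bitwShiftR(ids, pos[u]), 1L) else pinval[u]
      key <- key + bit * bitwShiftL(1L, i - 1L)
    }
    val <- net$tt[[j]][key + 1L]
    succ <- succ + val * bitwShiftL(1L, pos[j])
  }
  list(free = free, pins = p, succ = succ)
}

# Expand a free-state id to a full 0/1 state vector.
expand_state <- function(net, sm, id) {
  s <- integer(length(net$nodes))
  if (length(sm$pins)) s[match(names(sm$pins), net$nodes)] <- unname(sm$pins)
  m <- length(sm$free)
  if (m) s[sm$free] <- bitwAnd(bitwShiftR(id, seq_len(m) - 1L), 1L)
  s
}

# Attractor decomposition of a deterministic successor array.
# succ: 0-based successor ids. Returns list(att = per-state attractor index,
# cycles = list of integer id vectors, each a cycle in transition order).
attractor_components <- function(succ) {
  N <- length(succ)
  s1 <- succ + 1L                       # 1-based
  r <- s1
  steps <- max(1L, ceiling(log2(N)))
  for (i in seq_len(steps)) r <- r[r]   # r = f^(2^steps) >= f^N: on-cycle
  cyc_id <- integer(N)                  # 0 = not yet assigned
  cycles <- list()
  for (t in unique(r)) {
    if (cyc_id[t] > 0L) next
    k <- length(cycles) + 1L
    cur <- t
    cyc <- integer(0)
    repeat {
      cyc_id[cur] <- k
      cyc <- c(cyc, cur)
      cur <- s1[cur]
      if (cur == t) break
    }
    cycles[[k]] <- cyc - 1L
  }
  list(att = cyc_id[r], cycles = cycles)
}

#' Exhaustively compute all attractors and basin ratios
#'
#' Builds the full synchronous state transition graph over the free
#' (unpinned) nodes and decomposes it into attractors (point and cyclic)
#' with exact basin ratios. Attractors are reported in canonical order:
#' sorted by the 0/1 string of their lexicographically smallest state, and
#' each cycle is rotated to start at that state.
#'
#' @inheritParams synchronous_update
#' @param pins optional named pins restricting the state space
#' @param limit maximum number of free nodes (default
#'   `getOption("dcgs.exhaustive_limit", 22)`); beyond it a
#'   `dcgs_state_space_too_large` error is raised
#' @return list of attractor objects, each a list with `states` (list of
#'   full 0/1 vectors), `is_point`, `basin_ratio`, and `key` (the canonical
#'   state string identifying the attractor)
#' @export
find_attractors_exhaustive <- function(net, pins = NULL,
                                       limit = getOption("dcgs.exhaustive_limit", 22L)) {
  sm <- successor_map(net, pins, limit = limit)
  ac <- attractor_components(sm$succ)
  basins <- tabulate(ac$att, nbins = length(ac$cycles)) / length(sm$succ)
  atts <- lapply(seq_along(ac$cycles), function(k) {
    ids <- ac$cycles[[k]]
    states <- lapply(ids, function(id) expand_state(net, sm, id))
    keys <- vapply(states, state_string, character(1))
    rot <- order(keys)[1]                 # start at lex-min state
    ord <- c(rot:length(ids), if (rot > 1) 1:(rot - 1))
    states <- states[ord]
    list(states = states,
         is_point = length(ids) == 1L,
         basin_ratio = basins[k],
         key = state_string(states[[1]]))
  })
  atts[order(vapply(atts, `[[`, character(1), "key"))]
}

#' Point attractors of a network
#'
#' Convenience filter of [find_attractors_exhaustive()] returning only the
#' fixed points, in canonical order.
#'
#' @inheritParams find_attractors_exhaustive
#' @return list of attractor objects with `is_point = TRUE`
#' @export
point_attractors <- function(net, pins = NULL,
                             limit = getOption("dcgs.exhaustive_limit", 22L)) {
  Filter(function(a) a$is_point, find_attractors_exhaustive(net, pins, limit))
}

#' Enumerate fixed points via the SCC hierarchy
#'
#' Scalable fixed-point enumeration for networks whose full state space is
#' out of reach: the interaction graph restricted to free nodes is
#' decomposed into strongly connected components, and candidate partial
#' fixed states are extended block by block in topological order. Each
#' block of size `b` only requires scanning its `2^b` internal assignments
#' against the already-fixed upstream values, so the cost is governed by
#' the largest SCC, not the network size.
#'
#' @inheritParams find_attractors_exhaustive
#' @param scc_limit maximum free-SCC size (default
#'   `getOption("dcgs.scc_limit", 26)`); beyond it a `dcgs_scc_too_large`
#'   error is raised
#' @return list of full 0/1 state vectors (the fixed points), sorted by
#'   state string; agrees exactly with the point attractors of
#'   [find_attractors_exhaustive()] where both are computable
#' @export
find_point_attractors_hierarchical <- function(net, pins = NULL,
                                               scc_limit = getOption("dcgs.scc_limit", 26L)) {
  p <- normalize_pins(net, pins)
  pin_idx <- match(names(p), net$nodes)
  free <- setdiff(seq_along(net$nodes), pin_idx)
  g <- interaction_graph(net, nodes = net$nodes[free])
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  nb <- comp$no
  # topological order of blocks: repeatedly take blocks with no unresolved
  # upstream block
  edges <- igraph::as_edgelist(g)
  bfrom <- memb[edges[, 1]]; bto <- memb[edges[, 2]]
  cross <- bfrom != bto
  order_blocks <- block_topo_order(nb, cbind(bfrom[cross], bto[cross]))
  maxb <- if (nb) max(tabulate(memb, nbins = nb)) else 0L
  if (maxb > scc_limit)
    stop(structure(class = c("dcgs_scc_too_large", "error", "condition"),
                   list(message = sprintf(
                     "largest free SCC has %d nodes, above the hierarchical limit %d",
                     maxb, scc_limit), call = NULL)))
  node_of_block <- split(names(memb), memb)

  vals <- rep(NA_integer_, length(net$nodes))
  if (length(p)) vals[pin_idx] <- unname(p)
  partials <- list(vals)
  for (b in order_blocks) {
    block_nodes <- match(node_of_block[[as.character(b)]], net$nodes)
    block_nodes <- sort(block_nodes)
    m <- length(block_nodes)
    ids <- 0:(2^m - 1)
    bpos <- stats::setNames(seq_len(m) - 1L, block_nodes)
    nxt <- list()
    for (vals in partials) {
      ok <- rep(TRUE, length(ids))
      for (j in block_nodes) {
        ins <- net$inputs[[j]]
        key <- 0L
        for (i in seq_along(ins)) {
          u <- ins[i]
          bit <- if (u %in% block_nodes) {
            bitwAnd(bitwShiftR(ids, bpos[[as.character(u)]]), 1L)
          } else vals[u]
          key <- key + bit * bitwShiftL(1L, i - 1L)
        }
        ok <- ok & net$tt[[j]][key + 1L] ==
          bitwAnd(bitwShiftR(ids, bpos[[as.character(j)]]), 1L)
        if (!any(ok)) break
      }
      for (id in ids[ok]) {
        v2 <- vals
        v2[block_nodes] <- bitwAnd(bitwShiftR(id, seq_len(m) - 1L), 1L)
        nxt[[length(nxt) + 1L]] <- v2
      }
    }
    partials <- nxt
    if (!length(partials)) break
  }
  fps <- lapply(partials, function(v) { v[is.na(v)] <- 0L; v })
  fps[order(vapply(fps, state_string, character(1)))]
}

# Kahn topological order over blocks given cross-block edge matrix.
block_topo_order <- function(nb, bedges) {
  if (!nb) return(integer(0))
  bedges <- unique(bedges)
  indeg <- tabulate(bedges[, 2], nbins = nb)
  out_of <- split(bedges[, 2], factor(bedges[, 1], levels = seq_len(nb)))
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    b <- queue[1]; queue <- queue[-1]
    ord <- c(ord, b)
    for (d in out_of[[b]]) {
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) queue <- c(queue, d)
    }
  }
  ord
}
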