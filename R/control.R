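# Control frameworks for global stabilization to a target point attractor:
#  - brute-force control kernel (CK): minimal pin sets leaving the target
#    as the only attractor of the state transition graph;
#  - FVS control (FC): pin sources plus one minimal feedback vertex set;
#  - DCGS: per-SCC canalizing-set search, top-down, aggregating the
#    smallest sets; validated against the CK criterion.
# Pinned values are always taken from the target attractor.

ctrl_error <- function(class, msg) {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = NULL)))
}

# Validate that `target` is a fixed point of `net` under `pre_pins`
# (consistent with the pins); returns the normalised state.
check_point_target <- function(net, target, pre_pins) {
  if (is.list(target) && !is.null(target$is_point)) {
    if (!target$is_point)
      ctrl_error("dcgs_cyclic_target",
                 "target is a cyclic attractor; only point attractors can be targeted by persistent pinning")
    target <- target$states[[1]]
  }
  t <- normalize_state(net, target)
  p <- normalize_pins(net, pre_pins)
  if (length(p)) {
    ti <- t[match(names(p), net$nodes)]
    if (any(ti != unname(p)))
      ctrl_error("dcgs_target_not_point",
                 "pre-pinned values contradict the target state")
  }
  if (!identical(synchronous_update(net, t, pins = p), t))
    ctrl_error("dcgs_target_not_point",
               "target state is not a point attractor of the (pre-pinned) network")
  t
}

new_control_set <- function(net, framework, pin_nodes, target, pre_pins,
                            size, detail = NULL) {
  t <- normalize_state(net, target)
  pins <- stats::setNames(t[match(pin_nodes, net$nodes)], pin_nodes)
  structure(list(framework = framework,
                 pins = pins[order(match(names(pins), net$nodes))],
                 target = t,
                 pre_pins = normalize_pins(net, pre_pins),
                 size = size,
                 detail = detail),
            class = "control_set")
}

#' @export
print.control_set <- function(x, ...) {
  cat(sprintf("%s control set (size %d): %s\n", x$framework, x$size,
              if (length(x$pins))
                paste(sprintf("%s=%d", names(x$pins), x$pins), collapse = ", ")
              else "{}"))
  invisible(x)
}

#' Brute-force control kernel search
#'
#' Enumerates candidate pin sets of increasing size k = 0, 1, ... over the
#' free nodes, pinned to their target-attractor values, until some size
#' leaves the restricted state transition graph with a single attractor
#' equal to the target; all hits at that minimal size are returned.
#'
#' @param net a `boolean_network`
#' @param target a point attractor of the pre-pinned network, as 0/1
#'   vector/string or an attractor object
#' @param pre_pins named pins applied before the search (e.g. fixed input
#'   nodes); candidate nodes and reported sizes exclude them
#' @param limit exhaustive free-node limit, see [find_attractors_exhaustive()]
#' @return list of `control_set` objects (framework `"CK"`), possibly a
#'   single empty set when the network is already monostable to the target
#' @export
brute_force_ck <- function(net, target, pre_pins = NULL,
                           limit = getOption("dcgs.exhaustive_limit", 22L)) {
  t <- check_point_target(net, target, pre_pins)
  p <- normalize_pins(net, pre_pins)
  free <- setdiff(net$nodes, names(p))
  if (length(free) > limit)
    ctrl_error("dcgs_state_space_too_large",
               sprintf("CK search needs the full %d-node state space (limit %d)",
                       length(free), limit))
  for (k in 0:length(free)) {
    hits <- list()
    idx <- if (k == 0) list(integer(0)) else
      utils::combn(length(free), k, simplify = FALSE)
    for (ii in idx) {
      cand <- free[ii]
      pins2 <- c(p, stats::setNames(t[match(cand, net$nodes)], cand))
      if (stabilizes_to(net, pins2, t, limit)) hits[[length(hits) + 1L]] <- cand
    }
    if (length(hits))
      return(lapply(hits, function(cand)
        new_control_set(net, "CK", cand, t, p, size = k)))
  }
  ctrl_error("dcgs_impossible_target", "no control kernel found (unreachable)")
}

# Single-attractor criterion: the pinned STG has exactly one attractor and
# it is the target point.
stabilizes_to <- function(net, pins, t, limit) {
  atts <- find_attractors_exhaustive(net, pins, limit = limit)
  length(atts) == 1L && atts[[1]]$is_point &&
    identical(atts[[1]]$states[[1]], t)
}

#' Validate global stabilization of a control set
#'
#' Applies the control set's pins (on top of its pre-pins) and checks the
#' CK criterion exhaustively: the restricted state transition graph must
#' retain exactly one attractor, the target point.
#'
#' @param net a `boolean_network`
#' @param cs a `control_set`, or a named pin vector
#' @param target target state; defaults to the control set's stored target
#' @param pre_pins pre-pins when `cs` is a bare pin vector
#' @inheritParams brute_force_ck
#' @return list with `stabilizes` (logical) and `counterexample` (an
#'   off-target attractor object, or `NULL`)
#' @export
validate_global_stabilization <- function(net, cs, target = NULL,
                                          pre_pins = NULL,
                                          limit = getOption("dcgs.exhaustive_limit", 22L)) {
  if (inherits(cs, "control_set")) {
    pins <- c(cs$pre_pins, cs$pins)
    if (is.null(target)) target <- cs$target
  } else {
    pins <- c(normalize_pins(net, pre_pins), normalize_pins(net, cs))
  }
  if (is.null(target)) stop("target state required", call. = FALSE)
  t <- normalize_state(net, target)
  atts <- find_attractors_exhaustive(net, pins, limit = limit)
  ok <- length(atts) == 1L && atts[[1]]$is_point &&
    identical(atts[[1]]$states[[1]], t)
  bad <- NULL
  if (!ok) {
    off <- Filter(function(a) !(a$is_point && identical(a$states[[1]], t)), atts)
    if (length(off)) bad <- off[[1]]
  }
  list(stabilizes = ok, counterexample = bad)
}

#' FVS control (FC) sets
#'
#' The logic-independent baseline: every minimal feedback vertex set of the
#' pre-pinned interaction graph, pinned to target values together with the
#' source nodes, globally stabilizes the network to the target. Reported
#' sizes count only the FVS nodes (sources and pre-pinned inputs are
#' excluded, following the FC size convention).
#'
#' @inheritParams brute_force_ck
#' @return list of `control_set` objects (framework `"FC"`), one per
#'   minimal FVS
#' @export
fvs_control_set <- function(net, target, pre_pins = NULL, ...) {
  t <- check_point_target(net, target, pre_pins)
  p <- normalize_pins(net, pre_pins)
  free <- setdiff(net$nodes, names(p))
  g <- interaction_graph(net, nodes = free)
  fvss <- minimal_fvs(g, ...)
  srcs <- setdiff(intersect(source_nodes(net), free), unlist(fvss))
  lapply(fvss, function(fvs)
    new_control_set(net, "FC", union(fvs, srcs), t, p, size = length(fvs),
                    detail = list(fvs = fvs, sources = srcs)))
}

#' Minimal canalizing sets of an FVS
#'
#' Searches subsets S of the FVS in increasing size until percolating
#' `base pins + S at target values` directly fixes *every* FVS node to its
#' target value; all subsets of that minimal size are returned. A
#' candidate under which percolation fixes some FVS node to the opposite
#' value is rejected. Pinning the whole FVS always succeeds, so the search
#' terminates; if a base pin itself contradicts the target on an FVS node,
#' an `dcgs_impossible_target` error is raised.
#'
#' @param net a `boolean_network`
#' @param fvs character vector of FVS node names (whole network or one SCC)
#' @param target target point-attractor state
#' @param pre_pins pre-pinned inputs
#' @param upper_pins additional pins (DCGS: nodes of upper SCC blocks at
#'   target values)
#' @return list of character vectors (sorted), all of the minimal size, in
#'   lexicographic order; `list(character(0))` when the base pins already
#'   percolate the whole FVS
#' @export
canalizing_sets_for_fvs <- function(net, fvs, target, pre_pins = NULL,
                                    upper_pins = NULL) {
  t <- normalize_state(net, target)
  base <- c(normalize_pins(net, pre_pins), normalize_pins(net, upper_pins))
  tvals <- stats::setNames(t[match(fvs, net$nodes)], fvs)
  conflict <- intersect(names(base), fvs)
  if (any(base[conflict] != tvals[conflict]))
    ctrl_error("dcgs_impossible_target",
               "a base pin fixes an FVS node away from its target value")
  for (k in 0:length(fvs)) {
    hits <- list()
    idx <- if (k == 0) list(integer(0)) else
      utils::combn(length(fvs), k, simplify = FALSE)
    for (ii in idx) {
      cand <- sort(fvs)[ii]
      ps <- percolate(net, c(base, tvals[cand]))
      got <- ps$assignment[fvs]
      if (!anyNA(got) && all(got == tvals))
        hits[[length(hits) + 1L]] <- sort(fvs)[ii]
    }
    if (length(hits)) {
      keys <- vapply(hits, paste, character(1), collapse = "\r")
      hits <- hits[!duplicated(keys)]
      return(hits[order(vapply(hits, paste, character(1), collapse = "\r"))])
    }
  }
  ctrl_error("dcgs_impossible_target",
             "no FVS subset percolates the FVS to target values (unreachable)")
}

#' Classify FVS nodes into canalizing, canalized and monostable sets
#'
#' Relaxes the canalizing-set criterion to admit monostable nodes: subsets
#' S of the FVS are searched in increasing size until, under
#' `pre_pins + S at target values`, (i) percolation fixes no FVS node to a
#' non-target value, and (ii) the pinned system has a single attractor,
#' the target point. FVS nodes percolation-fixed and outside S form the
#' canalized set; the remaining FVS nodes form the monostable set, flagged
#' `unconditional` when they are already consistent across the attractors
#' of the pre-pinned system alone.
#'
#' @inheritParams canalizing_sets_for_fvs
#' @param limit exhaustive free-node limit (this is an analysis-scale
#'   operation: attractors of each candidate pinned system are computed)
#' @return object of class `fvs_classification`: `fvs`, `canalizing`,
#'   `canalized`, `monostable` (character vectors), `unconditional`
#'   (logical per monostable node)
#' @export
classify_fvs <- function(net, fvs, target, pre_pins = NULL,
                         limit = getOption("dcgs.exhaustive_limit", 22L)) {
  t <- check_point_target(net, target, pre_pins)
  p <- normalize_pins(net, pre_pins)
  tvals <- stats::setNames(t[match(fvs, net$nodes)], fvs)
  fvs_sorted <- sort(fvs)
  base_atts <- NULL
  for (k in 0:length(fvs)) {
    idx <- if (k == 0) list(integer(0)) else
      utils::combn(length(fvs), k, simplify = FALSE)
    for (ii in idx) {
      cand <- fvs_sorted[ii]
      pins2 <- c(p, tvals[cand])
      ps <- percolate(net, pins2)
      got <- ps$assignment[fvs]
      if (any(!is.na(got) & got != tvals)) next
      if (!stabilizes_to(net, pins2, t, limit)) next
      fixed <- fvs[!is.na(got)]
      canalized <- setdiff(fixed, cand)
      mono <- setdiff(fvs, fixed)
      if (length(mono) && is.null(base_atts))
        base_atts <- find_attractors_exhaustive(net, p, limit = limit)
      uncond <- vapply(mono, function(nd)
        consistency(net, p, nd, attractors = base_atts)$consistent, logical(1))
      return(structure(list(fvs = sort(fvs),
                            canalizing = cand,
                            canalized = sort(canalized),
                            monostable = sort(mono),
                            unconditional = stats::setNames(
                              uncond[order(mono)], sort(mono))),
                       class = "fvs_classification"))
    }
  }
  ctrl_error("dcgs_no_valid_classification",
             "no FVS subset yields the target as unique attractor; the target cannot be reached through this FVS")
}

#' @export
print.fvs_classification <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "{}"
  cat("FVS classification\n")
  cat("  canalizing:", fmt(x$canalizing), "\n")
  cat("  canalized: ", fmt(x$canalized), "\n")
  cat("  monostable:", fmt(x$monostable),
      if (length(x$monostable))
        paste0("(", paste(ifelse(x$unconditional, "unconditional",
                                 "conditional"), collapse = ", "), ")")
      else "", "\n")
  invisible(x)
}

#' Divide-and-conquer global stabilization (DCGS)
#'
#' The scalable control framework: (1) condense the interaction graph of
#' the free nodes into the SCC hierarchy; (2) sweep blocks top-down,
#' pinning all nodes of strictly upper blocks to target values, enumerate
#' each block's minimal FVSs on its internal subgraph, and find the
#' minimal canalizing sets of every FVS, keeping only the smallest sets
#' across the block's FVSs; (3) aggregate one smallest canalizing set per
#' block (cross-product over blocks, deduplicated) and add the source-node
#' pins. Monostable nodes are deliberately ignored, so a returned set is
#' guaranteed to stabilize only when per-block monostable sets are empty;
#' use [validate_global_stabilization()] where the state space permits.
#'
#' @inheritParams brute_force_ck
#' @param first_only return only the canonical (lexicographically first)
#'   control set instead of the full cross-product
#' @param verbose print a per-block trace (blocks, FVSs, canalizing sets)
#' @return list of `control_set` objects (framework `"DCGS"`), all of the
#'   same minimal total size; `detail` carries the per-block canalizing
#'   sets
#' @export
dcgs <- function(net, target, pre_pins = NULL, first_only = FALSE,
                 verbose = FALSE) {
  t <- check_point_target(net, target, pre_pins)
  p <- normalize_pins(net, pre_pins)
  free <- setdiff(net$nodes, names(p))
  h <- condensation(interaction_graph(net, nodes = free))
  per_block <- list()
  for (b in seq_along(h$blocks)) {
    nodes_b <- h$blocks[[b]]
    upper <- unlist(h$blocks[h$level < h$level[b]])
    upper_pins <- stats::setNames(t[match(upper, net$nodes)], upper)
    if (!h$is_cyclic[b]) next       # acyclic singleton: FVS is empty
    sub <- interaction_graph(net, nodes = nodes_b)
    fvss <- minimal_fvs(sub)
    sets_b <- list()
    for (fvs in fvss) {
      cs <- canalizing_sets_for_fvs(net, fvs, t, pre_pins = p,
                                    upper_pins = upper_pins)
      sets_b <- c(sets_b, cs)
    }
    sizes <- lengths(sets_b)
    sets_b <- sets_b[sizes == min(sizes)]
    keys <- vapply(sets_b, paste, character(1), collapse = "\r")
    sets_b <- sets_b[!duplicated(keys)]
    sets_b <- sets_b[order(vapply(sets_b, paste, character(1), collapse = "\r"))]
    if (verbose)
      message(sprintf("block %d (level %d) {%s}: %d FVS(s), smallest canalizing sets: %s",
                      b, h$level[b], paste(nodes_b, collapse = ","),
                      length(fvss),
                      paste(vapply(sets_b, function(s)
                        paste0("{", paste(s, collapse = ","), "}"),
                        character(1)), collapse = " ")))
    if (length(sets_b[[1]]) > 0L)   # size-0 blocks contribute nothing
      per_block[[length(per_block) + 1L]] <- sets_b
  }
  combos <- list(character(0))
  for (sets_b in per_block) {
    combos <- unlist(lapply(combos, function(cm)
      lapply(sets_b, function(s) union(cm, s))), recursive = FALSE)
    if (first_only) combos <- combos[1]
  }
  combos <- lapply(combos, sort)
  keys <- vapply(combos, paste, character(1), collapse = "\r")
  combos <- combos[!duplicated(keys)]
  combos <- combos[order(vapply(combos, paste, character(1), collapse = "\r"))]
  if (first_only) combos <- combos[1]
  srcs <- setdiff(intersect(source_nodes(net), free), unlist(combos))
  lapply(combos, function(cm)
    new_control_set(net, "DCGS", union(cm, srcs), t, p, size = length(cm),
                    detail = list(per_block = per_block, sources = srcs,
                                  hierarchy = h)))
}
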