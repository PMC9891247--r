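# Structural analysis of the interaction graph: strongly connected
# component condensation with top-down hierarchy levels, and exhaustive
# enumeration of all minimal feedback vertex sets (FVSs). Self-loops count
# as cycles throughout: an FVS must cover them, otherwise "acyclic" would
# not imply unique percolation.

as_igraph <- function(graph) {
  if (inherits(graph, "igraph")) return(graph)
  if (inherits(graph, "boolean_network")) return(interaction_graph(graph))
  stop("expected an igraph or boolean_network object", call. = FALSE)
}

#' SCC condensation with hierarchy levels
#'
#' Partitions the interaction graph into strongly connected components
#' (including singleton SCCs), builds the condensation DAG and assigns each
#' block a top-down level: 0 for blocks with no upstream block, otherwise
#' 1 + the maximum level of upstream blocks. Blocks are ordered (and
#' numbered) by level, then by their alphabetically smallest member, so the
#' decomposition is deterministic.
#'
#' @param graph a `boolean_network` or a directed `igraph`
#' @return object of class `scc_hierarchy`: `blocks` (list of character
#'   vectors, sorted node names), `level` (integer per block),
#'   `dag_edges` (2-column matrix of block indices, no cycles),
#'   `is_cyclic` (per block: size >= 2 or a self-loop),
#'   `max_scc_size` (the largest block size)
#' @export
condensation <- function(graph) {
  g <- as_igraph(graph)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  nb <- comp$no
  nodes <- names(memb)
  blocks <- unname(lapply(split(nodes, memb), function(x) sort(x)))
  edges <- igraph::as_edgelist(g)
  bfrom <- unname(memb[edges[, 1]]); bto <- unname(memb[edges[, 2]])
  selfloop_blocks <- unique(bfrom[bfrom == bto & edges[, 1] == edges[, 2]])
  cross <- unique(cbind(bfrom, bto)[bfrom != bto, , drop = FALSE])
  # levels: longest path from the top of the DAG
  level <- rep(0L, nb)
  for (b in block_topo_order(nb, cross)) {
    ups <- cross[cross[, 2] == b, 1]
    if (length(ups)) level[b] <- 1L + max(level[ups])
  }
  is_cyclic <- lengths(blocks) >= 2L | seq_len(nb) %in% selfloop_blocks
  first_member <- vapply(blocks, `[`, character(1), 1)
  ord <- order(level, first_member)
  remap <- match(seq_len(nb), ord)
  de <- cbind(from = remap[cross[, 1]], to = remap[cross[, 2]])
  de <- de[order(de[, 1], de[, 2]), , drop = FALSE]
  structure(list(blocks = blocks[ord],
                 level = level[ord],
                 dag_edges = de,
                 is_cyclic = unname(is_cyclic[ord]),
                 max_scc_size = if (nb) max(lengths(blocks)) else 0L),
            class = "scc_hierarchy")
}

#' @export
print.scc_hierarchy <- function(x, ...) {
  cat(sprintf("SCC hierarchy: %d blocks, largest %d nodes\n",
              length(x$blocks), x$max_scc_size))
  for (i in seq_along(x$blocks))
    cat(sprintf("  [%d] level %d%s: %s\n", i, x$level[i],
                if (x$is_cyclic[i]) " (cyclic)" else "",
                paste(x$blocks[[i]], collapse = ", ")))
  invisible(x)
}

#' Test acyclicity after node removal
#'
#' @param graph a `boolean_network` or directed `igraph`
#' @param candidate character vector of node names to remove
#' @return `TRUE` iff the graph minus `candidate` (and incident edges) has
#'   no directed cycle; a remaining self-loop counts as a cycle
#' @export
is_acyclic_after_removal <- function(graph, candidate) {
  g <- as_igraph(graph)
  stopifnot(all(candidate %in% igraph::V(g)$name))
  h <- igraph::delete_vertices(g, candidate)
  if (any(igraph::which_loop(h))) return(FALSE)
  igraph::is_dag(h)
}

#' Enumerate all minimal feedback vertex sets
#'
#' Exhaustive search in the style of brute-force FVS finders: candidate
#' subsets are tested in increasing size k = 0, 1, ... until some size
#' admits an FVS; all hits at that minimal size are returned. Candidates
#' are drawn only from nodes lying in cyclic SCCs (no minimal FVS can use
#' any other node), and subsets are walked in lexicographic order of node
#' indices, so the output is deterministic.
#'
#' @param graph a `boolean_network` or directed `igraph`
#' @param cap guard on the total number of acyclicity tests (default
#'   `1e6`); when exceeded the search aborts with advice to decompose the
#'   graph by SCC first
#' @return list of character vectors (each sorted), all of the same minimal
#'   cardinality; for an already acyclic graph, `list(character(0))`
#' @export
minimal_fvs <- function(graph, cap = getOption("dcgs.fvs_cap", 1e6)) {
  g <- as_igraph(graph)
  h <- condensation(g)
  universe <- sort(unname(unlist(h$blocks[h$is_cyclic])))
  if (!length(universe)) return(list(character(0)))
  tested <- 0
  for (k in seq_len(length(universe))) {
    n_subsets <- choose(length(universe), k)
    tested <- tested + n_subsets
    if (tested > cap)
      stop(structure(class = c("dcgs_fvs_cap_exceeded", "error", "condition"),
                     list(message = sprintf(
                       "FVS search would need > %g acyclicity tests; decompose by SCC first (see condensation()) or raise the cap",
                       cap), call = NULL)))
    hits <- list()
    idx <- utils::combn(length(universe), k, simplify = FALSE)
    for (ii in idx) {
      cand <- universe[ii]
      if (is_acyclic_after_removal(g, cand)) hits[[length(hits) + 1L]] <- cand
    }
    if (length(hits)) return(hits)
  }
  stop("unreachable: removing all cyclic-SCC nodes always leaves an acyclic graph")
}
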