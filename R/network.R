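# Boolean network representation: named nodes, one Boolean update rule each.
# Rules are stored as R expressions over node identifiers using !, &, |,
# together with a per-node truth table over the node's (syntactic) inputs.
# The truth table is the single source of dynamical truth; expressions are
# kept only for round-tripping rule files.

#' Construct a Boolean network from rule expressions
#'
#' Usually called through [parse_network()]; exposed for programmatic
#' construction of small models in examples and tests.
#'
#' @param nodes character vector of unique node identifiers, in declaration
#'   order. This order is canonical: states, truth-table bit positions and
#'   printed state strings all follow it.
#' @param rules named character vector or list of rule strings in R/bnet
#'   syntax (`!`, `&`, `|`, parentheses, constants `0`/`1`), one per node.
#' @return an object of class `boolean_network` with components
#'   `nodes`, `rules` (expressions), `inputs` (per-node integer vector of
#'   regulator indices, sorted), `tt` (per-node truth table as integer 0/1
#'   vector of length `2^k`, bit i of the row index corresponding to the
#'   i-th listed input).
#' @export
boolean_network <- function(nodes, rules) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes))
    stop("duplicate node identifiers: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "),
         call. = FALSE)
  bad <- nodes[!grepl("^[A-Za-z_.][A-Za-z0-9_.]*$", nodes)]
  if (length(bad))
    stop("invalid node identifiers: ", paste(bad, collapse = ", "),
         call. = FALSE)
  rules <- unlist(as.list(rules))
  if (!is.null(names(rules))) {
    if (!setequal(names(rules), nodes))
      stop("rule names do not match node set", call. = FALSE)
    rules <- rules[nodes]
  } else if (length(rules) != length(nodes)) {
    stop("need exactly one rule per node", call. = FALSE)
  }
  exprs <- lapply(seq_along(rules), function(i) {
    e <- tryCatch(str2lang(rules[[i]]), error = function(err)
      stop(sprintf("syntax error in rule for node '%s': %s",
                   nodes[i], conditionMessage(err)), call. = FALSE))
    e
  })
  unknown <- setdiff(unique(unlist(lapply(exprs, all.vars))), nodes)
  if (length(unknown))
    stop("rules reference undeclared node(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  net <- structure(list(nodes = nodes, rules = exprs), class = "boolean_network")
  net$inputs <- lapply(exprs, function(e) sort(match(all.vars(e), nodes)))
  net$tt <- lapply(seq_along(nodes), function(i)
    rule_truth_table(exprs[[i]], nodes[net$inputs[[i]]]))
  net
}

# Truth table of an expression over the given ordered input names.
# Row index r (0-based): bit (i-1) of r is the value of inputs[i].
rule_truth_table <- function(expr, inputs) {
  k <- length(inputs)
  ids <- 0:(2^k - 1)
  env <- list()
  for (i in seq_len(k))
    env[[inputs[i]]] <- bitwAnd(bitwShiftR(ids, i - 1L), 1L)
  v <- eval(expr, envir = env, enclos = baseenv())
  v <- as.integer(as.logical(v))
  if (length(v) == 1L) v <- rep(v, length(ids))
  if (anyNA(v) || length(v) != length(ids))
    stop("rule does not evaluate to a Boolean over its inputs", call. = FALSE)
  v
}

#' @export
print.boolean_network <- function(x, ...) {
  cat(sprintf("Boolean network: %d nodes, %d edges\n",
              length(x$nodes), nrow(interaction_edges(x))))
  for (i in seq_along(x$nodes))
    cat(sprintf("  %s, %s\n", x$nodes[i], deparse1(x$rules[[i]])))
  invisible(x)
}

#' Number of nodes of a network
#' @param net a `boolean_network`
#' @return integer node count
#' @export
n_nodes <- function(net) length(net$nodes)

#' Interaction graph edge list
#'
#' Directed edges u -> v for every node u appearing in v's rule. The edge
#' set is recomputed from the rules on every call, never cached.
#'
#' @param net a `boolean_network`
#' @return two-column character matrix (`from`, `to`); zero rows when the
#'   network has no regulatory inputs
#' @export
interaction_edges <- function(net) {
  from <- unlist(lapply(seq_along(net$nodes),
                        function(i) net$nodes[net$inputs[[i]]]))
  to <- rep(net$nodes, lengths(net$inputs))
  m <- cbind(from = as.character(from), to = as.character(to))
  m
}

#' Interaction graph as an igraph object
#'
#' @inheritParams interaction_edges
#' @param nodes optional subset of node names: the induced subgraph on these
#'   nodes is returned (used for per-SCC analyses).
#' @return an `igraph` directed graph whose vertices carry node names;
#'   isolated nodes are kept
#' @export
interaction_graph <- function(net, nodes = NULL) {
  edges <- interaction_edges(net)
  if (is.null(nodes)) nodes <- net$nodes
  keep <- edges[, 1] %in% nodes & edges[, 2] %in% nodes
  igraph::graph_from_data_frame(
    as.data.frame(edges[keep, , drop = FALSE]),
    directed = TRUE,
    vertices = data.frame(name = nodes))
}

#' Source nodes of a network
#'
#' A source (input) node is one whose update rule is a constant function:
#' either it has no regulators or its truth table is constant. Such nodes
#' hold their rule's constant after one step; all control frameworks pin
#' them to the target value without counting them in control-set sizes.
#'
#' @inheritParams interaction_edges
#' @return character vector of node names (possibly empty)
#' @export
source_nodes <- function(net) {
  const <- vapply(net$tt, function(tt) length(unique(tt)) == 1L, logical(1))
  net$nodes[const]
}

#' Parse a Boolean network rule file
#'
#' Two dialects are supported. `bnet` is the BoolNet "targets, factors"
#' format: an optional `targets, factors` header, one `node, expression`
#' line per node, operators `&`, `|`, `!`, parentheses and constants
#' `0`/`1`, `#` comments. `pyexpr` uses `node = expression` lines with
#' Python keywords `and`, `or`, `not` (also accepting `True`/`False`).
#'
#' @param text rule file content as a single string or character vector of
#'   lines, or a path to an existing file.
#' @param dialect `"bnet"` (default) or `"pyexpr"`.
#' @return a [boolean_network()]
#' @export
parse_network <- function(text, dialect = c("bnet", "pyexpr")) {
  dialect <- match.arg(dialect)
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text))
    text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines_raw <- lines
  lines <- sub("#.*$", "", lines)
  keep <- which(trimws(lines) != "")
  nodes <- character(); rules <- character()
  for (ln in keep) {
    s <- trimws(lines[ln])
    if (dialect == "bnet") {
      if (tolower(gsub("\\s", "", s)) == "targets,factors") next
      m <- regexpr(",", s, fixed = TRUE)
      if (m < 0)
        stop(sprintf("line %d: expected 'node, expression': %s",
                     ln, trimws(lines_raw[ln])), call. = FALSE)
      nm <- trimws(substr(s, 1, m - 1))
      ex <- trimws(substr(s, m + 1, nchar(s)))
    } else {
      m <- regexpr("=", s, fixed = TRUE)
      if (m < 0)
        stop(sprintf("line %d: expected 'node = expression': %s",
                     ln, trimws(lines_raw[ln])), call. = FALSE)
      nm <- trimws(substr(s, 1, m - 1))
      ex <- trimws(substr(s, m + 1, nchar(s)))
      ex <- gsub("\\bnot\\b", "!", ex)
      ex <- gsub("\\band\\b", "&", ex)
      ex <- gsub("\\bor\\b", "|", ex)
      ex <- gsub("\\bTrue\\b", "1", ex)
      ex <- gsub("\\bFalse\\b", "0", ex)
    }
    if (nm %in% nodes)
      stop(sprintf("line %d: duplicate definition of node '%s'", ln, nm),
           call. = FALSE)
    if (ex == "")
      stop(sprintf("line %d: empty rule for node '%s'", ln, nm), call. = FALSE)
    tryCatch(str2lang(ex), error = function(err)
      stop(sprintf("line %d: syntax error in rule for node '%s': %s",
                   ln, nm, conditionMessage(err)), call. = FALSE))
    nodes <- c(nodes, nm); rules <- c(rules, ex)
  }
  if (!length(nodes)) stop("no rules found in input", call. = FALSE)
  boolean_network(nodes, rules)
}

#' Write a Boolean network to rule-file text
#'
#' Inverse of [parse_network()]: `parse_network(write_network(net))` yields a
#' rule-equivalent network (identical truth tables) with the same node order.
#'
#' @param net a `boolean_network`
#' @param dialect `"bnet"` or `"pyexpr"`
#' @param path optional file path; when given the text is also written there
#' @return the rule file content as a single string (invisibly when `path`
#'   is given)
#' @export
write_network <- function(net, dialect = c("bnet", "pyexpr"), path = NULL) {
  dialect <- match.arg(dialect)
  exprs <- vapply(net$rules, deparse1, character(1))
  if (dialect == "bnet") {
    out <- c("targets, factors", paste0(net$nodes, ", ", exprs))
  } else {
    py <- exprs
    py <- gsub("&&", "&", py, fixed = TRUE)
    py <- gsub("||", "|", py, fixed = TRUE)
    py <- gsub("!", " not ", py, fixed = TRUE)
    py <- gsub("&", " and ", py, fixed = TRUE)
    py <- gsub("|", " or ", py, fixed = TRUE)
    py <- gsub("\\s+", " ", py)
    out <- paste0(net$nodes, " = ", trimws(py))
  }
  txt <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(txt))
  }
  txt
}

# Normalise a pin specification to a named integer vector of 0/1 aligned
# with the network, erroring on unknown nodes or conflicting duplicates.
normalize_pins <- function(net, pins) {
  if (is.null(pins) || length(pins) == 0L)
    return(stats::setNames(integer(0), character(0)))
  v <- unlist(pins)
  nm <- names(v)
  if (is.null(nm) || any(nm == ""))
    stop("pins must be named node=value", call. = FALSE)
  unknown <- setdiff(nm, net$nodes)
  if (length(unknown))
    stop("pin references unknown node(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  v <- as.integer(v)
  if (any(!v %in% c(0L, 1L))) stop("pin values must be 0 or 1", call. = FALSE)
  if (anyDuplicated(nm)) {
    agg <- tapply(v, nm, function(x) length(unique(x)))
    if (any(agg > 1))
      stop("conflicting pin values for node(s): ",
           paste(names(agg)[agg > 1], collapse = ", "), call. = FALSE)
    v <- v[!duplicated(nm)]; nm <- nm[!duplicated(nm)]
  }
  ord <- order(match(nm, net$nodes))
  stats::setNames(v[ord], nm[ord])
}

# Validate and normalise a state vector (0/1, possibly named) to an
# unnamed integer vector in canonical node order.
normalize_state <- function(net, s) {
  if (is.character(s) && length(s) == 1L && grepl("^[01]+$", s))
    s <- as.integer(strsplit(s, "")[[1]])
  s <- as.integer(unlist(s))
  if (!is.null(names(s))) s <- s[net$nodes]
  if (length(s) != length(net$nodes) || anyNA(s) || any(!s %in% c(0L, 1L)))
    stop("state must assign 0/1 to every node in network order", call. = FALSE)
  unname(s)
}

# Format a state vector as a 0/1 string in declaration order.
state_string <- function(s) paste(s, collapse = "")
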