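# Generator of "biological random Boolean networks": out-degrees from a
# truncated power law P(k) = A k^-gamma on 1..n, in-degrees from a Poisson
# distribution truncated to 1..n, wired by configuration-model stub
# pairing (self-loops allowed, parallel edges rejected), with update rules
# drawn from a library of canalizing functions keyed by in-degree.
# Networks are accepted only when they possess at least a minimum number
# of point attractors, matching the selection applied to the ensembles
# the control frameworks are benchmarked on.

#' Configuration for the biological random network generator
#'
#' Defaults state the ensemble used throughout the analysis: 10-node
#' networks, power-law out-degree with exponent 2.5 (biological networks
#' have exponents between 2 and 3), Poisson in-degree with mean 1.75
#' (average degree of biological networks is roughly 1.5-2), and a filter
#' keeping only networks with at least two point attractors.
#'
#' @param n node count (>= 2)
#' @param gamma power-law exponent of the out-degree distribution
#' @param lam Poisson mean of the in-degree distribution
#' @param min_point_attractors acceptance filter on fixed-point count
#' @param function_library list mapping in-degree k to a character vector
#'   of rule templates over placeholders `x1..xk`; defaults to
#'   [default_function_library()]
#' @param max_attempts cap on generate-and-filter attempts
#' @return list of class `rbn_config`
#' @export
rbn_config <- function(n = 10L, gamma = 2.5, lam = 1.75,
                       min_point_attractors = 2L,
                       function_library = NULL,
                       max_attempts = 2000L) {
  stopifnot(n >= 2, gamma > 0, lam > 0, min_point_attractors >= 0)
  if (is.null(function_library))
    function_library <- default_function_library(max_k = n)
  structure(list(n = as.integer(n), gamma = gamma, lam = lam,
                 min_point_attractors = as.integer(min_point_attractors),
                 function_library = function_library,
                 max_attempts = as.integer(max_attempts)),
            class = "rbn_config")
}

#' Truncated power-law out-degree probabilities
#'
#' @param n maximum degree (support is 1..n)
#' @param gamma exponent
#' @return numeric vector p with `p[k] = A k^-gamma`, summing to 1
#' @export
power_law_pmf <- function(n, gamma = 2.5) {
  k <- seq_len(n)
  w <- k^(-gamma)
  w / sum(w)
}

#' Truncated Poisson in-degree probabilities and mean
#'
#' Poisson(lam) conditioned on 1 <= k <= n (draws of 0 or > n are
#' resampled, so the realized distribution is the conditional one).
#'
#' @param n maximum degree
#' @param lam Poisson mean before truncation
#' @return list with `pmf` (length n, support 1..n) and `mean`
#' @export
truncated_poisson <- function(n, lam = 1.75) {
  k <- seq_len(n)
  w <- stats::dpois(k, lam)
  p <- w / sum(w)
  list(pmf = p, mean = sum(k * p))
}

#' Sample reconciled out- and in-degree sequences
#'
#' In-degrees are drawn first (truncated Poisson); the out-degree sequence
#' (truncated power law) is redrawn until its total is within the largest
#' single degree of the in-degree total, then adjusted by +/-1 on
#' uniformly chosen nodes until the totals match exactly, keeping every
#' degree in 1..n. This preserves both marginal shapes approximately.
#'
#' @param cfg an [rbn_config()]
#' @return list with integer vectors `out_degrees` and `in_degrees`
#'   (equal sums) and `out_degrees_raw` (the power-law draw before the
#'   +/-1 reconciliation; the two marginal means differ, so the realized
#'   out-degrees are a shifted version of the raw ones)
#' @export
sample_degree_sequences <- function(cfg) {
  n <- cfg$n
  pin <- truncated_poisson(n, cfg$lam)$pmf
  in_deg <- sample.int(n, n, replace = TRUE, prob = pin)
  pout <- power_law_pmf(n, cfg$gamma)
  total_in <- sum(in_deg)
  for (try in seq_len(1000L)) {
    out_deg <- sample.int(n, n, replace = TRUE, prob = pout)
    gap <- abs(sum(out_deg) - total_in)
    if (gap <= max(c(out_deg, in_deg))) break
    if (try == 1000L) stop("could not reconcile degree sequences", call. = FALSE)
  }
  out_raw <- out_deg
  pick <- function(idx) idx[sample.int(length(idx), 1L)]
  while (sum(out_deg) != total_in) {
    if (sum(out_deg) < total_in) {
      i <- pick(which(out_deg < n))
      out_deg[i] <- out_deg[i] + 1L
    } else {
      i <- pick(which(out_deg > 1L))
      out_deg[i] <- out_deg[i] - 1L
    }
  }
  # out_degrees_raw: the accepted draw before +/-1 adjustment, i.e. the
  # stated power law. The power-law mean (~1.53 at n=10) and truncated
  # Poisson mean (~2.11) differ, so exact sum reconciliation necessarily
  # shifts the realized out-degree marginal upward; the in-degree marginal
  # is preserved exactly.
  list(out_degrees = out_deg, in_degrees = in_deg, out_degrees_raw = out_raw)
}

#' Wire a digraph realizing the given degree sequences
#'
#' Configuration-model pairing: out-stubs are matched to a random
#' permutation of in-stubs; pairings creating parallel edges are rejected
#' and redrawn (self-loops are permitted). Realized degrees equal the
#' requested ones exactly.
#'
#' @param out_degrees,in_degrees integer vectors of equal sum
#' @param max_tries rejection-sampling cap
#' @return two-column integer matrix of edges (`from`, `to`)
#' @export
generate_structure <- function(out_degrees, in_degrees, max_tries = 200L) {
  stopifnot(sum(out_degrees) == sum(in_degrees))
  out_stubs <- rep(seq_along(out_degrees), out_degrees)
  in_stubs <- rep(seq_along(in_degrees), in_degrees)
  for (i in seq_len(max_tries)) {
    to <- if (length(in_stubs) > 1L) sample(in_stubs) else in_stubs
    e <- cbind(from = out_stubs, to = to)
    if (!anyDuplicated(e)) return(e)
  }
  stop(structure(class = c("dcgs_wiring_failed", "error", "condition"),
                 list(message = "degree sequences admit no simple digraph within the retry budget",
                      call = NULL)))
}

#' Generate one biological random Boolean network
#'
#' Draws degree sequences, wires the structure, assigns every node a rule
#' drawn uniformly from the function library entry for its in-degree
#' (inputs attached in random order), and accepts the network only when it
#' has at least `cfg$min_point_attractors` fixed points. Rejected networks
#' are redrawn from scratch up to `cfg$max_attempts` times.
#'
#' @param cfg an [rbn_config()]
#' @param seed optional integer seed; when given the generation is
#'   bit-reproducible
#' @return a `boolean_network` with attributes `n_point_attractors` and
#'   `attempts`
#' @export
generate_biological_random_network <- function(cfg = rbn_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("n", seq_len(cfg$n))
  for (attempt in seq_len(cfg$max_attempts)) {
    deg <- sample_degree_sequences(cfg)
    edges <- tryCatch(generate_structure(deg$out_degrees, deg$in_degrees),
                      dcgs_wiring_failed = function(e) NULL)
    if (is.null(edges)) next
    rules <- character(cfg$n)
    ok <- TRUE
    for (v in seq_len(cfg$n)) {
      ins <- edges[edges[, 2] == v, 1]
      k <- length(ins)
      lib <- if (k <= length(cfg$function_library))
        cfg$function_library[[k]] else NULL
      if (is.null(lib) || !length(lib)) { ok <- FALSE; break }
      tmpl <- lib[[sample.int(length(lib), 1L)]]
      perm <- if (k > 1L) sample(ins) else ins
      rules[v] <- instantiate_template(tmpl, nodes[perm])
    }
    if (!ok) next
    net <- boolean_network(nodes, rules)
    npa <- length(find_point_attractors_hierarchical(net))
    if (npa >= cfg$min_point_attractors) {
      attr(net, "n_point_attractors") <- npa
      attr(net, "attempts") <- attempt
      return(net)
    }
  }
  stop("attempt cap exceeded without an accepted network", call. = FALSE)
}

# Replace placeholders x1..xk in a rule template by actual node names.
instantiate_template <- function(tmpl, input_names) {
  for (i in rev(seq_along(input_names)))   # x10 before x1
    tmpl <- gsub(paste0("\\bx", i, "\\b"), input_names[i], tmpl)
  tmpl
}

#' Default canalizing function library
#'
#' Rule templates over placeholders `x1..xk`, keyed by in-degree k. For
#' k = 1 both identity and negation; for k >= 2 all nested canalizing
#' chain functions `s1 x1 op2 (s2 x2 op3 (... sk xk))` with each sign
#' `si` in {plain, negated} and each operator in {`&`, `|`} - the function
#' class biological update rules are overwhelmingly drawn from. A
#' user-supplied library (see [load_function_library()]) can replace it to
#' mirror a specific model corpus.
#'
#' @param max_k largest in-degree to cover
#' @return list of character vectors indexed by in-degree
#' @export
default_function_library <- function(max_k = 5L) {
  lib <- vector("list", max_k)
  for (k in seq_len(max_k)) {
    if (k == 1L) { lib[[k]] <- c("x1", "!x1"); next }
    signs <- expand.grid(rep(list(c("", "!")), k), stringsAsFactors = FALSE)
    ops <- expand.grid(rep(list(c("&", "|")), k - 1L), stringsAsFactors = FALSE)
    if (nrow(signs) * nrow(ops) > 512L) {
      # large k: keep a deterministic evenly-spaced subset
      signs <- signs[seq(1L, nrow(signs), length.out = min(nrow(signs), 32L)), ,
                     drop = FALSE]
      ops <- ops[seq(1L, nrow(ops), length.out = min(nrow(ops), 16L)), ,
                 drop = FALSE]
    }
    out <- character(0)
    for (si in seq_len(nrow(signs))) {
      for (oi in seq_len(nrow(ops))) {
        expr <- paste0(signs[si, k], "x", k)
        for (j in (k - 1L):1L)
          expr <- paste0(signs[si, j], "x", j, " ", ops[oi, j], " (", expr, ")")
        out <- c(out, expr)
      }
    }
    lib[[k]] <- out
  }
  lib
}

#' Load a function library from JSON
#'
#' Expected format: a JSON object mapping in-degree (as string) to an
#' array of rule template strings over `x1..xk`, e.g.
#' `{"1": ["x1"], "2": ["x1 & x2", "x1 | !x2"]}`. Templates may use either
#' `&`/`|`/`!` or `and`/`or`/`not`.
#'
#' @param path JSON file path
#' @return list of character vectors indexed by in-degree
#' @export
load_function_library <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  ks <- as.integer(names(raw))
  if (anyNA(ks) || any(ks < 1L))
    stop("library keys must be positive in-degrees", call. = FALSE)
  lib <- vector("list", max(ks))
  for (i in seq_along(ks)) {
    tm <- as.character(raw[[i]])
    tm <- gsub("\\bnot\\b", "!", tm)
    tm <- gsub("\\band\\b", "&", tm)
    tm <- gsub("\\bor\\b", "|", tm)
    tm <- gsub("!\\s+", "!", tm)
    lib[[ks[i]]] <- tm
  }
  lib
}

#' Generate a batch of networks with a manifest
#'
#' @param count number of networks
#' @param cfg an [rbn_config()]
#' @param seed base seed; network i uses seed `seed + i - 1`
#' @param outdir optional directory: writes `net_<i>.bnet` files plus a
#'   `manifest.json` (seed, config, per-network attractor counts)
#' @return list of `boolean_network` objects (invisibly when writing)
#' @export
generate_network_batch <- function(count, cfg = rbn_config(), seed = 1L,
                                   outdir = NULL) {
  nets <- lapply(seq_len(count), function(i)
    generate_biological_random_network(cfg, seed = seed + i - 1L))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(nets))
      write_network(nets[[i]], "bnet",
                    path = file.path(outdir, sprintf("net_%03d.bnet", i)))
    manifest <- list(
      seed = seed,
      config = list(n = cfg$n, gamma = cfg$gamma, lam = cfg$lam,
                    min_point_attractors = cfg$min_point_attractors),
      networks = lapply(seq_along(nets), function(i) list(
        file = sprintf("net_%03d.bnet", i),
        seed = seed + i - 1L,
        n_point_attractors = attr(nets[[i]], "n_point_attractors"))))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    return(invisible(nets))
  }
  nets
}
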