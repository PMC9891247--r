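---
title: "Global stabilizing control of Boolean networks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Global stabilizing control of Boolean networks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcgs)
```

## The model

A Boolean network over nodes $v_1,\dots,v_N$ assigns each node a state in
$\{0,1\}$ and an update rule $f_i$ over its regulators. Under the
synchronous scheme, the network state $s(T) \in \{0,1\}^N$ evolves as
$s_i(T) = f_i(s(T-1))$ for all $i$ simultaneously, so the state
transition graph (STG) over the $2^N$ states has out-degree exactly one.
Every trajectory ends in a cycle of the STG: a single self-looping state
is a *point attractor* (fixed point, $s = f(s)$), a longer cycle a
*cyclic attractor*. The *basin ratio* of an attractor is the fraction of
states whose trajectory reaches it; basin ratios sum to one.

Stable cell phenotypes correspond to attractors of molecular regulatory
networks, and a therapeutic intervention corresponds to *global
stabilization*: fixing a small node set to constant values — persistent
control inputs, e.g. constitutive activation or knock-out — such that
**every** initial state converges to one chosen target attractor. This
package addresses the problem of finding minimal such node sets for a
target *point* attractor, for which persistent pinning is well posed.
Targeting a cyclic attractor with persistent pins would itself reshape
the attractor landscape, so the package refuses cyclic targets with a
typed error rather than producing a misleading answer.

Pinning semantics throughout: a pinned node's rule is *replaced* by the
constant; the pinned STG lives on the free nodes only.

## Three control frameworks

**Brute-force control kernel (CK).** `brute_force_ck()` enumerates pin
sets of increasing size $k = 0, 1, \dots$ over the free nodes, always
pinned to their target-attractor values, and returns every set of the
first size for which the pinned STG retains a single attractor, the
target. This is the exact optimum and the validation oracle
(`validate_global_stabilization()` applies the same single-attractor
criterion to any candidate set), but it costs
$O(3^N)$ in the worst case and is limited to networks whose full state
space is enumerable (default 22 free nodes, `options(dcgs.exhaustive_limit=)`).

**FVS control (FC).** A *feedback vertex set* (FVS) is a node set whose
removal leaves the interaction graph acyclic; self-loops count as
cycles. Pinning a FVS plus the source nodes to the values they take in
any attractor provably drives a dissipative system into that attractor,
using structure only. `minimal_fvs()` enumerates **all** minimum-size
FVSs exhaustively (subsets in lexicographic order, candidates restricted
to nodes of cyclic SCCs), and `fvs_control_set()` emits one control set
per minimal FVS. FVS sizes are independent of the target, hence usually
larger than CKs. Reported FC sizes count FVS nodes only — source/input
nodes, which are pinned but fixed in any case, are excluded by
convention.

**DCGS.** The divide-and-conquer framework combines structure and
dynamics:

1. *Condense* the interaction graph of the free nodes into strongly
   connected components (`condensation()`). Each block gets a top-down
   level: $\ell(b) = 1 + \max \ell(\text{upstream blocks})$, 0 for top
   blocks.
2. *Sweep blocks top-down.* For the current block, pin all nodes of
   strictly upper blocks to target values, enumerate the block's minimal
   FVSs on its internal subgraph, and search each FVS's *canalizing
   sets* (`canalizing_sets_for_fvs()`): subsets $S$ of increasing size
   until percolating the pins fixes every FVS node to its target value.
   Only the smallest canalizing sets across the block's FVSs are kept.
3. *Aggregate.* A global control set is the union of one smallest
   canalizing set per block, plus the source-node pins; all
   cross-product combinations are returned (they are interchangeable by
   construction), or one canonical set with `first_only = TRUE`.

The cost is governed by the largest SCC, $O(N_{SCC} \cdot 2^{N_{SCC}})$
rather than $O(2^N)$, because no STG is ever built.

## Canalization percolation

The dynamical engine of DCGS is the *canalizing effect*: when pinned
nodes make some rules constant, their targets are fixed in turn, and the
fixation percolates. `percolate()` computes the least fixed point of
this iteration with a worklist; fixation is monotone, so the result is
independent of visitation order (asserted by test).

A deliberate choice is how "determined" is decided. `is_determined()`
restricts the node's truth table to the fixed inputs and checks whether
**every** completion of the unfixed inputs agrees — an exhaustive check,
not three-valued Kleene evaluation. Kleene is sound but incomplete: it
misses rules that are constant without being syntactically canalized
(`A | !A` is determined to 1 with `A` unfixed). Exhaustiveness costs
$2^k$ evaluations for a rule with $k$ unfixed inputs, negligible at the
in-degrees of biological rules (mean 1.75 here).

Two facts make percolation the correct engine for control:

* *Attractor consistency*: if the pins assign a subset of a fixed point
  $a^*$ its $a^*$-values, every node percolation fixes carries its
  $a^*$-value (soundness).
* *Acyclic completeness*: pinning a full FVS percolates the entire
  network, because the remaining graph is acyclic and values propagate
  topologically. This is why a canalizing set that fixes its whole FVS
  also fixes the whole network.

## Classifying FVS nodes; when DCGS is not minimal

Relative to a target attractor, the nodes of an FVS divide into three
disjoint sets (`classify_fvs()`):

* **canalizing** — a minimal subset that must actually be pinned;
* **canalized** — fixed to target values by percolation of the
  canalizing pins;
* **monostable** — never percolation-fixed, but holding one constant
  value across all attractors of the pinned system (*unconditional* if
  they are consistent even without the pins, *conditional* otherwise).

The classification search relaxes the canalizing-set criterion: a
candidate subset is accepted when percolation fixes no FVS node to a
non-target value and the pinned system's unique attractor is the target,
which requires exhaustive attractor computation — classification is an
analysis-scale operation, unlike DCGS itself.

DCGS deliberately ignores consistency (checking it would need STGs and
destroy scalability). The consequences, quantified on the bundled
fixture world by the acceptance suite:

* when no monostable node exists and some CK lies inside an FVS, DCGS
  sets are exactly CKs (size and validity);
* when monostable nodes exist, DCGS must pin them although a CK need
  not, paying exactly the monostable size;
* in the rare case where **no** CK of the attractor lies inside any FVS
  (1 of 285 fixture attractors; about 0.4%), the canalizing sets are one
  node larger than the CKs yet still stabilize.

A returned DCGS set can fail validation only in monostable cases; the
tool reports the failure with a counterexample attractor rather than
falling back to brute force.

## The synthetic fixture world

`generate_biological_random_network()` emulates the degree and logic
statistics of curated biological Boolean models:

| parameter | default | meaning |
|---|---|---|
| `n` | 10 | node count of fixtures |
| `gamma` | 2.5 | out-degree power law $P(k) \propto k^{-\gamma}$, $k \in 1..n$ (biological exponents lie in 2–3) |
| `lam` | 1.75 | Poisson in-degree mean, truncated to $1..n$ (biological average degree 1.5–2) |
| `min_point_attractors` | 2 | acceptance filter: multistable fixtures only |
| `function_library` | nested canalizing chains | update rules per in-degree |

Wiring is a configuration model: stub pairing with rejection of parallel
edges, self-loops permitted, realized degrees exact. Because the two
stated degree laws have different means (≈1.53 vs ≈2.11 at the
defaults) while any digraph must balance them, the in-degree marginal is
preserved exactly and the out-degree sequence absorbs the mismatch
through ±1 adjustments; only the power-law *shape* of the out-marginal
survives reconciliation, a limitation inherited from the stated laws
themselves.

Update rules come from a library keyed by in-degree. The bundled default
is the full family of nested canalizing chain functions
($s_1 x_1 \ \mathrm{op}_2\ (s_2 x_2\ \mathrm{op}_3\ (\dots)$) with all
sign/operator combinations) — the class biological rules predominantly
belong to. Real model corpora additionally contain non-chain canalizing
functions; a JSON library (`load_function_library()`) can substitute
them. This substitution is the one acknowledged deviation of the fixture
world, and it shows: monostable sets in our fixtures occasionally reach
size 3–4 (about 2% of attractors), a pattern arising when all
multistability is confined to a single self-referencing switch node
while the rest of the cyclic structure is dynamically frozen. With the
original corpus-derived rules, reported monostable sets were all of size
1. A green fixture test therefore establishes algorithmic correctness on
multistable, sparsely connected canalizing networks; it does not certify
the exact monostable-frequency statistics of any particular model
corpus.

## Numerical and representational choices

* **State encoding**: integer bitmask over canonical declaration order,
  node $i$ at bit $i-1$; printed state strings follow declaration order.
  (Bit order is a free choice; it is fixed once and round-trips.)
* **Attractor identity and order**: an attractor is identified by its
  lexicographically smallest state string; cycles are rotated to start
  there, and attractor lists are sorted by that key. All tie-breaks
  (FVS enumeration, canalizing sets, DCGS cross-products) are
  lexicographic on sorted node names, so every result is deterministic.
* **Attractor decomposition**: pointer doubling on the successor array
  ($\lceil \log_2 2^m \rceil$ vectorized passes), then cycle labelling —
  no recursion, no hashing.
* **Limits**: exhaustive operations guard at 22 free nodes (≈4M
  states); hierarchical fixed-point enumeration guards at SCCs of 26
  nodes; FVS search guards at $10^6$ acyclicity tests with advice to
  decompose first. All are `options()`-configurable, and all raise typed
  errors (`dcgs_state_space_too_large`, `dcgs_scc_too_large`,
  `dcgs_fvs_cap_exceeded`) that the CLI maps to distinct exit codes.
* **Degenerate inputs**: constant-rule nodes are sources, pinned in
  every framework but excluded from sizes; an already-acyclic graph has
  the empty FVS, and a block whose canalizing set is empty contributes
  nothing; a candidate whose percolation fixes an FVS node *against* the
  target is rejected, and a pre-pin contradicting the target raises
  `dcgs_impossible_target`.
* **SCC levels**: the hierarchy level is defined by the longest-path
  recurrence from the top. Bottom-up peeling of terminal blocks, an
  equivalent-sounding alternative, assigns different indices to blocks
  that are incomparable in the DAG; the two orderings nevertheless agree
  on every ancestor relation, which is all the DCGS sweep uses.
* **Benchmarking**: `run_benchmark()` targets the major point attractor
  (largest basin, ties lexicographic; beyond the exhaustive limit, the
  lexicographically smallest hierarchical fixed point), applies a
  per-record timeout (default 1 h), records failures as `NA` without
  aborting, and summarizes the regression slope of $\log_2$ time versus
  network size per framework.

## Known limitations

* Synchronous update only; no asynchronous or probabilistic schemes.
* Point-attractor targets only (cyclic targets are refused, see above).
* DCGS is not minimal, and may not even stabilize, in the presence of
  monostable nodes; it reports rather than repairs such cases
  (indirect-fixation search would require STG examination).
* Exhaustive minimal-FVS enumeration is exponential in the size of the
  largest SCC; networks that are one giant SCC with a near-SCC-sized
  FVS defeat the decomposition. Such structures are rare in curated
  biological models.
* The generator does not reproduce any specific published network
  corpus; it reproduces degree/logic statistics.
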