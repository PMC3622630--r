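# superwalk

Exact combinatorial machinery for the **De Bruijn Superwalk with
Multiplicities** (DBSM) model of genome assembly, aimed at researchers and
students studying the complexity of assembly formulations.

In the de Bruijn model of order *k*, vertices are *k*-mers, edges are
(*k*+1)-mers, and each read is a walk in the graph. When per-edge copy
numbers have been estimated, an assembly is a **superwalk**: a walk that
contains every read walk as a contiguous subwalk and traverses each edge *e*
exactly its multiplicity *m(e)* times. DBSM asks whether such a superwalk
exists. This package implements the constructive chain that connects DBSM
to the classical Shortest Common Superstring (SCS) problem:

* **Gadget encoding.** The character gadgets T₀ = `000111` and
  T₁ = `001011` define the encoding T(c₁c₂…cₙ) = T_{c₁}T_{c₂}…T_{cₙ}. Both
  gadgets are balanced (three `0`s, three `1`s) and mutually
  non-overlapping: no proper suffix of either equals a proper prefix of
  either. Consequently L₀(T(S′)) = L₁(T(S′)) = 3|S′|, substrings encode to
  substrings, every suffix/prefix overlap of two encodings has length
  ≡ 0 (mod 6), and every occurrence of T(S₁′) inside T(S₂′) starts at a
  position ≡ 1 (mod 6) — positions are 1-based throughout.
* **Reductions.** `reduce_scs_to_csm()` maps an SCS instance
  ({S₁′,…,Sₙ′}, l′) to the Common Superstring with Multiplicities (CSM)
  instance ({T(Sᵢ′)}, l₀ = l₁ = 3l′); `reduce_csm_to_dbsm()` maps a binary
  CSM instance onto a de Bruijn graph of any order *k* in which character
  `0` becomes the loop `0^(k+1)` and character `1` becomes a cycle of *k*+1
  edges carrying a single `1`. Witness mappings run in both directions
  (`lift_scs_witness()`, `extract_scs_witness()`,
  `map_walk_witness_to_csm()`).
* **Exact solvers.** `solve_scs_exact()` (subset DP over pairwise maximal
  overlaps), `solve_csm_exact()` and `solve_dbsm_exact()` (pruned
  lexicographic depth-first search), and `solve_dbsm_single_edge()` — the
  polynomial Eulerian special case that applies when every read is a single
  edge.
* **Generators.** `exhaustive_scs_corpus()` for instance-by-instance
  equivalence checking, `planted_dbsm()` for guaranteed-YES instances, and
  `perturb_to_no()` for guaranteed-NO negatives.

## Worked example

Take the SCS instance {`01`, `10`} with length bound l′ = 3 and push it
through the whole chain:

```r
library(superwalk)

inst <- scs_instance(c("01", "10"), length_bound = 3)
solve_scs_exact(inst)
#> SCS solver: YES, witness: 101 (2 nodes)

csm <- reduce_scs_to_csm(inst)
csm
#> CSM instance: 2 string(s), multiplicities 0=9, 1=9
solve_csm_exact(csm, force = TRUE)
#> CSM solver: YES, witness: 000111001011000111 (41 nodes)

dbsm <- reduce_csm_to_dbsm(csm, k = 1)
dbsm
#> DBSM instance: k = 1, 3 edge(s), 2 read walk(s), total multiplicity 27
res <- solve_dbsm_exact(dbsm, force = TRUE)
res
#> DBSM solver: YES, witness: 00 00 00 01 10 01 10 01 10 00 00 01 10 00 01 10 01 10 00 00 00 01 10 01 10 01 10 (52 nodes)

map_walk_witness_to_csm(res$witness, build_embedding(1))
#> [1] "000111001011000111"
```

The SCS answer is YES because `101` (length 3 ≤ l′) contains both strings.
The reduced CSM instance asks for a superstring of the two encodings with
exactly nine `0`s and nine `1`s; its lexicographically least witness
`000111001011000111` is T(`010`) — the encoding of the other shortest
superstring. On the order-1 de Bruijn graph the witness walk traverses the
loop `00` nine times and the cycle `01`→`10` nine times, matching the
multiplicities, and parses back to the same CSM witness. Tightening the
bound to l′ = 2 flips all three answers to NO:

```r
solve_scs_exact(scs_instance(c("01", "10"), 2))
#> SCS solver: NO (2 nodes)
```

A command-line interface wrapping the same functions (subcommands `encode`,
`reduce`, `solve`, `verify`, `gen`, `selftest`) is installed at
`system.file("cli", "superwalk", package = "superwalk")`.

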