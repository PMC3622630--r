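---
title: "Methods: gadget encodings, reductions and exact search for assembly superwalks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gadget encodings, reductions and exact search for assembly superwalks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superwalk)
```

## The three problems and why they are chained

Genome assembly under maximum parsimony is the Shortest Common Superstring
problem: given reads $S_1',\dots,S_n'$ over $\{0,1\}$ and a bound $l'$,
decide whether a string of length at most $l'$ contains every read as a
substring. The de Bruijn model replaces strings by walks: vertices are
$k$-mers, edges are $(k{+}1)$-mers, each read is a walk, and — once
per-edge copy numbers are fixed — an assembly is a *superwalk* that
contains every read walk as a contiguous subwalk and traverses each edge
$e$ exactly $m(e)$ times (DBSM). The bridge between the two worlds is the
Common Superstring with Multiplicities problem (CSM): find a string
containing all given strings whose per-character counts $L_c(S)$ equal
prescribed targets $l_c$ exactly. This package implements both reduction
steps constructively, together with witness mappings and exact solvers, so
that the equivalence of the three problems can be *checked instance by
instance* on exhaustive small corpora rather than taken on faith.

## The gadget encoding

`default_gadget_code()` maps `0` to $T_0 = 000111$ and `1` to
$T_1 = 001011$; $T(c_1\dots c_n) = T_{c_1}\cdots T_{c_n}$. Two properties
drive everything:

* **Balance.** Each gadget has three `0`s and three `1`s, so
  $L_0(T(S')) = L_1(T(S')) = 3\,|S'|$. This is why the reduction can set
  $l_0 = l_1 = 3 l'$ and make the CSM length budget *exactly* the encoded
  SCS length bound.
* **Non-overlap.** No proper suffix of either gadget equals a proper
  prefix of either gadget (`verify_nonoverlap()` checks all ordered pairs
  exhaustively). Hence two encodings can only abut on gadget boundaries:
  every suffix/prefix overlap of $T(S_1')$ with $T(S_2')$ has length
  $\equiv 0 \pmod 6$, and every occurrence of $T(S_1')$ in $T(S_2')$
  starts at a position $\equiv 1 \pmod 6$ and projects to a genuine
  occurrence of $S_1'$ in $S_2'$ (`position_to_source()`).

Positions are 1-based everywhere. The empty pattern is defined to occur at
every position $1,\dots,|s|+1$; the alignment properties are stated for
non-empty patterns only. `gadget_code()` is parameterised so that broken
codes (overlapping or unbalanced gadget sets) can be constructed in tests;
only equal lengths and pairwise distinctness are enforced at construction,
while non-overlap is a property to *verify*, not an invariant to assume.

## Reductions and witness mappings

`reduce_scs_to_csm()` encodes every instance string and sets
$l_0 = l_1 = 3l'$. The YES-direction witness map (`lift_scs_witness()`)
pads the SCS witness with `0` to length $l'$ before encoding, so the
character budget is met exactly.

The NO-direction map (`extract_scs_witness()`) must turn an arbitrary CSM
witness $S$ back into an SCS witness. A CSM witness need not be an
encoding image — it may contain filler characters covered by no encoded
string. The construction used here: record the *leftmost* occurrence of
each encoded string in $S$, merge the occurrence intervals into maximal
covered runs, decode each run, and concatenate the decoded runs left to
right. Overlapping encoded occurrences align modulo 6, so each run is an
encoding image and decodes uniquely; every original string lies inside a
single run; and the total covered length is at most $|S| = 6l'$, so the
result respects the bound. Choosing the leftmost occurrence makes the map
deterministic; any single choice per string would do. This constructive
coverage argument deliberately avoids invoking a shortest common
superstring of the encoded strings, which could not be computed in
polynomial time.

`reduce_csm_to_dbsm()` embeds the conceptual one-vertex, two-loop graph
into a genuine order-$k$ de Bruijn graph: character `0` becomes the loop
$0^{k+1}$ at vertex $0^k$ and character `1` becomes the cycle
$0^k1,\,0^{k-1}10,\dots,10^k$ of $k{+}1$ edges through $0^k$. Each CSM
string translates to a read walk (`translate_string_to_walk()`); the loop
gets multiplicity $l_0$ and every cycle edge $l_1$. The graph always has
exactly $k+2$ edges, and the zero edge is kept even when $l_0 = 0$ so the
graph shape is independent of the multiplicities. For alphabets larger
than binary, the first two symbols in alphabet order play the roles of `0`
and `1`; the remaining symbols are unused. The inverse map
(`map_walk_witness_to_csm()`) parses a walk greedily — loop edge to `0`,
complete cycle block to `1` — and rejects partial cycle blocks. For walks
on the embedded graph that meet the multiplicities, block boundaries can
only fall at $0^k$, so the greedy parse cannot fail on verified witnesses;
the error path exists and is exercised synthetically.

## Exact solvers

All searches explore candidates in fixed lexicographic order, so answers
*and witnesses* are deterministic; there is no randomness in any solver.

* `solve_scs_exact()` removes strings that are substrings of others, then
  runs the standard subset dynamic program over pairwise maximal overlaps
  (state: subset of strings, last string). The witness is a shortest
  merge; the answer compares the optimum against $l'$.
* `solve_csm_exact()` builds candidate strings character by character in
  alphabet order, pruning a branch when a character budget is exhausted or
  when some not-yet-matched instance string no longer fits: for every
  unmatched string there must exist a suffix-of-prefix overlap from which
  its remainder fits into the remaining length *and* the remaining
  per-character budgets. Because pruning is sound, the first completed
  candidate is the lexicographically least solution.
* `solve_dbsm_exact()` searches edge sequences depth-first, choosing the
  start vertex implicitly through the first edge, maintaining remaining
  multiplicities and, per read, the set of in-progress partial block
  matches. A branch is pruned when some unmatched read can no longer be
  hosted (remaining length, or a needed edge's remaining multiplicity,
  is insufficient for every continuation point).
* `solve_dbsm_single_edge()` handles the polynomial special case where
  every read is a single edge (empty reads are vacuous): duplicate each
  edge by its multiplicity and test the directed Eulerian-walk conditions
  — per-vertex in/out balance up to one $+1/{-1}$ pair and weak
  connectivity of the positive-multiplicity edges (checked with igraph).
  The witness is built by cycle splicing; with all degrees balanced the
  walk starts at the lexicographically least non-isolated vertex.

Degenerate inputs are defined, not special-cased: empty instances are YES
with empty witnesses, reads through multiplicity-zero edges make an
instance NO via the uniform count check, and a superwalk may start and end
anywhere. Soft size limits (8 substring-free strings for SCS, total
multiplicity 24 for CSM and 30 for DBSM) make the exponential searches
refuse loudly rather than run unbounded; `force = TRUE` overrides them.
Runtimes are polynomial in the *sum* of multiplicities, not their
logarithms — which is why the JSON serializer optionally writes
multiplicities in unary, honouring the convention that they are part of
the input size.

## Instance generators and what they do (not) emulate

`exhaustive_scs_corpus()` enumerates every multiset of at most `max_n`
binary strings of length up to `max_len`, crossed with every bound up to
`max_bound`, duplicate-free under multiset equality. `planted_dbsm()`
draws a uniform random binary genome, samples reads as uniform random
substrings, and sets each edge's multiplicity to its exact traversal count
in the genome's own walk, which is therefore a verifying superwalk for
every seed. `perturb_to_no()` either bumps one multiplicity (breaking the
planted certificate; the result is labelled *unknown* and resolved by the
exact solver, never asserted) or zeroes one read-covered edge
(guaranteeing NO). Every generator is a pure function of its arguments
including the seed.

The generators emulate error-free, single-stranded reads with exact copy
counts — the idealised regime the decision problems are posed in. They do
not model sequencing errors, coverage bias, quality scores or reverse
complements, so passing tests say nothing about robustness to noisy data;
they establish the combinatorial correctness of the encoding, the
reductions and the solvers.

## Suite sizes and numerical choices

The property suites run at sizes chosen to keep exhaustive claims honest
while staying desk-scale: alignment lemmas exhaustively over all binary
pairs up to length 4 plus 1000 seeded random pairs up to length 12;
decode/encode round trips exhaustively to length 8; the equivalence chain
over the full corpus with strings up to length 3, at most 2 strings, and
bounds up to 3, for $k \in \{1,2,3\}$ (480 instances, 1440 doubly-reduced
DBSM solves); Eulerian-vs-exact agreement on 300 random single-edge
instances with total multiplicity at most 12; generator soundness over 100
seeds each way. The doubly-reduced instances exceed the DBSM soft limit by
design (total multiplicity $6l'(k+2)/2$ reaches 45 at $l'=3,k=3$), so the
suites pass `force = TRUE`; the structured pruning keeps those searches
small.

## Limitations

Everything here is exact and exponential-time by intent; nothing scales
beyond desk-size instances, and no heuristic or approximate mode is
provided. The reduction chain is one-directional (SCS into DBSM); mapping
arbitrary DBSM instances to other formalisms is out of scope, as is the
general Chinese Postman problem — only the exact-multiplicity Eulerian
variant needed for the single-edge case is implemented.
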