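---
title: "Permutation systems as behavior-mode programs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Permutation systems as behavior-mode programs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(permutoglia)
```

## The model

The package implements a graph-theoretic model of how the brainstem
reticular formation could generate and arbitrate behavior modes
(sleeping, eating, working, ...). The formal substrate is an *n*-valued
permutation system: the n! orderings of the integers 1..n, acted on by
the n−1 *negation operators* N~1~..N~n−1~, where N~i~ exchanges the
neighboring values i and i+1 inside a permutation. The graph with the
n! permutations as vertices and single negation steps as edges is the
*permutograph* — the Cayley graph of the symmetric group S~n~ with
adjacent-transposition generators. It is (n−1)-regular, connected, and
bipartite by permutation parity, so every closed walk has even length.

A *Hamilton loop* is a closed walk visiting every permutation exactly
once. In the model each such loop is an intentional program: a
candidate behavior mode carried by the glial syncytium and tested
against the neuronal network. A gap-junction plaque stores a redundant
repertoire of loops (each with its reverse run, since behavior modes
come in opposed pairs such as wakefulness–sleeping), and a command
architecture selects abductively — not by deduction from rules, but by
matching environmental evidence against the repertoire and letting the
best-supported program command the whole system for a time (redundancy
of potential command).

## Operator semantics

Two readings of N~i~ exist: exchange the *values* i and i+1 wherever
they stand (value-swap), or exchange the entries at *positions* i and
i+1 (position-swap). The formalism's defining example — converting
1 2 3 4 5 into 1 3 2 4 5 by exchanging the values 2 and 3 — reads the
operator as acting on values, so value-swap is the default. Both semantics are involutions and give
isomorphic permutographs — permutation inversion maps one onto the
other — so `semantics = "position"` is offered as a flag and every
structural result (counts, loop validity from the identity) is
identical under either. The test suite checks the isomorphism
pointwise for n = 3, 4.

## Counting Hamilton loops

For the quadrivalent system, exhaustive backtracking anchored at the
identity vertex finds 88 directed Hamiltonian cycles; identifying each
cycle with its reversal leaves 44 undirected loops. The counting
convention is therefore: **44 counts cycles up to rotation and
reversal; distinguishing directions doubles it to 88.** This is the
only convention consistent with doubling, and it is confirmed by an
independent naive oracle in the test suite (a vertex-sequence DFS with
its own adjacency construction and its own canonicalization, compared
on both counts and canonical key sets). Canonical keys rotate a loop to
start at rank 1 and, for undirected counting, take the
lexicographically smaller of the two directions' operator sequences.

Enumeration is refused for n ≥ 5 (exit code 3 at the command line):
already the pentavalent system's cycle count is far beyond desk-scale
computation, and the model needs only the quadrivalent census plus a
constructive generator. `construct_loop()` provides one verified loop
for any n ≤ 7 via the plain-change (Steinhaus–Johnson–Trotter) order,
whose last permutation differs from the first by one adjacent swap and
therefore closes the cycle. Plain changes are native to position-swap
semantics; for value-swap the operator sequence is reversed, which is
exactly the inversion isomorphism applied to a walk that starts at the
identity. The contract is validity (checked by `verify_loop()`), not a
specific sequence.

The classical tabulations of the quadrivalent system circulate only in
corrupted transcriptions (impossible entries such as 36 in a 24-element
system), so tests anchor on the one clean 24-operator sequence
N₁N₂N₃N₂N₃N₂N₁N₂ repeated three times from 1234 — verified by stepping
through before being frozen into the tests — and on structural
invariants, never on transcribed cells. Likewise the lexicographic
numbering is reconstructed from the lexicographic rule itself (ranks
are 1-based: identity = 1, reversed identity = n!), not from any table.

## The Günther matrix

A single Hamilton loop yields an n! × n! visit-order table: one row per
choice of starting permutation, entry (r, c) the 1-based position of
permutation c in the walk entered at permutation r. Rows are cyclic
relabelings of one another — displacing the start by k positions along
the loop shifts all orders by −k modulo n! — which the tests verify by
brute-force re-walks from displaced starts.

## Plaque kinetics

The biology supplies three numbers and no kinetic law: connexin
half-life 1.5–3.5 h, about 10 % functional channels in a plaque, and
plaque dissolution/reassembly within about 4 h. Defaults are the
mid-range half-life (2.5 h), target functional fraction 0.10, and
lifetime 4 h. The adopted law is the simplest memoryless birth–death
process honoring them: per step of length *dt* (hours) each functional
channel survives with probability 2^−dt/t½^, and nonfunctional channels
convert at the balancing rate r = f(1−s)/(1−f) that pins the expected
functional fraction at the target f. Whether "about 10 %" is a steady
state or a snapshot is not stated; it is treated as a steady state, and
the seeded simulation recovers it within binomial Monte-Carlo error at
10^4^ channels. Dissolution resets the channel population while the
loop repertoire persists — the embodiment of the loops is redundant and
survives plaque turnover. The mapping from individual channels to
individual negation-operator applications is conceptual and is not
modeled mechanically.

## The command architecture

The simulator follows a two-system architecture: perception and
relation computers condense the environment into an
`environment_signal` (a named, non-negative evidence vector plus a
priority); the command computer (`abductive_select()`) picks the mode
with maximal weighted evidence — evidence times per-mode gain, default
gain 1, since the weighting rule itself is unspecified — with ties
broken first by the mode's prior percent share and then by name order,
so with all-zero evidence the 30 % prior puts "Sleeps" in command. The
executive computer (`execute_program_sequence()`) traverses each loop
step by step, one clock tick per negation — the finest granularity the
architecture admits, chosen because nothing finer is observable in the
formalism. A higher-priority signal preempts the active program,
which is logged `REJECTED_BY_PRIORITY`, and replaces the queue —
preempted work is never silently lost.

Each program attempt maps onto one of six realization outcomes: an
erroneous operator sequence (`ERROR_NO_CYCLE`), a valid but
sensorily unsupported cycle (`CYCLE_NOT_REINFORCED`), an activated
cycle (`CYCLE_ACTIVATED`), a feasible cycle outranked by another
program (`REJECTED_BY_PRIORITY`), a cycle not yet in the repertoire
(`NOVEL_CYCLE`), and a repeatedly activated cycle (`IMPRINTED`, default
after 3 activations — a minimal learning rule). Novel cycles do not
enter the repertoire automatically; they must be imprinted first, the
conservative reading of an underdetermined point.

The mode-to-loop binding is also underdetermined ("n-plaque chips"):
the default assigns loops in canonical enumeration order to the 20
packaged mode rows (loop_id 1..20), overridable via the `loop_id`
column.

## The scheduler and what a green test establishes

`run_schedule()` draws a stochastic mode sequence whose expected time
shares equal the repertoire percents: at each switch a mode is drawn
with probability proportional to its percent and held for a geometric
dwell. The default dwell mean is 1 step — i.e. independent per-step
draws — because that is the simplest process with the stated stationary
allocation, and it is the regime in which the binomial 3σ band used by
the acceptance checks (e.g. Sleeps = 30 % ± 0.43 points at 10^5^ steps)
is the correct yardstick. Longer dwells (`dwell_mean > 1`) keep the
expected shares but inflate the variance beyond that band; they model
behavioral persistence, not a different allocation.

The packaged repertoire is the 20-mode table summing to exactly 100 %;
user-supplied tables are accepted within 100 ± 20 % and rejected
outside. The scheduler emulates only the stationary time allocation of
behavior modes. It deliberately does not emulate circadian or ultradian
rhythmicity, mode-transition structure (which mode follows which), or
environmental coupling — so a green share-recovery test establishes
that the sampler is calibrated, not that the sequence resembles a
realistic behavioral time series.

## Numerical and interface choices

- Ranks are 1-based throughout; permutations serialize as digit strings
  for n ≤ 9 and comma-separated integers beyond.
- Valuedness is capped at 8 by default (`max_n` raises it explicitly);
  graphs at 7; enumeration at 4.
- Loop collections are JSON lines with fixed key order and canonical
  loop ordering, so equal sets produce byte-identical files; matrices
  and traces are CSV; configs and scenarios are YAML (JSON accepted by
  extension).
- All randomness flows through R's seeded generator; every CLI run
  logs its config digest and seed, and `--seed` reproduces any run.
  Exit codes: 0 success, 2 validation failure, 3 refusal.
- Edges are stored undirected with an operator label (gap junctions
  conduct bidirectionally); direction is a traversal concern.

## Known limitations

No calcium-wave or neurotransmitter physiology, no connexin-type
distinctions, no spatial plaque geometry, no general group theory
beyond adjacent transpositions, no heuristic Hamiltonian search for
n ≥ 5, and no learning beyond the imprint counter. The glial network
this models has not been experimentally identified; the package is a
formal instrument for exploring the hypothesis, not a fitted biological
model.
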