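# permutoglia

Permutation systems, Hamilton loops, and a glial–neuronal
reticular-formation simulator.

## What this is for

The brainstem reticular formation keeps an organism in exactly one
*mode of behavior* at a time — it sleeps, it eats, it works — and
switches modes according to whichever environmental information is most
compelling. One hypothesis frames this formally: the glial syncytium
(the gap-junction-coupled astrocyte network) generates *intentional
programs* as closed cycles in an n-valued permutation system, and the
neuronal system executes the program that wins command.

`permutoglia` implements that formalism and the simulator built on it,
for anyone who wants to compute with it rather than read about it:

- **Permutation core** — the n! permutations of 1..n in lexicographic
  order, 1-based ranking/unranking, and the n−1 negation operators
  N<sub>i</sub> (exchange of the neighboring values i and i+1; an
  involution).
- **Permutograph** — the operator-labeled graph on all permutations,
  i.e. the Cayley graph of S<sub>n</sub> with adjacent-transposition
  generators: (n−1)-regular, bipartite, connected. Export to GraphML,
  DOT or a CSV edge list.
- **Hamilton loops** — verification, deterministic construction (plain
  changes / Steinhaus–Johnson–Trotter), exhaustive enumeration for the
  quadrivalent system (44 loops up to rotation and reversal, 88
  directed), canonical keys, and the Günther matrix (visit orders for
  every choice of start).
- **Gap-junction plaque** — a container of loop programs closed under
  reversal, with stochastic channel turnover: survival
  2<sup>−dt/t½</sup> per step (half-life default 2.5 h), balancing
  renewal holding ~10 % of channels functional, dissolution and
  reassembly every ~4 h.
- **Reticular simulator** — the 20-mode behavior repertoire (Sleeps
  30 %, Works 25 %, ..., summing to 100 %), abductive program selection
  (argmax of weighted evidence, prior-share tie-break), step-by-step
  program execution with a timing unit, priority interrupts, six-way
  outcome classification, and a seeded mode scheduler.

## Worked example

```r
library(permutoglia)

g <- build_permutograph(4)
g
#> <permutograph> n = 4 (value-swap): 24 vertices, 36 labeled edges
neighbors(g, 1)        # from the identity 1234, one neighbor per operator
#> N1 N2 N3
#>  7  3  2

# a classic 24-operator sequence closes a Hamilton loop from 1234
fig <- hamilton_loop(1:4, rep(c(1, 2, 3, 2, 3, 2, 1, 2), 3))
v <- verify_loop(fig)
v$valid                # TRUE
head(v$visits, 8)      # 1 7 13 19 20 14 8 2 ...

enumerate_loops(4, "undirected")$count
#> 44                   (88 when directions are distinguished)

# a plaque embodying the full repertoire, each loop with its reverse run
p <- build_plaque(enumerate_loops(4)$loops, channel_count = 10000)
p
#> <gap-junction plaque> 88 directed loop programs, 10000 channels (10.0% functional)
ts <- simulate_plaque(p, hours = 12, dt = 0.5, seed = 1)
tail(ts$functional_fraction, 5)
#> 0.104 0.103 0.102 0.101 0.100   # turnover holds the ~10% steady state

# behavior modes: stochastic schedule recovers the configured time shares
rep <- load_default_modes()
s <- run_schedule(rep, duration = 1e5, seed = 1)
head(s[order(-s$expected_pct), ], 3)
#>   mode expected_pct empirical_pct
#> Sleeps           30        30.150
#>  Works           25        24.782
#> Interpersonal attends       8         8.064

# abduction: the best-supported program commands
abductive_select(environment_signal(evidence = c(Eats = 0.9, Sleeps = 0.1)),
                 rep)
#> "Eats"
```

The neighbor ranks (7, 3, 2) are the lexicographic positions of 2134,
1324 and 1243; the loop's visit order walks all 24 permutations once and
closes; 44/88 is the exhaustive Hamiltonian-cycle census of the
quadrivalent permutograph; and the schedule's empirical shares sit
within binomial sampling error of the repertoire percents.

A command-line surface wraps the same operations
(`inst/cli/permutoglia`): `build-graph`, `find-loop`, `verify-loop`,
`enumerate-loops`, `guenther-matrix`, `build-plaque`, `simulate-rf`,
`export`, with `--config`, `--seed`, `--log-level`, `--out`. Exit codes:
0 success, 2 validation failure, 3 refusal (enumeration at n ≥ 5).

## Further reading

`vignettes/permutation-programs.Rmd` documents the model, the counting
convention behind 44/88, the plaque kinetic law and its defaults, the
command architecture's tie-break and outcome rules, and what the green
tests do and do not establish.
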