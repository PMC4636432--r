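---
title: "Exact Moran dynamics on graphs: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact Moran dynamics on graphs: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moranfix)
```

## The model

A population of constant size $N$ occupies the nodes of a graph. Each node
holds one individual: wild-types have fitness $1$, the mutant type has
constant fitness $r > 0$ ($r < 1$ disadvantageous, $r > 1$ advantageous).
One birth and one death happen per time step, and the two update rules
differ only in where selection acts:

* **Birth-death (Bd).** An individual is sampled from the whole population
  with probability proportional to fitness; its offspring replaces a
  uniformly chosen out-neighbour (outgoing link weight $1/k_i$ for a node
  with $k_i$ out-neighbours). Selection is global.
* **death-Birth (dB).** A uniformly chosen individual dies; its
  in-neighbours compete for the vacancy with probability proportional to
  their fitness, so under neutrality replacement is equally probable among
  the neighbours. Selection is local.

Self-replacement is excluded in both rules — there are no self-loops, and a
dying individual does not compete for its own slot. (With self-loops the dB
rule turns into imitation updating, a different process that is out of scope
here, as are the rules with selection at death.)

The state of the process is the set of nodes currently mutant, encoded as a
bitmask integer in $[0, 2^N)$. The all-wild-type and all-mutant
configurations are absorbing; the **fixation probability** $\varphi^G(r)$ is
the probability of reaching the all-mutant state from a single mutant placed
on a node chosen uniformly at random.

## Exact computation

The transition matrix over all $2^N$ configurations is reordered into
canonical form
$$T = \begin{pmatrix} Q & R \\ 0 & I \end{pmatrix},$$
with $Q$ the $t \times t$ block of transient-to-transient probabilities
($t = 2^N - 2$) and $R$ the $t \times 2$ block into extinction and
fixation. The fundamental matrix $F = (I-Q)^{-1}$ gives expected sojourn
times, and absorption probabilities are $\Phi = F R$. `moranfix` never forms
the inverse: `fixation_probabilities()` performs one sparse LU solve of
$(I-Q)\Phi = R$ (`Matrix`), enforcing a residual below $10^{-9}$ in the max
norm. Each row of $Q$ has at most (number of links) non-zeros, so $N = 12$
to $14$ remains practical; at $N = 14$ the canonical matrix has
$(2^{14})^2 \approx 2.7 \cdot 10^8$ entries, of which only a few million
are non-zero.

The assembly itself (`transition_model()`) is vectorised over states: one
pass per directed link classifies all $2^N$ states by the types at its two
endpoints and emits the corresponding triplets, with fitness totals obtained
from precomputed popcounts. `step_distribution()` computes the same
one-step law for a single configuration by direct enumeration; the test
suite checks the two routes against each other row by row, along with row
stochasticity to $10^{-12}$.

Structural short-circuits run before any solve (`fixation_probability()`):

* **Disconnected graphs** (weak connectivity for directed graphs — the
  underlying skeleton) get $\varphi = 0$: no single mutant can reach every
  component. Treating directed graphs through their undirected skeleton is
  our own convention for a case the theory leaves open; it keeps the
  "disconnected" category identical for directed and undirected ensembles.
* **One-rooted directed graphs** (exactly one node with in-degree zero and
  positive out-degree) get $\varphi = 1/N$ exactly: only a mutant on the
  root can fix, and from there its lineage fixes with probability one.
* **Multi-rooted graphs** get $\varphi = 0$. We generalise this to any
  directed graph with more than one *source strongly-connected component*:
  such graphs have no in-degree-zero node in some cases, yet fixation from a
  single start is still impossible, and without the short-circuit the
  mixed recurrent classes would make $(I-Q)$ singular. Classification
  reports these under the `multi_rooted` label.

Two further conventions the process definition does not pin down:

* **Bd on a node with no out-neighbour** (possible in directed graphs):
  such nodes are excluded from the birth lottery. This is equivalent to
  letting them win the lottery and treating the event as a null
  self-transition — a state-dependent lazification that leaves absorption
  probabilities unchanged — and the equivalence is asserted against a dense
  oracle in the tests.
* **dB on a node with no in-neighbour**: unreachable after the root
  short-circuits (such a node is either a root or isolated), so the full
  solver refuses these inputs rather than inventing semantics.

## Closed forms used as oracles

For the complete graph (the well-mixed population) the chain is
tri-diagonal in the number of mutants and
$$\varphi^M = \frac{1}{1 + \sum_{k=1}^{N-1}\prod_{j=1}^{k} T_j^-/T_j^+}$$
collapses to
$$\varphi^M_{Bd} = \frac{1 - 1/r}{1 - 1/r^N}, \qquad
  \varphi^M_{dB} = \frac{N-1}{N}\,\frac{1 - 1/r}{1 - 1/r^{N-1}}.$$
Both are special-cased to their limit $1/N$ at $r = 1$ instead of relying on
floating-point cancellation. The two references differ noticeably at small
$N$, which is why `reference_phi()` always matches the reference to the
update rule — comparing a dB graph against the Bd reference would
misclassify systematically at these sizes.

On a cycle the mutants always occupy a contiguous arc, so the $2^N$ chain
reduces exactly to the mutant count. For dB the interior rates are
$T_j^+ = \tfrac{2}{N}\tfrac{r}{r+1}$, $T_j^- = \tfrac{2}{N}\tfrac{1}{r+1}$,
with boundary cases $T_1^- = 1/N$ (a lone mutant that dies is surely
replaced) and $T_{N-1}^+ = 1/N$ (the last wild-type that dies is surely
replaced). The general-$N$ reduction is gated twice in the tests — exact
agreement with the hand-derived $N = 4$ rates and with the full $2^N$
solver for $N = 4..10$. At
$N = 4$ this yields $\varphi^\circ_{dB} = 2r^2/(3r^2+2r+3)$ and the deficit
$$\varphi^\circ_{dB} - \varphi^M_{dB}
  = \frac{-r^2(r-1)^2}{4(r^2+r+1)(3r^2+2r+3)} \le 0,$$
zero only at $r = 1$: the cycle under dB lowers fixation for advantageous
*and* disadvantageous mutants, making it neither an amplifier nor a
suppressor. The general-$N$ inequality is verified numerically on a grid
($N = 4..12$, $r \in (0, 3]$) rather than re-deriving the algebraic proof.

## Classification

`classify_graph()` probes $\varphi^G$ at $r = 0.75$ and $r = 1.25, 1.5,
1.75$ (the defaults of `classification_config()`): **amplifier** if
$\varphi^G < \varphi^M$ at the disadvantageous value and
$\varphi^G > \varphi^M$ at every advantageous value, **suppressor** for the
reversed pattern, otherwise **unclassified**. $r = 1$ is computed as a
sanity check ($\varphi = 1/N$ exactly, by the neutral-lineage coupling
argument) but takes no part in the decision. Five probe values suffice for
these graph sizes but cannot exclude exotic asymptotics at large $r$; that
caveat is inherent to the probe-based definition.

Equality handling is explicit rather than left to floating point:
differences with
$|\varphi^G - \varphi^M| \le 10^{-9}$ (configurable) count as ties. A graph
tied at every probe is labelled `wellmixed_equivalent`; under Bd, isothermal
graphs — equal replacement temperature at every node, which the isothermal
theorem maps exactly onto the well-mixed case — are labelled that way
without solving. Unclassified graphs are subdivided into `"margin"` (some
decision difference fell within tolerance — an audit flag, not a result)
and `"mixed"` (a genuinely mixed sign pattern, like the cycle under dB),
and every classification records its minimum decision margin so borderline
calls are auditable.

## The synthetic ensembles

`er_graph()` draws $G(N, p)$ graphs: each of the $\binom{N}{2}$ (undirected)
or $N(N-1)$ (directed) possible links is present independently with
probability $p$, never a self-loop. This is the study condition the
ensemble experiments emulate; `run_sweep()` drives it over a $p$-grid
(defaults: 21 evenly spaced values, 200 graphs per point) and
classifies every sample — the grid and ensemble size are config knobs with
those defaults — deriving a per-graph sub-seed from the sweep seed
so any single graph can be replayed exactly. Analytic overlays accompany
the empirical fractions:

* connectivity $P_N$ from the recursion
  $P_N = 1 - \sum_{K=1}^{N-1}\binom{N-1}{K-1}P_K(1-p)^{K(N-K)}$, $P_1 = 1$
  (at $N=4$: $-6p^6 + 24p^5 - 33p^4 + 16p^3$);
* the $N = 4$ isothermal probability $p^6 + 3p^4(1-p)^2$
  (complete graph plus the three labelled 4-cycles);
* for directed ensembles, the probability
  $1 - (1 - (1-p)^{N-1})^N$ of at least one in-degree-zero node.

The tests require empirical fractions to track these curves within three
binomial standard errors. For directed ensembles one could either classify
every sampled graph or condition on connectivity first; the sweep output
reports all categories side by side (disconnected and rooted graphs are
their own labels), so both views can be read off the same table.

What the generator does *not* emulate: degree-correlated or scale-free
structure, weighted links, and mutant placement biased by reproduction
rates (uniform placement is assumed throughout). Conclusions from passing
tests are therefore about small dense-ish ER ensembles, not about real
contact networks.

## The Monte-Carlo check

`simulate_fixation()` (compiled) runs the chain from a uniformly random
single-mutant start to absorption and reports the fixation frequency with
its binomial standard error. It is deliberately the *independent* route:
the exact solver must agree with it within three standard errors across a
randomised battery. It also illustrates why the exact route is the
workhorse — classification margins are often $10^{-3}$ or smaller
(see the census table: the cycle's dB margin is $6 \cdot 10^{-4}$), which
a $3\sigma$ simulation criterion would need $\sim 10^7$ realisations per
$r$ to resolve.

## Problem sizes and numerical choices

The shipped experiments use exhaustive enumeration at $N = 4$ (all six
connected graphs up to isomorphism, brute-forced over the $2^6$ labelled
graphs with pairwise isomorphism checks), ensembles of several hundred
connected ER graphs at $N = 6..10$ for the dB amplifier search, 50-graph
ensembles at $N = 8$ for the Bd/dB contrast, and $10^5$ Monte-Carlo
realisations per cross-check. These sizes resolve every claim the package
makes while keeping the full suite in the minutes range on a single core;
the solver itself is validated up to $N = 14$ (matrix assembly) and
$N = 12$ (cycle solves against the arc reduction).

Other fixed choices: transient states are ordered by bitmask value with the
absorbing pair appended last (deterministic layout, trivial
serialisation); wild-type fitness is exactly 1 and $r > 0$ is enforced;
solver residuals above $10^{-9}$ are an error, never a warning; edge lists
serialise as a one-line header (`N directed|undirected`) plus 0-based
`i j` pairs, so graphs round-trip through plain text without a format
dependency.

## Known limitations

* The $2^N$ state space caps exact solves near $N = 14$; symmetry
  reduction would help individual graphs but not ensemble screening.
* Probe-based classification can in principle mislabel a graph whose
  fixation curve crosses the reference outside the probe set.
* The dB amplifier search is evidence of absence at the tested sizes and
  ensembles, not a proof that dB amplifiers do not exist.
* Fixation *times* are not exposed, although the fundamental matrix
  computes them as a by-product; game-theoretic (frequency-dependent)
  fitness and the bD/Db/BD/DB rule variants are out of scope.
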