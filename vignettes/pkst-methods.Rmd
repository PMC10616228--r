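---
title: "Models and methods behind pkst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pkst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkst)
```

`pkst` models human problem solving on well-structured tasks as navigation
of a *problem space* and assesses individuals adaptively from either their
correct/incorrect answers or their full move sequences. This vignette lays
out the models, the choices we made where the mathematics or the data
generation left genuine freedom, and what the bundled simulations do and do
not establish.

## From problem spaces to knowledge spaces

A problem space is a triple `(S, Ω, ·)`: a finite state set, a finite
operation set, and a deterministic partial action of operation strings on
states. A problem is an ordered pair of distinct states `(s, t)` with `t`
reachable from `s`. The Tower of London generator (`tol_space()`) builds
the canonical example: three pegs of capacities 3, 2, 1 and three colored
balls give 6 occupancy arrangements × 6 color permutations = 36 states, 108
legal moves, and 1260 problems. State identifiers spell the peg contents
("12|3|"); the arrangement and permutation indices are exposed so that any
external numbering of the states can be attached as a lookup table.

A *goal space* singles out an absorbing goal `g` and failure `f`; every
other state must reach `g`. For tasks scored like the ToL — credit only for
minimum-length solutions — the *shortest-path* construction keeps exactly
the distance-decreasing moves and routes every other legal move to `f`.
Failure entry is therefore "any off-path move" and carries no operation
label of its own; the number of off-path moves per state varies (0–3 in the
full ToL space) and is irrelevant to the model, which only needs the
aggregate failure rate.

Solution paths of a problem `(s, g)` are its minimum-length move sequences.
The subpath relation orders them: `sπ ⊑ tσ` when `σ = απβ` and applying
`α` to `t` lands on `s`. A *competence state* is a path set downward closed
under `⊑`; the *problem function* `p(C)` collects the problems solved by at
least one path in `C`; the image family `𝒦 = {p(C)}` is the derived
knowledge space.

### Two readings of the subpath relation

The package implements two readings of "`π` occurs inside `σ`":

* **anchored** — the literal factorization above: the occurrence must start
  at the matching state (`t·α = s`). Because operations of this kind are
  injective and all solution paths end at the goal, anchored subpaths of a
  solution path are exactly its suffixes.
* **sequence** (default for derivations) — only the operation string of
  `π` must occur contiguously in that of `σ`. This treats a skill as a
  *movement pattern*: mastering "swap these two balls through the spare
  peg" transfers to every context where that maneuver is required, not only
  to the one embedded in the longer path at the matching state.

The two coincide on the nine-state running example (13 competence states,
11 knowledge states either way) but differ on the full ToL goal space,
where the same maneuver recurs at different states along longer paths: the
sequence reading yields 242,498 knowledge states for the designated goal,
the anchored reading 525,265. We default to the sequence reading for
`competence_space()` and `knowledge_space()` — it is the cognitively more
generous assumption and matches the scale of knowledge spaces reported for
this task family — while `is_subpath()` defaults to the literal anchored
definition. Both are one argument away everywhere.

### The designated goal state

Removing one-move problems from the 35-problem full goal space leaves 31
exactly when the goal admits four legal moves. Two occupancy types qualify,
(2,1,0) and (1,1,1); only the (2,1,0) type gives 11 problems with more than
one minimum-length solution (the (1,1,1) type gives 13), so
`tol_goal_state()` designates the (2,1,0)-type state (color permutation 1,
id `"12|3|"`) and `tol_goal_candidates()` lists all eligible states.

### Computing the knowledge space

Every down-set is a union of principal down-sets and `p` distributes over
union, so `𝒦` is the union closure of the atoms `p(↓π)` plus the empty
set — no enumeration of the (astronomically larger) competence space is
needed. States are bitmasks chunked 31 bits per integer; closure is
incremental (each atom is OR-ed into the family, then the family is
deduplicated), so the cost is proportional to the final family size. The
242,498-state ToL space derives in well under a minute on one core.
Explicit competence-space enumeration (`competence_space()`) stays
available for small path sets, guarded at `2^20` states.

## The Markov solution process model

Given a knowledge state `K`, the move from state `i` to `j` (an elementary
pair of the goal space, including `(i, f)`) has probability `β_ij` when the
solver "knows what they are doing" and `η_ij` otherwise; rows are completed
by failure residuals `β_if = 1 − Σβ_ij`, `η_if = 1 − Ση_ij`. What "knowing"
means is the planning assumption:

| administered problem in `K` | current problem in `K` | msp1 | msp2 | msp3 |
|---|---|---|---|---|
| yes | yes | β | β | β |
| yes | no  | β | η | η |
| no  | yes | η | β | η |
| no  | no  | η | η | η |

`msp1` is pre-planning (the whole solution is planned up front), `msp2`
interim planning (each move depends on the current position only), `msp3`
their conjunction. An intermediate state whose problem is not in the domain
(for example a one-move state after one-move problems were dropped) counts
as *not* in `K`; this convention reproduces the worked examples'
likelihoods and keeps `K ⊆ Q` meaningful.

## Adaptive assessment

All engines maintain a likelihood over the knowledge structure, select the
next problem by half-split (minimize `|2ℒ(𝒦_q) − 1|`, ties broken uniformly
at random within an absolute tolerance of 1e−12), and stop once some state
exceeds the threshold `p ∈ (.5, 1]` (default .5, the smallest value that
guarantees a unique modal state) or the domain is exhausted. Problems are
administered without replacement by default (`allow_repeats` restores the
general procedure). The CMP updates once per response with careless/lucky
rates `β_q, η_q`; the MSP engines update once per observed move with the
dispatched `β_ij`/`η_ij`. Both updates are plain Bayes rules and have
equivalent multiplicative forms (`ζ_{q,1} = (1−β_q)/η_q`,
`ζ_{q,0} = (1−η_q)/β_q`; per move `ζ = β_ij/η_ij`, or `η_if/β_if` on a
failure transition, applicable whenever `β_ij > η_ij` off the failure
column and `η_if > β_if` on it); the equivalences are verified to machine
precision in the test suite. Weights are renormalized after every update
(sum-to-one tolerance 1e−12), which doubles as underflow control at the
scales shipped here; for structures far beyond 10^5 states a log-space
accumulator would be the next step.

## The synthetic-data generator

`generate_params()`, `sample_states()`, `simulate_process()` and
`simulate_cohort()` emulate a complete simulation study:

* **Transition tables.** Per non-absorbing state, the careless residual
  `β_if ~ U(0, x]` and the lucky-guess mass `1 − η_if ~ U(0, x]`; the
  remaining row mass is split over the on-path successors by normalized
  uniform draws. `x` is thus the *maximum per-move error of either kind* —
  `x = .01` makes knowers almost surely stay on path and guessers almost
  surely fail at once, `x = .20` allows substantial careless slips and
  lucky guesses. (An alternative convention draws `η_if` itself uniformly
  on `(0, 1−x]`; that makes guessers arbitrarily lucky in *both* error
  conditions, leaves matched-engine recovery near chance, and contradicts
  reading `x` as the maximum error level, so we do not use it.)
* **True states.** A random distribution over the structure (normalized
  uniform weights) is drawn once, then subjects are sampled i.i.d. from it;
  the draw is shared across conditions on the same structure.
* **Processes.** Moves are sampled from the dispatched categorical rows
  until goal or failure; absorption is guaranteed by the goal-space
  structure, and in a shortest-path space a goal-terminated process can
  never undercut the minimum length.

Every stochastic component takes a seed; cohort simulation derives one seed
per (subject, problem) so any record regenerates in isolation.

`run_study()` scores each engine at every step `m`: a subject's likelihood
is frozen at the termination step for the per-`m` Hamming and entropy
series (the only reading under which the proportion-terminated curve is
monotone), while the true-positive rate uses the modal state after the full
domain has been administered. The CMP needs per-problem `β_q, η_q` that a
process-level generator does not supply; we derive them from the generating
table as absorption probabilities — `β_q = 1 − P(reach goal from s0 | β
rows)`, `η_q = P(reach goal | η rows)` — computed by backward induction on
the distance layers, so the dichotomous model is exactly the one implied by
the process model.

### What the simulations do and do not show

The bundled study conditions run on the nine-state fragment's 11-state
structure (5 problems, N up to 155) and finish in seconds; the test suite
states these sizes explicitly. Passing them shows that matched
generator/engine pairs recover states near-perfectly at low error and
degrade gracefully at high error, that the monotonicities hold, and that
all four engines consume identical data faithfully. It does not establish
performance on real participants: simulated guessers follow the same
parametric family the engines assume (no model misfit), problems are
administered exhaustively rather than by a clinician's protocol, and
response times, learning during the test, and strategy shifts are outside
the model. Replaying real logs of the same JSONL shape (`replay_log()`)
reports efficiency and stability metrics only, since true states are then
unknown.

## Numerical and degenerate-input conventions

* Domains are ordered lexicographically inside bitmasks; serialized
  structures record the order.
* Arg-max/arg-min ties use an absolute tolerance of 1e−12 and are broken
  uniformly at random with the caller's seed, for reproducible tie sets
  across platforms.
* An all-zero posterior (impossible data under every state) raises an
  error rather than renormalizing.
* A single-state space has no problems; an unreachable goal raises the
  goal-space reachability error; probability tables with row sums above 1
  are rejected at construction.
* All file formats round-trip exactly (numbers written at full precision).

## Known limitations

* The anchored/sequence choice matters for large spaces and real
  decisions between them would need behavioral evidence on skill transfer.
* The competence space is only enumerated explicitly below `2^20` states;
  beyond that only the knowledge space is available.
* `run_study()` holds the knowledge structure fixed and known; structure
  learning from data is out of scope.
* The CMP item parameters used on simulated data are model-implied; with
  empirically calibrated `β_q, η_q` its relative performance could differ.
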