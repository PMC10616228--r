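# pkst

Procedural knowledge space theory (PKST) in R: formal models and adaptive
assessment of human problem solving in well-structured tasks such as the
Tower of London (ToL) test of planning ability.

## The problem

Neuropsychological planning tests present a sequence of puzzles and
traditionally score each as correct/incorrect. That discards two things: the
structural relations among the puzzles (solving a problem along a solution
path implies mastering every sub-problem encountered along that path) and
the observable move-by-move solution process. `pkst` implements the
machinery to exploit both:

* **Problem spaces** — finite labeled deterministic transition systems
  `(S, Ω, ·)`: states, operations, and operation application with
  `s·ε = s` and `(s·σ)·π = s·σπ`. A *problem* is a pair `(s, t)` with `t`
  reachable from `s`. The bundled ToL generator produces the classical
  36-state, 108-move space with 1260 problems.
* **Goal spaces** — problem spaces with absorbing goal `g` and failure `f`
  states. In a *shortest-path* goal space a move that leaves every
  minimum-length path to `g` enters `f`, so solving means solving in the
  minimum number of moves.
* **Skill maps and derived structures** — solution paths `sπ` ordered by
  the subpath relation `⊑`; competence states (path sets downward closed
  under `⊑`); the problem function `p(C) = {q : τ(q) ∩ C ≠ ∅}`; and the
  knowledge space `𝒦 = {p(C)}`, computed as the union closure of the atoms
  `p(↓π)` over bitmask families (the full ToL goal space yields 242,498
  knowledge states in well under a minute).
* **The Markov solution process model (MSPM)** — per elementary move
  `(i, j)` a rate `β_ij` (solver knows a relevant solution path) or `η_ij`
  (solver guesses), dispatched by a planning assumption: pre-planning
  (`msp1`, membership of the administered problem), interim planning
  (`msp2`, membership of the current problem), or mixed planning (`msp3`,
  both).
* **Adaptive assessment** — the continuous Markov procedure (CMP) on
  dichotomous responses and MSP-based procedures that update the likelihood
  `ℒ(K)` once per observed move, both with half-split question selection
  (minimize `|2ℒ(𝒦_q) − 1|`) and threshold termination; plus a
  simulation-study harness with accuracy (Hamming distance, true-positive
  rate) and efficiency (entropy, termination curves) metrics.

## A worked assessment

A problem solver whose latent knowledge state is `{s1, s3, s4, s7, s8}`
(problems of the nine-state ToL fragment shipped as `fig2_space()`, all with
goal `s9`) is assessed move by move under mixed planning:

```r
library(pkst)

ks <- ktol_structure()        # the 11-state knowledge structure
gs <- fig2_goal_space()       # nine-state shortest-path goal space, goal s9

rec <- run_assessment(
  ks,
  list(s4 = c("s4", "s6", "s8", "s9"),                  # observed processes
       s1 = c("s1", "s3", "s5", "s7", "s8", "s9")),
  engine = "msp3", gs = gs, params = table4_params(),
  threshold = 0.5, seed = 1)

tidy(rec)
#> # A tibble: 2 × 7
#>       m problem response          max_likelihood entropy terminated modal_set
#>   <int> <chr>   <chr>                      <dbl>   <dbl> <lgl>      <list>
#> 1     1 s4      s4>s6>s8>s9                0.167   2.59  FALSE      <chr [4]>
#> 2     2 s1      s1>s3>s5>s7>s8>s9          0.918   0.449 TRUE       <chr [5]>

glance(rec)
#> # A tibble: 1 × 6
#>   engine n_questions terminated max_likelihood entropy estimate
#>   <chr>        <int> <lgl>               <dbl>   <dbl> <chr>
#> 1 msp3             2 TRUE                0.918   0.449 s1,s3,s4,s7,s8
```

After the first problem (`s4`, solved via `s6` and `s8`) every state
containing both `s4` and `s8` has likelihood .17; the second process solves
`s1` and, because its path contains solutions of `s3`, `s7` and `s8` as
subpaths, the likelihood of the true state jumps to .92 — above the .5
threshold, so the assessment stops after two problems. The classical CMP on
correct/incorrect responses alone needs three (see
`vignette("pkst-methods")`).

Larger-scale use follows the same verbs: `tol_space()` →
`goal_space(..., drop_one_move = TRUE)` → `solution_paths()` →
`knowledge_space()` gives the full 242,498-state ToL space, and
`run_study()` simulates cohorts under any of the three generative
assumptions and scores all four engines on them.

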