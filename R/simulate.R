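#' Simulate a solution process under the MSPM
#'
#' Starting from the problem's initial state, each move is drawn from the
#' categorical distribution over the on-path successors and the failure state
#' given by the row of `beta` (solver in the know) or `eta` (solver guessing)
#' parameters selected by the planning assumption; the process stops on
#' entering the goal or the failure state. Termination is guaranteed by the
#' goal-space structure.
#'
#' @param gs A [goal_space()].
#' @param params A [transition_params()] table for `gs`.
#' @param q Problem: the initial state of a domain problem.
#' @param K Knowledge state: character vector of mastered domain problems.
#' @param assumption Planning assumption, `"msp1"`, `"msp2"` or `"msp3"`.
#' @param seed Optional integer seed.
#' @return A `solution_process`: list with `problem`, `visited` (state
#'   sequence from `q` to the terminal state) and `terminal` (`"goal"` or
#'   `"failure"`).
#' @examples
#' gs <- fig2_goal_space()
#' simulate_process(gs, table4_params(), "s4",
#'                  K = c("s1", "s3", "s4", "s7", "s8"), "msp3", seed = 1)
#' @export
simulate_process <- function(gs, params, q, K, assumption, seed = NULL) {
  if (!q %in% gs$domain$initial) stop("problem ", q, " not in the goal-space domain")
  assumption <- match.arg(assumption, c("msp1", "msp2", "msp3"))
  with_seed_if(seed, {
    visited <- q
    cur <- q
    while (!cur %in% c(gs$goal, gs$failure)) {
      succs <- c(sp_successors(gs, cur)$to, gs$failure)
      pr <- vapply(succs, function(j) {
        transition_prob(params, cur, j, q, K, assumption, gs)
      }, 0)
      cur <- sample(succs, 1L, prob = pr)
      visited <- c(visited, cur)
    }
    structure(list(problem = q, visited = visited,
                   terminal = if (cur == gs$goal) "goal" else "failure"),
              class = "solution_process")
  })
}

#' @export
print.solution_process <- function(x, ...) {
  cat("<solution_process> ", paste(x$visited, collapse = " -> "),
      " [", x$terminal, "]\n", sep = "")
  invisible(x)
}

#' Dichotomize a solution process
#'
#' @param sp A `solution_process` (or a bare visited-state vector).
#' @param gs The [goal_space()] it was observed in.
#' @return `1L` if the process ended at the goal, `0L` at failure.
#' @export
dichotomize <- function(sp, gs) {
  visited <- if (inherits(sp, "solution_process")) sp$visited else sp
  last <- visited[length(visited)]
  if (last == gs$goal) return(1L)
  if (last == gs$failure) return(0L)
  stop("process is not terminal: ends at ", last)
}

#' Sample knowledge states from a random distribution
#'
#' Generates a random probability distribution over the states of a
#' knowledge structure (independent uniform weights, normalized) and draws
#' `n` states i.i.d. from it. Both the distribution and the draws are
#' reproducible from the seed.
#'
#' @param ks A [knowledge_structure()].
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @param weights Optional fixed probability vector over states (overrides
#'   the random distribution).
#' @return A list with `states` (integer state indices, length `n`) and
#'   `distribution` (the probability vector used).
#' @export
sample_states <- function(ks, n, seed = NULL, weights = NULL) {
  with_seed_if(seed, {
    w <- weights %||% stats::runif(ks$n_states)
    w <- w / sum(w)
    idx <- if (n > 0) sample.int(ks$n_states, n, replace = TRUE, prob = w) else integer(0)
    list(states = idx, distribution = w)
  })
}

#' Simulate a full response cohort
#'
#' For each subject (a true knowledge state) simulates one solution process
#' per domain problem under the generative assumption, the raw material of a
#' simulation-study condition. Each subject/problem pair uses its own derived
#' seed so any record can be regenerated in isolation.
#'
#' @param gs A [goal_space()].
#' @param params A [transition_params()] table.
#' @param true_states List (or vector) of knowledge states: each a character
#'   vector of mastered problems.
#' @param assumption Generative planning assumption.
#' @param seed Integer root seed.
#' @return A tibble with columns `subject`, `problem`, `visited`
#'   (list-column of state sequences), `terminal` and `correct`.
#' @export
simulate_cohort <- function(gs, params, true_states, assumption, seed = 1L) {
  dom <- gs$domain$initial
  rows <- vector("list", length(true_states) * length(dom))
  k <- 0L
  for (w in seq_along(true_states)) {
    for (qi in seq_along(dom)) {
      k <- k + 1L
      sp <- simulate_process(gs, params, dom[qi], true_states[[w]], assumption,
                             seed = derive_seed(seed, k))
      rows[[k]] <- tibble::tibble(
        subject = w, problem = dom[qi], visited = list(sp$visited),
        terminal = sp$terminal, correct = dichotomize(sp, gs)
      )
    }
  }
  dplyr::bind_rows(rows)
}
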