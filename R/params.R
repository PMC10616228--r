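#' Transition parameter tables for the Markov solution process model
#'
#' The MSPM attaches to every elementary transition `(i, j)` two free
#' parameters: `beta[i, j]`, the move probability of a solver who knows a
#' solution path of the relevant problem, and `eta[i, j]`, the corresponding
#' guessing probability of a solver who does not. Rows are completed by the
#' failure residuals `beta[i, f] = 1 - sum_j beta[i, j]` and
#' `eta[i, f] = 1 - sum_j eta[i, j]`, so every row of the implied transition
#' matrix is stochastic. `transition_params()` validates a user table;
#' `generate_params()` draws one at random for a goal space.
#'
#' @param table A data frame with columns `i`, `j`, `beta`, `eta`, one row
#'   per on-path elementary transition (failure residuals are implicit).
#' @param gs Optional [goal_space()]; when given, rows are checked against
#'   its elementary pairs.
#' @return A `transition_params` object: the tibble plus per-state failure
#'   residual attributes.
#' @examples
#' table4_params()
#' @export
transition_params <- function(table, gs = NULL) {
  tab <- tibble::as_tibble(table[c("i", "j", "beta", "eta")])
  tab$i <- as.character(tab$i)
  tab$j <- as.character(tab$j)
  if (any(tab$beta < 0 | tab$beta > 1 | tab$eta < 0 | tab$eta > 1)) {
    stop("beta and eta must lie in [0, 1]")
  }
  if (!is.null(gs)) {
    ep <- elementary_pairs(gs)
    on <- ep[ep$j != gs$failure, ]
    bad <- !paste(tab$i, tab$j) %in% c(paste(on$i, on$j), paste(gs$goal, gs$goal))
    if (any(bad)) stop("not an elementary pair of the goal space: (",
                       tab$i[bad][1], ", ", tab$j[bad][1], ")")
  }
  bsum <- tapply(tab$beta, tab$i, sum)
  esum <- tapply(tab$eta, tab$i, sum)
  if (any(bsum > 1 + 1e-9) || any(esum > 1 + 1e-9)) {
    stop("row sums exceed 1; failure residuals would be negative")
  }
  structure(tab, class = c("transition_params", class(tab)),
            beta_fail = 1 - bsum, eta_fail = 1 - esum)
}

#' @export
print.transition_params <- function(x, ...) {
  cat("<transition_params> ", nrow(x), " elementary transitions\n", sep = "")
  NextMethod()
}

# look up beta/eta for a transition, resolving failure residuals
lookup_rates <- function(params, i, j, failure) {
  if (identical(j, failure)) {
    b <- attr(params, "beta_fail")[i]
    e <- attr(params, "eta_fail")[i]
    if (is.na(b)) stop("state ", i, " has no parameter rows")
    return(c(beta = unname(b), eta = unname(e)))
  }
  hit <- which(params$i == i & params$j == j)
  if (!length(hit)) stop("(", i, ", ", j, ") is not an elementary pair with parameters")
  c(beta = params$beta[hit], eta = params$eta[hit])
}

#' @rdname transition_params
#' @param x Maximum error level of the generated data: per non-absorbing
#'   state `i` the careless-error residual `beta[i, f]` is drawn uniformly
#'   from `(0, x]` and the lucky-guess mass `1 - eta[i, f]` uniformly from
#'   `(0, x]` (so `eta[i, f]` lies in `[1 - x, 1)`); both error sources are
#'   bounded by `x` per move. The study design uses `x = .01` (low error)
#'   and `x = .20` (high error).
#' @param seed Optional integer seed; equal seeds give identical tables.
#' @export
generate_params <- function(gs, x, seed = NULL) {
  stopifnot(inherits(gs, "goal_space"))
  if (!(is.numeric(x) && length(x) == 1L && x > 0 && x < 1)) {
    stop("error level x must lie in (0, 1)")
  }
  with_seed_if(seed, {
    rows <- list()
    for (i in names(gs$dist)[gs$dist >= 1]) {
      succs <- sp_successors(gs, i)$to
      b_f <- stats::runif(1, 0, x)
      e_f <- 1 - stats::runif(1, 0, x)
      bw <- stats::runif(length(succs))
      ew <- stats::runif(length(succs))
      rows[[length(rows) + 1L]] <- tibble::tibble(
        i = i, j = succs,
        beta = bw / sum(bw) * (1 - b_f),
        eta = ew / sum(ew) * (1 - e_f)
      )
    }
    transition_params(dplyr::bind_rows(rows), gs)
  })
}

#' Single-move transition probability under a planning assumption
#'
#' Dispatches between `beta[i, j]` and `eta[i, j]` according to the planning
#' assumption: `msp1` (pre-planning) uses `beta` iff the administered problem
#' `(s0, g)` is in the knowledge state `K`; `msp2` (interim planning) uses
#' `beta` iff the current problem `(i, g)` is in `K`; `msp3` (mixed planning)
#' requires both. A state `i` whose problem `(i, g)` is not in the domain
#' counts as not in `K`.
#'
#' @param params A [transition_params()] table.
#' @param i,j Current and next problem state (`j` may be the failure state).
#' @param s0 Initial state of the administered problem.
#' @param K Knowledge state: character vector of domain problems mastered.
#' @param assumption One of `"msp1"`, `"msp2"`, `"msp3"`.
#' @param gs The [goal_space()] (identifies the failure state and domain).
#' @return A single probability.
#' @export
transition_prob <- function(params, i, j, s0, K, assumption, gs) {
  rates <- lookup_rates(params, i, j, gs$failure)
  dom <- gs$domain$initial
  in_s0 <- s0 %in% dom && s0 %in% K
  in_i <- i %in% dom && i %in% K
  use_beta <- switch(match.arg(assumption, c("msp1", "msp2", "msp3")),
                     msp1 = in_s0, msp2 = in_i, msp3 = in_s0 && in_i)
  unname(if (use_beta) rates["beta"] else rates["eta"])
}
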