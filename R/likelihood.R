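#' Likelihood distributions over knowledge states
#'
#' Adaptive assessment maintains a probability distribution over the states
#' of a knowledge structure, updated after every observed response (or every
#' observed move). `uniform_likelihood()` is the usual uninformative starting
#' point.
#'
#' @param ks A [knowledge_structure()].
#' @param weights Optional non-negative weights (normalized internally).
#' @return A `likelihood` object: list with `structure` and `weights`
#'   (summing to one).
#' @export
uniform_likelihood <- function(ks, weights = NULL) {
  w <- weights %||% rep(1, ks$n_states)
  if (any(w < 0)) stop("weights must be non-negative")
  s <- sum(w)
  if (s <= 0) stop("weights sum to zero")
  structure(list(structure = ks, weights = w / s), class = "likelihood")
}

#' @export
print.likelihood <- function(x, ...) {
  cat("<likelihood> over ", x$structure$n_states, " states; max ",
      format(max(x$weights), digits = 4), "\n", sep = "")
  invisible(x)
}

renormalize <- function(L, w) {
  s <- sum(w)
  if (s <= 0) stop("zero normalizing constant: all posterior mass vanished")
  L$weights <- w / s
  L
}

#' Total likelihood mass on states containing a problem
#'
#' @param L A [uniform_likelihood()] object.
#' @param q A domain problem.
#' @return A probability.
#' @export
mass_containing <- function(L, q) {
  i <- match(q, L$structure$domain)
  if (is.na(i)) stop("problem ", q, " not in the structure's domain")
  sum(L$weights[L$structure$membership[, i]])
}

#' Half-split question selection
#'
#' Selects, among the problems still available, one that minimizes
#' `|2 L(K_q) - 1|` where `L(K_q)` is the likelihood mass on states
#' containing `q`: the problem whose mastery is most uncertain. Ties (within
#' an absolute tolerance of 1e-12) are broken uniformly at random.
#'
#' @param L A [uniform_likelihood()] object.
#' @param available Character vector of candidate problems.
#' @param seed Optional seed for tie breaking.
#' @return A single problem identifier.
#' @export
half_split_select <- function(L, available, seed = NULL) {
  if (!length(available)) stop("no problems available for selection")
  scores <- vapply(available, function(q) abs(2 * mass_containing(L, q) - 1), 0)
  ties <- which(scores <= min(scores) + TIE_TOL)
  if (length(ties) == 1L) return(available[ties])
  with_seed_if(seed, available[ties[sample.int(length(ties), 1L)]])
}

#' Bayesian updating rule of the continuous Markov procedure
#'
#' Multiplies the likelihood of each state by the conditional response
#' probability (careless error `beta_q`, lucky guess `eta_q`) and
#' renormalizes: states containing `q` get `1 - beta_q` (correct) or
#' `beta_q` (incorrect); states not containing `q` get `eta_q` or
#' `1 - eta_q`.
#'
#' @param L A [uniform_likelihood()] object.
#' @param q The administered problem.
#' @param r Observed response, `0` or `1`.
#' @param beta_q,eta_q Careless-error and lucky-guess probabilities of `q`.
#' @return The updated `likelihood`.
#' @export
cmp_update <- function(L, q, r, beta_q, eta_q) {
  i <- match(q, L$structure$domain)
  if (is.na(i)) stop("problem ", q, " not in the structure's domain")
  if (!r %in% c(0, 1)) stop("response must be 0 or 1")
  inq <- L$structure$membership[, i]
  p <- if (r == 1) ifelse(inq, 1 - beta_q, eta_q) else ifelse(inq, beta_q, 1 - eta_q)
  renormalize(L, p * L$weights)
}

#' Multiplicative updating rule
#'
#' The multiplicative counterpart of [cmp_update()]: a correct response
#' multiplies the likelihood of states containing `q` by `zeta1`; an
#' incorrect response multiplies the likelihood of states not containing `q`
#' by `zeta0`; all other states keep weight 1 before renormalization. With
#' `zeta1 = (1 - beta_q) / eta_q` and `zeta0 = (1 - eta_q) / beta_q` it is
#' equivalent to the Bayesian rule.
#'
#' @inheritParams cmp_update
#' @param zeta1,zeta0 Update multipliers, both greater than 1.
#' @return The updated `likelihood`.
#' @export
multiplicative_update <- function(L, q, r, zeta1, zeta0) {
  i <- match(q, L$structure$domain)
  if (is.na(i)) stop("problem ", q, " not in the structure's domain")
  inq <- L$structure$membership[, i]
  z <- if (r == 1) ifelse(inq, zeta1, 1) else ifelse(inq, 1, zeta0)
  renormalize(L, z * L$weights)
}

#' Move-by-move updating rule of the MSP procedures
#'
#' Applies one Bayesian update per observed elementary transition
#' `i -> j` of a solution process: the likelihood of each state `K` is
#' multiplied by the transition probability under the planning assumption
#' (`beta[i, j]` or `eta[i, j]`, with failure residuals for `j = f`) and
#' renormalized.
#'
#' @param L A [uniform_likelihood()] object.
#' @param s0 Initial state of the administered problem.
#' @param i,j The observed transition (`j` may be the failure state).
#' @param params A [transition_params()] table.
#' @param assumption Planning assumption, `"msp1"`, `"msp2"` or `"msp3"`.
#' @param gs The [goal_space()].
#' @return The updated `likelihood`.
#' @export
msp_update <- function(L, s0, i, j, params, assumption, gs) {
  assumption <- match.arg(assumption, c("msp1", "msp2", "msp3"))
  rates <- lookup_rates(params, i, j, gs$failure)
  ks <- L$structure
  dom <- ks$domain
  s0_col <- match(s0, dom)
  i_col <- match(i, dom)
  in_s0 <- if (is.na(s0_col)) rep(FALSE, ks$n_states) else ks$membership[, s0_col]
  in_i <- if (is.na(i_col)) rep(FALSE, ks$n_states) else ks$membership[, i_col]
  use_beta <- switch(assumption, msp1 = in_s0, msp2 = in_i, msp3 = in_s0 & in_i)
  p <- ifelse(use_beta, rates["beta"], rates["eta"])
  renormalize(L, p * L$weights)
}

#' Multiplicative form of the move-by-move update
#'
#' Equivalent to [msp_update()] whenever `beta[i, j] > eta[i, j]` for
#' non-failure `j` and `eta[i, f] > beta[i, f]`: states in the beta case are
#' multiplied by `beta[i, j] / eta[i, j]` (or `eta[i, f] / beta[i, f]` when
#' the observed transition enters failure), all others by 1.
#'
#' @inheritParams msp_update
#' @return The updated `likelihood`.
#' @export
msp_multiplicative_update <- function(L, s0, i, j, params, assumption, gs) {
  assumption <- match.arg(assumption, c("msp1", "msp2", "msp3"))
  rates <- lookup_rates(params, i, j, gs$failure)
  zeta <- unname(if (identical(j, gs$failure)) rates["eta"] / rates["beta"]
                 else rates["beta"] / rates["eta"])
  ks <- L$structure
  s0_col <- match(s0, ks$domain)
  i_col <- match(i, ks$domain)
  in_s0 <- if (is.na(s0_col)) rep(FALSE, ks$n_states) else ks$membership[, s0_col]
  in_i <- if (is.na(i_col)) rep(FALSE, ks$n_states) else ks$membership[, i_col]
  use_beta <- switch(assumption, msp1 = in_s0, msp2 = in_i, msp3 = in_s0 & in_i)
  # on a failure transition the eta-case states receive the >1 multiplier
  z <- if (identical(j, gs$failure)) ifelse(use_beta, 1, zeta) else ifelse(use_beta, zeta, 1)
  renormalize(L, z * L$weights)
}

#' Shannon entropy of a likelihood distribution
#'
#' @param L A [uniform_likelihood()] object.
#' @return Entropy in bits (`0 log 0` taken as 0).
#' @export
likelihood_entropy <- function(L) {
  w <- L$weights[L$weights > 0]
  -sum(w * log2(w))
}

# modal states within tie tolerance of the maximum
modal_states <- function(L) which(L$weights >= max(L$weights) - TIE_TOL)
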