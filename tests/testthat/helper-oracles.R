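# shared fixtures and independent brute-force oracles

# memoized Tower of London objects (built once per test run)
tol_env <- new.env()
tol_fixture <- function() {
  if (is.null(tol_env$space)) {
    tol_env$space <- tol_space()
    tol_env$goal <- tol_goal_state(tol_env$space)
    tol_env$gs <- goal_space(tol_env$space, tol_env$goal, drop_one_move = TRUE)
    tol_env$sm <- solution_paths(tol_env$gs)
  }
  tol_env
}

path_labels <- function(sm, ids) {
  paste0(sm$paths$start[match(ids, sm$paths$path_id)],
         sm$paths$ops[match(ids, sm$paths$path_id)])
}

# brute-force oracle: knowledge space as the image of all down-closed path
# subsets under direct application of the problem function (no atoms, no
# union closure). Only feasible for small path sets.
brute_knowledge_space <- function(sm, anchored = FALSE) {
  ps <- sm$paths
  n <- nrow(ps)
  stopifnot(n <= 15)
  plist <- lapply(seq_len(n), function(i) list(start = ps$start[i], ops = ps$ops[i]))
  rel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    rel[i, j] <- is_subpath(plist[[i]], plist[[j]], sm$gs$space, anchored = anchored)
  }
  fam <- list()
  for (mask in 0:(2^n - 1)) {
    inset <- bitwAnd(bitwShiftL(1L, 0:(n - 1)), mask) != 0
    down <- TRUE
    for (j in which(inset)) if (!all(inset[rel[, j]])) { down <- FALSE; break }
    if (!down) next
    fam[[length(fam) + 1L]] <- sort(unique(ps$problem[inset]))
  }
  unique(fam)
}

# brute-force down-set enumeration (competence space) over 2^n subsets
brute_competence_space <- function(sm, anchored = FALSE) {
  ps <- sm$paths
  n <- nrow(ps)
  stopifnot(n <= 15)
  plist <- lapply(seq_len(n), function(i) list(start = ps$start[i], ops = ps$ops[i]))
  rel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    rel[i, j] <- is_subpath(plist[[i]], plist[[j]], sm$gs$space, anchored = anchored)
  }
  fam <- list()
  for (mask in 0:(2^n - 1)) {
    inset <- bitwAnd(bitwShiftL(1L, 0:(n - 1)), mask) != 0
    down <- TRUE
    for (j in which(inset)) if (!all(inset[rel[, j]])) { down <- FALSE; break }
    if (down) fam[[length(fam) + 1L]] <- which(inset)
  }
  fam
}

# a line problem space s1 -> s2 -> ... -> goal (chain of nested paths)
line_goal_space <- function(n) {
  states <- c(paste0("u", seq_len(n)), "gg")
  edges <- data.frame(from = states[seq_len(n)], op = "a", to = states[-1])
  goal_space(problem_space(edges), "gg")
}

# a star problem space: k states, each one distinct move from the goal
# (an antichain of pairwise-incomparable one-move paths)
star_goal_space <- function(k) {
  edges <- data.frame(from = paste0("v", seq_len(k)),
                      op = letters[seq_len(k)], to = "gg")
  goal_space(problem_space(edges), "gg")
}

# random layered shortest-path goal space: every edge decreases the distance
# by one, so the SP construction keeps all edges
random_layered_goal_space <- function(seed, layers = 3, width = 3) {
  withr::with_seed(seed, {
    lay <- c(list("gg"), lapply(seq_len(layers), function(k) {
      paste0("n", k, "_", seq_len(sample(2:width, 1)))
    }))
    edges <- list()
    for (k in seq_len(layers) + 1) {
      for (s in lay[[k]]) {
        nto <- sample(seq_len(min(3, length(lay[[k - 1]]))), 1)
        tos <- sample(lay[[k - 1]], nto)
        edges[[length(edges) + 1L]] <- data.frame(
          from = s, op = letters[seq_along(tos)], to = tos)
      }
    }
    goal_space(problem_space(do.call(rbind, edges)), "gg")
  })
}

# transition tables satisfying the multiplicativity condition
# (beta_ij > eta_ij for on-path j, eta_if > beta_if) by construction
random_theorem_params <- function(gs, seed) {
  withr::with_seed(seed, {
    rows <- list()
    for (i in names(gs$dist)[gs$dist >= 1]) {
      succs <- gs$edges$to[gs$edges$from == i]
      b_f <- stats::runif(1, 0, 0.1)
      e_f <- stats::runif(1, b_f + 0.05, 0.95)
      ew <- stats::runif(length(succs))
      eta <- ew / sum(ew) * (1 - e_f)
      vw <- stats::runif(length(succs), 0.1, 1)
      beta <- eta + vw / sum(vw) * (e_f - b_f)
      rows[[length(rows) + 1L]] <- data.frame(i = i, j = succs, beta = beta, eta = eta)
    }
    transition_params(do.call(rbind, rows), gs)
  })
}

# near-deterministic rates: knowing -> on-path move almost surely,
# not knowing -> immediate failure almost surely
noiseless_params <- function(gs, eps = 1e-6) {
  rows <- list()
  for (i in names(gs$dist)[gs$dist >= 1]) {
    succs <- gs$edges$to[gs$edges$from == i]
    k <- length(succs)
    rows[[length(rows) + 1L]] <- data.frame(
      i = i, j = succs, beta = (1 - eps) / k, eta = eps / k)
  }
  transition_params(do.call(rbind, rows), gs)
}
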