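#' Build a shortest-path goal space
#'
#' A goal space is a problem space with two distinguished absorbing states, a
#' goal `g` and a failure state `f`: both absorb every operation, and every
#' other state can reach `g`. All problems have the form `(s, g)`. In a
#' shortest-path (SP) goal space a problem counts as solved only when the goal
#' is reached in the minimum number of moves, so any move that leaves every
#' minimum-length path to the goal enters the failure state instead. The
#' constructed space therefore keeps exactly the transitions that decrease
#' the distance to the goal; all other legal moves of the original space are
#' redirected to `f` (failure entry is "any off-path move" and carries no
#' operation label of its own).
#'
#' @param space A [problem_space()].
#' @param goal State identifier of the goal.
#' @param drop_one_move If `TRUE`, problems solvable in a single move are
#'   removed from the domain (their initial states remain in the space as
#'   intermediate states).
#' @param failure Identifier to use for the added failure state.
#'
#' @return An object of class `goal_space`: a list with the underlying
#'   `space`, `goal`, `failure`, the on-path edge table `edges`, the distance
#'   to goal `dist` (named vector), the problem `domain` tibble
#'   (`initial`, `goal`, `min_moves`) and the per-state legal move counts of
#'   the original space.
#' @examples
#' gs <- goal_space(fig2_space(), "s9")
#' gs$domain
#' @export
goal_space <- function(space, goal, drop_one_move = FALSE, failure = "(f)") {
  stopifnot(inherits(space, "problem_space"))
  if (!goal %in% space$states) stop("goal state ", goal, " not in space")
  if (failure %in% space$states) stop("failure identifier ", failure, " clashes with a state")
  d <- igraph::distances(space_graph(space), to = goal, mode = "out")[, 1]
  if (any(is.infinite(d))) {
    bad <- names(d)[is.infinite(d)][1]
    stop("goal space condition violated: state ", bad, " cannot reach the goal ", goal)
  }
  edges <- space$edges
  on_path <- d[edges$to] == d[edges$from] - 1
  kept <- edges[on_path, ]
  dom <- tibble::tibble(initial = names(d)[d >= 1], goal = goal,
                        min_moves = as.integer(d[d >= 1]))
  if (drop_one_move) dom <- dom[dom$min_moves > 1L, ]
  dom <- dplyr::arrange(dom, .data$initial)
  structure(
    list(space = space, goal = goal, failure = failure,
         edges = kept, dist = d, domain = dom,
         legal = legal_moves(space), drop_one_move = drop_one_move),
    class = "goal_space"
  )
}

#' @export
print.goal_space <- function(x, ...) {
  cat("<goal_space> goal ", x$goal, ", ", nrow(x$domain), " problems, ",
      nrow(x$edges), " on-path moves (+ failure)\n", sep = "")
  invisible(x)
}

#' Elementary transition pairs of a goal space
#'
#' The elementary pairs are the on-path single-move transitions `(i, j)` of
#' the shortest-path space plus, for every non-absorbing state `i`, the pair
#' `(i, f)` collecting all off-path moves.
#'
#' @param gs A [goal_space()].
#' @return A tibble with columns `i` and `j`.
#' @export
elementary_pairs <- function(gs) {
  keep <- gs$dist[gs$edges$from] >= 1
  on <- tibble::tibble(i = gs$edges$from[keep], j = gs$edges$to[keep])
  fail <- tibble::tibble(i = names(gs$dist)[gs$dist >= 1], j = gs$failure)
  dplyr::arrange(dplyr::bind_rows(on, fail), .data$i, .data$j)
}

# on-path successors of state i (NULL when absorbing)
sp_successors <- function(gs, i) {
  gs$edges[gs$edges$from == i, c("op", "to")]
}
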