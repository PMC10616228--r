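#' Construct a problem space
#'
#' A problem space is a finite set of problem states together with a set of
#' labeled operations acting on them: applying operation `op` in state `from`
#' deterministically yields state `to`. Operation strings act by left-to-right
#' composition and the empty string is the identity, so the edge table fully
#' determines the (partial) action of all operation sequences.
#'
#' @param edges A data frame with columns `from`, `op`, `to`: one row per
#'   legal elementary transition.
#' @param states Optional character vector of state identifiers; defaults to
#'   all states appearing in `edges`. States never touched by an operation can
#'   be added here.
#' @param operations Optional character vector of operation labels; defaults
#'   to the labels appearing in `edges`.
#'
#' @return An object of class `problem_space` with elements `states`,
#'   `operations` and `edges` (a tibble).
#' @examples
#' sp <- problem_space(data.frame(from = "u", op = "a", to = "v"))
#' apply_ops(sp, "u", "a")
#' @export
problem_space <- function(edges, states = NULL, operations = NULL) {
  edges <- tibble::as_tibble(edges[c("from", "op", "to")])
  edges$from <- as.character(edges$from)
  edges$op <- as.character(edges$op)
  edges$to <- as.character(edges$to)
  key <- paste(edges$from, edges$op, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- edges[duplicated(key), ]
    stop("operation application must be deterministic; duplicated (state, operation) pair: (",
         dup$from[1], ", ", dup$op[1], ")")
  }
  states <- sort(unique(c(states, edges$from, edges$to)))
  operations <- unique(c(operations, edges$op))
  structure(
    list(states = states, operations = operations, edges = edges,
         succ = stats::setNames(edges$to, key)),
    class = "problem_space"
  )
}

#' @export
print.problem_space <- function(x, ...) {
  cat("<problem_space> ", length(x$states), " states, ",
      length(x$operations), " operations, ", nrow(x$edges), " transitions\n", sep = "")
  invisible(x)
}

#' Apply an operation sequence to a state
#'
#' @param space A [problem_space()].
#' @param state A state identifier.
#' @param ops An operation sequence: character vector of labels, or a compact
#'   string such as `"abABA"` when all labels are single characters. The empty
#'   sequence returns `state` unchanged.
#'
#' @return The resulting state, or `NA_character_` when the sequence is not
#'   applicable from `state`.
#' @export
apply_ops <- function(space, state, ops) {
  ops <- as_ops(ops)
  for (op in ops) {
    state <- space$succ[paste(state, op, sep = "\r")]
    if (is.na(state)) return(NA_character_)
    state <- unname(state)
  }
  unname(state)
}

# igraph view of the transition graph (states as vertices)
space_graph <- function(space) {
  igraph::graph_from_data_frame(
    space$edges[c("from", "to")], directed = TRUE,
    vertices = data.frame(name = space$states)
  )
}

#' Enumerate all problems of a problem space
#'
#' A problem is an ordered pair of distinct states `(initial, goal)` such that
#' some operation sequence transforms the initial state into the goal state.
#'
#' @param space A [problem_space()].
#' @return A tibble with columns `initial`, `goal` and `min_moves` (length of
#'   a shortest transforming sequence), one row per problem.
#' @export
problems <- function(space) {
  d <- igraph::distances(space_graph(space), mode = "out")
  idx <- which(is.finite(d) & d > 0, arr.ind = TRUE)
  out <- tibble::tibble(
    initial = rownames(d)[idx[, 1]],
    goal = colnames(d)[idx[, 2]],
    min_moves = as.integer(d[idx])
  )
  dplyr::arrange(out, .data$initial, .data$goal)
}

#' Count legal moves per state
#'
#' @param space A [problem_space()].
#' @return A named integer vector: number of applicable operations per state.
#' @export
legal_moves <- function(space) {
  n <- table(factor(space$edges$from, levels = space$states))
  stats::setNames(as.integer(n), space$states)
}
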