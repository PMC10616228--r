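#' Enumerate solution paths and build the skill map
#'
#' A solution path is a start state plus a non-empty operation sequence; it
#' solves a problem when applying the sequence to the start state yields the
#' goal. In a shortest-path goal space the solving paths of a problem are
#' exactly its minimum-length paths to the goal, enumerated here by walking
#' distance-decreasing transitions. Grouping the paths by the problem they
#' solve yields the skill map tau: problems are identified by their initial
#' state since all goals coincide.
#'
#' @param gs A [goal_space()].
#' @param domain Optional character vector restricting the problems (initial
#'   states) considered; defaults to the full goal-space domain.
#' @return An object of class `skill_map`: list with `domain` (character),
#'   `goal`, `paths` (tibble `path_id`, `problem`, `start`, `ops`) and the
#'   originating goal space `gs`. `ops` is the compact operation string.
#' @examples
#' sm <- solution_paths(fig2_goal_space(), domain = c("s1", "s3", "s4", "s7", "s8"))
#' sm$paths
#' @export
solution_paths <- function(gs, domain = NULL) {
  stopifnot(inherits(gs, "goal_space"))
  dom <- domain %||% gs$domain$initial
  missing <- setdiff(dom, gs$domain$initial)
  if (length(missing)) stop("not in the goal-space domain: ", paste(missing, collapse = ", "))
  dom <- sort(dom)
  rows <- list()
  walk <- function(state, acc) {
    if (state == gs$goal) return(list(acc))
    nxt <- sp_successors(gs, state)
    out <- list()
    for (k in seq_len(nrow(nxt))) {
      out <- c(out, walk(nxt$to[k], c(acc, nxt$op[k])))
    }
    out
  }
  for (s in dom) {
    for (p in walk(s, character(0))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(problem = s, start = s,
                                                  ops = ops_string(p))
    }
  }
  paths <- dplyr::bind_rows(rows)
  paths$path_id <- seq_len(nrow(paths))
  structure(
    list(domain = dom, goal = gs$goal,
         paths = paths[c("path_id", "problem", "start", "ops")], gs = gs),
    class = "skill_map"
  )
}

#' @export
print.skill_map <- function(x, ...) {
  cat("<skill_map> ", length(x$domain), " problems, ", nrow(x$paths),
      " solution paths (goal ", x$goal, ")\n", sep = "")
  invisible(x)
}

#' The subpath relation between two solution paths
#'
#' Path `p` is a subpath of path `q` when the operation sequence of `q`
#' factorizes as alpha-pi-beta with pi the sequence of `p` and, under the
#' anchored reading, applying alpha to the start of `q` lands on the start of
#' `p`. With `anchored = FALSE` only the sequence condition is checked, i.e.
#' the operations of `p` must occur contiguously inside those of `q`: this
#' treats a skill as a movement pattern independent of where it is executed.
#' The relation is reflexive and transitive under either reading. Knowing a
#' path implies knowing all of its subpaths.
#'
#' @param p,q Solution paths: lists with elements `start` and `ops` (compact
#'   string or character vector).
#' @param space The [problem_space()] in which the paths live (used for the
#'   anchoring state check).
#' @param anchored Require the factorization to land on `p`'s start state
#'   (the literal definition). Default `TRUE`.
#' @return `TRUE` or `FALSE`.
#' @examples
#' f2 <- fig2_space()
#' is_subpath(list(start = "s4", ops = "ABA"),
#'            list(start = "s1", ops = "abABA"), f2)
#' @export
is_subpath <- function(p, q, space, anchored = TRUE) {
  po <- as_ops(p$ops)
  qo <- as_ops(q$ops)
  np <- length(po)
  nq <- length(qo)
  if (np > nq) return(FALSE)
  for (k in 0:(nq - np)) {
    if (!identical(qo[(k + 1):(k + np)], po)) next
    if (!anchored) return(TRUE)
    pre <- if (k > 0) qo[seq_len(k)] else character(0)
    at <- apply_ops(space, q$start, pre)
    if (identical(at, p$start)) return(TRUE)
  }
  FALSE
}

# n x n logical matrix: rel[i, j] is TRUE iff path i is a subpath of path j
subpath_relation <- function(sm, subpath = c("sequence", "anchored")) {
  subpath <- match.arg(subpath)
  ps <- sm$paths
  n <- nrow(ps)
  plist <- lapply(seq_len(n), function(i) list(start = ps$start[i], ops = ps$ops[i]))
  rel <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      rel[i, j] <- is_subpath(plist[[i]], plist[[j]], sm$gs$space,
                              anchored = (subpath == "anchored"))
    }
  }
  rel
}
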