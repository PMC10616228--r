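#' The Tower of London problem space
#'
#' Builds the move graph of the Tower of London (ToL) test: three pegs of
#' capacities 3, 2 and 1 (left, center, right) holding three colored balls.
#' A state is a spatial arrangement of the balls on the pegs combined with a
#' color permutation; there are 6 occupancy arrangements times 6 color
#' permutations = 36 states. The six operations move the top ball between
#' pegs: `a` left to center, `b` center to right, `c` left to right, and the
#' inverse moves written here `A`, `B`, `C` (center to left, right to center,
#' right to left). A move is legal iff the source peg is non-empty and the
#' target peg is below capacity.
#'
#' State identifiers spell out the peg contents bottom-to-top with ball colors
#' `1`, `2`, `3`, pegs separated by `|`: `"12|3|"` holds balls 1,2 on the left
#' peg and ball 3 on the center peg. The attached state table additionally
#' records the occupancy arrangement index (1-6, in the fixed order
#' (3,0,0), (2,1,0), (2,0,1), (1,2,0), (1,1,1), (0,2,1)) and the color
#' permutation index (1-6, lexicographic). Published state codings for the
#' ToL use an arrangement-by-permutation pair as well; supply a lookup table
#' keyed by these two indices to translate to any external labeling.
#'
#' @return A [problem_space()] with 36 states and 108 directed legal moves,
#'   carrying a `state_info` attribute: a tibble with columns `id`,
#'   `arrangement`, `occupancy` and `permutation`.
#' @examples
#' tol <- tol_space()
#' length(tol$states)
#' @export
tol_space <- function() {
  arrangements <- list(c(3, 0, 0), c(2, 1, 0), c(2, 0, 1),
                       c(1, 2, 0), c(1, 1, 1), c(0, 2, 1))
  caps <- c(3L, 2L, 1L)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  moves <- list(a = c(1L, 2L), b = c(2L, 3L), c = c(1L, 3L),
                A = c(2L, 1L), B = c(3L, 2L), C = c(3L, 1L))

  id_of <- function(pegs) paste(vapply(pegs, paste, "", collapse = ""), collapse = "|")
  info <- vector("list", 36L)
  k <- 0L
  state_pegs <- list()
  for (ai in seq_along(arrangements)) {
    for (pi in seq_along(perms)) {
      occ <- arrangements[[ai]]
      cols <- perms[[pi]]
      pegs <- list(integer(0), integer(0), integer(0))
      at <- 1L
      for (peg in 1:3) {
        if (occ[peg] > 0) {
          pegs[[peg]] <- cols[at:(at + occ[peg] - 1L)]
          at <- at + occ[peg]
        }
      }
      k <- k + 1L
      info[[k]] <- tibble::tibble(
        id = id_of(pegs), arrangement = ai,
        occupancy = paste(occ, collapse = ","), permutation = pi
      )
      state_pegs[[id_of(pegs)]] <- pegs
    }
  }
  info <- dplyr::bind_rows(info)

  edges <- list()
  for (id in info$id) {
    pegs <- state_pegs[[id]]
    for (op in names(moves)) {
      fromto <- moves[[op]]
      src <- pegs[[fromto[1]]]
      dst <- pegs[[fromto[2]]]
      if (length(src) == 0L || length(dst) >= caps[fromto[2]]) next
      np <- pegs
      np[[fromto[1]]] <- src[-length(src)]
      np[[fromto[2]]] <- c(dst, src[length(src)])
      edges[[length(edges) + 1L]] <- tibble::tibble(from = id, op = op, to = id_of(np))
    }
  }
  sp <- problem_space(dplyr::bind_rows(edges), states = info$id,
                      operations = names(moves))
  attr(sp, "state_info") <- info
  sp
}

#' Candidate ToL goal states with four one-move neighbours
#'
#' Removing all one-move problems from the full goal space leaves 31 of 35
#' problems exactly when the goal state admits four legal moves. Two occupancy
#' types qualify: (2,1,0) and (1,1,1). The two are distinguished by derived
#' structure counts: with the (2,1,0)-type goal exactly 11 of the 31 problems
#' have more than one minimum-length solution, versus 13 for the
#' (1,1,1)-type. [tol_goal_state()] returns the designated default, the
#' (2,1,0)-type state at color permutation 1.
#'
#' @param space A ToL space from [tol_space()].
#' @return `tol_goal_candidates()`: a tibble of the eligible states;
#'   `tol_goal_state()`: a single state id.
#' @export
tol_goal_candidates <- function(space = tol_space()) {
  info <- attr(space, "state_info")
  lm <- legal_moves(space)
  dplyr::filter(info, lm[.data$id] == 4L)
}

#' @rdname tol_goal_candidates
#' @param occupancy Peg occupancy of the goal, `"2,1,0"` (default) or `"1,1,1"`.
#' @param permutation Color permutation index, 1-6.
#' @export
tol_goal_state <- function(space = tol_space(), occupancy = "2,1,0", permutation = 1L) {
  info <- attr(space, "state_info")
  hit <- info$id[info$occupancy == occupancy & info$permutation == permutation]
  if (length(hit) != 1L) stop("no ToL state with occupancy ", occupancy,
                              " and permutation ", permutation)
  hit
}
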