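#' Knowledge structures over a problem domain
#'
#' A knowledge state is the subset of domain problems an individual can
#' solve; a knowledge structure is a family of such states containing the
#' empty set and the full domain. A structure closed under arbitrary union is
#' a knowledge space. States are stored as bitmasks over the lexicographically
#' ordered domain; a logical membership matrix (rows = states, columns =
#' problems) is kept alongside for fast likelihood computations.
#'
#' @param domain Character vector of problem identifiers (sorted internally).
#' @param states Either a list of character vectors (each a subset of
#'   `domain`) or a logical membership matrix with one column per domain
#'   problem in sorted order.
#' @return An object of class `knowledge_structure` with elements `domain`,
#'   `masks`, `membership` and `n_states`.
#' @examples
#' ks <- knowledge_structure(c("p", "q"), list(character(0), "q", c("p", "q")))
#' ks$n_states
#' @export
knowledge_structure <- function(domain, states) {
  domain <- sort(as.character(domain))
  n <- length(domain)
  if (is.matrix(states)) {
    stopifnot(is.logical(states), ncol(states) == n)
    memb <- states
  } else {
    memb <- matrix(FALSE, length(states), n)
    for (k in seq_along(states)) {
      idx <- match(states[[k]], domain)
      if (anyNA(idx)) stop("state ", k, " contains problems outside the domain")
      memb[k, idx] <- TRUE
    }
  }
  masks <- mask_dedupe(mask_from_membership(memb))
  new_knowledge_structure(domain, masks)
}

new_knowledge_structure <- function(domain, masks) {
  structure(
    list(domain = domain, masks = masks,
         membership = mask_membership(masks, length(domain)),
         n_states = nrow(masks)),
    class = "knowledge_structure"
  )
}

#' @export
print.knowledge_structure <- function(x, ...) {
  cat("<knowledge_structure> ", x$n_states, " states over ",
      length(x$domain), " problems\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a knowledge structure into a long membership table
#'
#' @param x A [knowledge_structure()].
#' @param ... Unused.
#' @return A tibble with columns `state` (index), `problem`, `member`.
#' @method tidy knowledge_structure
#' @export
tidy.knowledge_structure <- function(x, ...) {
  tibble::tibble(
    state = rep(seq_len(x$n_states), each = length(x$domain)),
    problem = rep(x$domain, times = x$n_states),
    member = as.vector(t(x$membership))
  )
}

#' List the problem sets of a knowledge structure
#'
#' @param ks A [knowledge_structure()].
#' @return A list of character vectors, one per state.
#' @export
state_sets <- function(ks) {
  apply(ks$membership, 1L, function(r) ks$domain[r], simplify = FALSE)
}

#' Derive the competence space of a skill map
#'
#' Competence states are the subsets of solution paths that respect path
#' inclusion (downward closed under the subpath relation); their collection
#' is the competence space. Enumeration is explicit (breadth-first closure
#' adding one admissible path at a time), guarded because the competence
#' space can be exponentially larger than the knowledge space it delineates.
#'
#' @param sm A [solution_paths()] skill map.
#' @param subpath Subpath reading used for the partial order: `"sequence"`
#'   (contiguous operation substring, the default) or `"anchored"` (also
#'   requires the embedding to start at the subpath's start state).
#' @param max_states Guard on the number of competence states; exceeding it
#'   aborts with advice to derive the knowledge space directly.
#' @return A list of integer vectors of path ids (each downward closed),
#'   ordered by size; class `competence_space` with the skill map attached.
#' @export
competence_space <- function(sm, subpath = c("sequence", "anchored"),
                             max_states = 2^20) {
  subpath <- match.arg(subpath)
  rel <- subpath_relation(sm, subpath)
  n <- nrow(rel)
  if (n > 30L) stop("too many paths for explicit competence-space enumeration; ",
                    "derive the knowledge space instead (knowledge_space())")
  preds <- lapply(seq_len(n), function(j) which(rel[, j] & seq_len(n) != j))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  assign("0", TRUE, envir = seen)
  frontier <- 0L
  all_masks <- 0L
  while (length(frontier)) {
    nxt <- integer(0)
    for (m in frontier) {
      inset <- bitwAnd(bitwShiftL(1L, 0:(n - 1L)), m) != 0L
      for (x in which(!inset)) {
        if (all(inset[preds[[x]]])) {
          m2 <- bitwOr(m, bitwShiftL(1L, x - 1L))
          key <- as.character(m2)
          if (!exists(key, envir = seen, inherits = FALSE)) {
            assign(key, TRUE, envir = seen)
            nxt <- c(nxt, m2)
          }
        }
      }
    }
    all_masks <- c(all_masks, nxt)
    if (length(all_masks) > max_states) {
      stop("competence space exceeds max_states = ", max_states,
           "; derive the knowledge space instead (knowledge_space())")
    }
    frontier <- nxt
  }
  states <- lapply(sort(all_masks), function(m) which(bitwAnd(bitwShiftL(1L, 0:(n - 1L)), m) != 0L))
  states <- states[order(lengths(states))]
  structure(states, class = "competence_space", skill_map = sm, subpath = subpath)
}

#' @export
print.competence_space <- function(x, ...) {
  cat("<competence_space> ", length(x), " competence states over ",
      nrow(attr(x, "skill_map")$paths), " paths\n", sep = "")
  invisible(x)
}

#' The problem function
#'
#' Maps a competence state (set of solution paths) to the knowledge state it
#' delineates: the problems solved by at least one path in the set.
#'
#' @param C Integer vector of path ids (a competence state).
#' @param sm The [solution_paths()] skill map.
#' @return Sorted character vector of problems.
#' @examples
#' sm <- solution_paths(fig2_goal_space(), domain = c("s1", "s3", "s4", "s7", "s8"))
#' problem_function(c(1, 2, 3), sm)
#' @export
problem_function <- function(C, sm) {
  stopifnot(all(C %in% sm$paths$path_id))
  sort(unique(sm$paths$problem[match(C, sm$paths$path_id)]))
}

#' Derive the knowledge space of a skill map
#'
#' The knowledge space is the image of the competence space under the problem
#' function. It is computed without enumerating competence states: the atoms
#' are the images p(down-set of a single path), and since every down-set is a
#' union of principal down-sets and p distributes over union, the space is
#' the union closure of the atoms together with the empty set.
#'
#' @inheritParams competence_space
#' @return A [knowledge_structure()] whose `space` flag is implicit: the
#'   result is union-closed by construction and contains the empty set and
#'   the full domain.
#' @examples
#' sm <- solution_paths(fig2_goal_space(), domain = c("s1", "s3", "s4", "s7", "s8"))
#' knowledge_space(sm)$n_states
#' @export
knowledge_space <- function(sm, subpath = c("sequence", "anchored")) {
  subpath <- match.arg(subpath)
  rel <- subpath_relation(sm, subpath)
  domain <- sm$domain
  n <- length(domain)
  atoms <- matrix(0L, nrow(rel), mask_nchunks(n))
  for (j in seq_len(nrow(rel))) {
    probs <- unique(sm$paths$problem[rel[, j]])
    atoms[j, ] <- mask_from_indices(match(probs, domain), n)
  }
  atoms <- mask_dedupe(atoms)
  fam <- close_under_union(atoms)
  new_knowledge_structure(domain, fam)
}

#' States of a structure containing a given problem
#'
#' @param ks A [knowledge_structure()].
#' @param q A domain problem.
#' @return Integer vector of state indices.
#' @export
states_containing <- function(ks, q) {
  i <- match(q, ks$domain)
  if (is.na(i)) stop("problem ", q, " not in the structure's domain")
  which(ks$membership[, i])
}

#' Check closure under union
#'
#' Verifies pairwise union closure, either exhaustively (small structures) or
#' on a random sample of pairs.
#'
#' @param ks A [knowledge_structure()].
#' @param sample_pairs If not `NULL`, the number of random pairs checked
#'   instead of all pairs.
#' @param seed Optional seed for the sampled check.
#' @return `TRUE` or `FALSE`.
#' @export
is_union_closed <- function(ks, sample_pairs = NULL, seed = NULL) {
  keyset <- new.env(hash = TRUE, parent = emptyenv())
  keys <- do.call(paste, as.data.frame(ks$masks))
  for (k in keys) assign(k, TRUE, envir = keyset)
  pair_ok <- function(i, j) {
    u <- bitwOr(ks$masks[i, ], ks$masks[j, ])
    exists(paste(u, collapse = " "), envir = keyset, inherits = FALSE)
  }
  if (is.null(sample_pairs)) {
    for (i in seq_len(ks$n_states)) for (j in seq_len(ks$n_states)) {
      if (!pair_ok(i, j)) return(FALSE)
    }
  } else {
    with_seed_if(seed, {
      for (k in seq_len(sample_pairs)) {
        ij <- sample.int(ks$n_states, 2L, replace = TRUE)
        if (!pair_ok(ij[1], ij[2])) return(FALSE)
      }
    })
  }
  TRUE
}
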