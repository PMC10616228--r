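#' Built-in fixtures: the nine-state running example and its companions
#'
#' `fig2_space()` is the nine-state portion of the Tower of London problem
#' space used as a running example throughout the package documentation:
#' states `s1`-`s9` linked by the moves `a` (left to center), `b` (center to
#' right) and their inverses `A`, `B`, with `s9` the natural goal.
#' `fig2_goal_space()` wraps it as a shortest-path goal space with goal `s9`.
#' `table4_params()` is the transition-parameter table used by the worked
#' MSP example. `ktol_structure()` is the 11-state knowledge structure
#' delineated by the five problems `{s1, s3, s4, s7, s8}`.
#' `example1_item_params()` carries the per-problem careless/lucky rates of
#' the worked continuous-Markov example. `load_fixture()` fetches any of
#' them by name.
#'
#' @return See individual descriptions.
#' @examples
#' fig2_space()
#' load_fixture("ktol_structure")
#' @export
fig2_space <- function() {
  problem_space(data.frame(
    from = c("s1", "s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8"),
    op   = c("a",  "b",  "b",  "a",  "A",  "B",  "B",  "A",  "A"),
    to   = c("s2", "s3", "s4", "s5", "s6", "s7", "s8", "s8", "s9")
  ))
}

#' @rdname fig2_space
#' @param drop_one_move Passed to [goal_space()].
#' @export
fig2_goal_space <- function(drop_one_move = FALSE) {
  goal_space(fig2_space(), "s9", drop_one_move = drop_one_move)
}

#' @rdname fig2_space
#' @export
fig2_skill_map <- function() {
  solution_paths(fig2_goal_space(), domain = c("s1", "s3", "s4", "s7", "s8"))
}

#' @rdname fig2_space
#' @export
table4_params <- function() {
  transition_params(data.frame(
    i = c("s1", "s1", "s2", "s3", "s4", "s5", "s6", "s7", "s8", "s9"),
    j = c("s2", "s3", "s4", "s5", "s6", "s7", "s8", "s8", "s9", "s9"),
    beta = c(0.36, 0.62, 0.99, 0.99, 0.99, 0.99, 0.99, 0.99, 0.99, 1.00),
    eta  = c(0.01, 0.03, 0.06, 0.08, 0.01, 0.09, 0.09, 0.09, 0.08, 1.00)
  ))
}

#' @rdname fig2_space
#' @export
ktol_structure <- function() {
  knowledge_structure(
    c("s1", "s3", "s4", "s7", "s8"),
    list(character(0), "s8", c("s4", "s8"), c("s7", "s8"), c("s4", "s7", "s8"),
         c("s1", "s4", "s8"), c("s3", "s7", "s8"), c("s1", "s4", "s7", "s8"),
         c("s3", "s4", "s7", "s8"), c("s1", "s3", "s7", "s8"),
         c("s1", "s3", "s4", "s7", "s8"))
  )
}

#' @rdname fig2_space
#' @export
example1_item_params <- function() {
  tibble::tibble(
    problem = c("s1", "s3", "s4", "s7", "s8"),
    beta = c(0.004, 0.03, 0.02, 0.01, 0.007),
    eta = c(1e-6, 5e-5, 4e-5, 0.007, 0.08)
  )
}

#' @rdname fig2_space
#' @param name One of `"fig2_space"`, `"fig2_goal_space"`,
#'   `"fig2_skill_map"`, `"tol_full"`, `"table4_params"`,
#'   `"ktol_structure"`, `"example1_item_params"`.
#' @export
load_fixture <- function(name) {
  fixtures <- list(
    fig2_space = fig2_space,
    fig2_goal_space = fig2_goal_space,
    fig2_skill_map = fig2_skill_map,
    tol_full = tol_space,
    table4_params = table4_params,
    ktol_structure = ktol_structure,
    example1_item_params = example1_item_params
  )
  if (!name %in% names(fixtures)) {
    stop("unknown fixture '", name, "'; available: ",
         paste(names(fixtures), collapse = ", "))
  }
  fixtures[[name]]()
}
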