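#' Run an adaptive assessment
#'
#' Iterates the adaptive loop: select the next problem by the half-split
#' rule among the problems not yet administered, collect the response, update
#' the likelihood (once per response for the `cmp` engine, once per observed
#' move for the `msp*` engines), and stop as soon as some state's likelihood
#' exceeds the termination threshold `p` or every problem has been asked.
#' The final estimate is a modal state of the last likelihood; modal ties
#' are broken uniformly at random.
#'
#' @param ks A [knowledge_structure()].
#' @param responses Response provider. Either a named list mapping each
#'   problem to a response — a binary value for `cmp`, a full visited-state
#'   vector (initial state through terminal state) for `msp*` — or a function
#'   `function(problem)` returning the same.
#' @param engine `"cmp"`, `"msp1"`, `"msp2"` or `"msp3"`.
#' @param gs The [goal_space()] (required for `msp*` engines).
#' @param params A [transition_params()] table (for `msp*`).
#' @param item_params For `cmp`: a data frame with columns `problem`, `beta`,
#'   `eta` giving the per-problem careless-error and lucky-guess rates.
#' @param threshold Termination threshold `p` in `(.5, 1]`.
#' @param prior Optional initial `likelihood`; defaults to uniform.
#' @param seed Optional seed (tie breaking in selection and modal choice).
#' @param allow_repeats Administer with replacement (the general continuous
#'   Markov procedure permits re-asking); default `FALSE`, matching the
#'   without-replacement protocol where the step count never exceeds the
#'   domain size.
#' @param stop_at_threshold Stop administering once the threshold is
#'   exceeded (default). With `FALSE` the loop continues through the whole
#'   domain while still recording at which step the criterion was first met —
#'   used by the study harness to compute per-step metrics.
#' @return An `assessment_record`: list with `administered` (tibble: step
#'   `m`, `problem`, `response`, `max_likelihood`, `entropy`, `terminated`,
#'   and `modal_set`, a list-column holding the tie-broken modal state at
#'   each step), `likelihood` (final), `modal` (integer state indices of
#'   maximal final likelihood), `estimate` (single tie-broken modal index),
#'   `n_questions` (steps administered) and `engine`.
#' @examples
#' ks <- ktol_structure()
#' resp <- list(s1 = 1L, s3 = 1L, s4 = 1L, s7 = 1L, s8 = 1L)
#' ip <- example1_item_params()
#' rec <- run_assessment(ks, resp, engine = "cmp", item_params = ip, seed = 1)
#' glance(rec)
#' @export
run_assessment <- function(ks, responses, engine = c("cmp", "msp1", "msp2", "msp3"),
                           gs = NULL, params = NULL, item_params = NULL,
                           threshold = 0.5, prior = NULL, seed = NULL,
                           allow_repeats = FALSE, stop_at_threshold = TRUE) {
  engine <- match.arg(engine)
  if (!(threshold > 0.5 - 1e-12 && threshold <= 1)) {
    stop("termination threshold must lie in (.5, 1]")
  }
  if (engine == "cmp") {
    if (is.null(item_params)) stop("cmp engine needs item_params (problem, beta, eta)")
  } else {
    if (is.null(gs) || is.null(params)) stop("msp engines need gs and params")
  }
  provider <- if (is.function(responses)) responses else function(q) responses[[q]]
  L <- prior %||% uniform_likelihood(ks)
  available <- ks$domain
  steps <- list()
  m <- 0L
  reached <- FALSE
  keep_going <- TRUE
  while (length(available) && keep_going) {
    m <- m + 1L
    q <- half_split_select(L, available, seed = if (is.null(seed)) NULL else derive_seed(seed, m))
    if (!allow_repeats) available <- setdiff(available, q)
    resp <- provider(q)
    if (is.null(resp)) stop("response provider returned nothing for problem ", q)
    if (engine == "cmp") {
      ip <- item_params[item_params$problem == q, ]
      if (nrow(ip) != 1L) stop("item_params must have exactly one row for problem ", q)
      L <- cmp_update(L, q, resp, ip$beta, ip$eta)
      resp_label <- as.character(resp)
    } else {
      visited <- if (inherits(resp, "solution_process")) resp$visited else resp
      if (visited[1] != q) stop("process for problem ", q, " starts at ", visited[1])
      for (k in seq_len(length(visited) - 1L)) {
        L <- msp_update(L, q, visited[k], visited[k + 1L], params,
                        assumption = engine, gs = gs)
      }
      resp_label <- paste(visited, collapse = ">")
    }
    over <- max(L$weights) > threshold
    reached <- reached || over
    md <- modal_states(L)
    md_pick <- if (length(md) == 1L) md else {
      with_seed_if(if (is.null(seed)) NULL else derive_seed(seed, 10000L + m),
                   md[sample.int(length(md), 1L)])
    }
    steps[[m]] <- tibble::tibble(
      m = m, problem = q, response = resp_label,
      max_likelihood = max(L$weights), entropy = likelihood_entropy(L),
      terminated = over,
      modal_set = list(ks$domain[ks$membership[md_pick, ]])
    )
    if (stop_at_threshold && over) keep_going <- FALSE
  }
  modal <- modal_states(L)
  estimate <- if (length(modal) == 1L) modal else {
    with_seed_if(if (is.null(seed)) NULL else derive_seed(seed, 0L),
                 modal[sample.int(length(modal), 1L)])
  }
  structure(
    list(administered = dplyr::bind_rows(steps), likelihood = L, modal = modal,
         estimate = estimate, n_questions = m, terminated = reached,
         engine = engine),
    class = "assessment_record"
  )
}

#' @export
print.assessment_record <- function(x, ...) {
  cat("<assessment_record> engine ", x$engine, ": ", x$n_questions,
      " problems, ", if (x$terminated) "terminated" else "domain exhausted",
      "; estimate = {", paste(x$likelihood$structure$domain[
        x$likelihood$structure$membership[x$estimate, ]], collapse = ", "),
      "}\n", sep = "")
  invisible(x)
}

#' Tidy an assessment record
#'
#' @param x An `assessment_record`.
#' @param ... Unused.
#' @return The per-step administration tibble.
#' @method tidy assessment_record
#' @export
tidy.assessment_record <- function(x, ...) x$administered

#' One-row summary of an assessment record
#'
#' @param x An `assessment_record`.
#' @param ... Unused.
#' @return A tibble with engine, question count, termination flag, final
#'   maximum likelihood, final entropy and the estimated state (as a
#'   comma-separated problem list).
#' @method glance assessment_record
#' @export
glance.assessment_record <- function(x, ...) {
  ks <- x$likelihood$structure
  tibble::tibble(
    engine = x$engine,
    n_questions = x$n_questions,
    terminated = x$terminated,
    max_likelihood = max(x$likelihood$weights),
    entropy = likelihood_entropy(x$likelihood),
    estimate = paste(ks$domain[ks$membership[x$estimate, ]], collapse = ",")
  )
}

#' Problem set of the estimated state
#'
#' @param record An `assessment_record`.
#' @return Character vector of problems in the tie-broken modal state.
#' @export
estimated_state <- function(record) {
  ks <- record$likelihood$structure
  ks$domain[ks$membership[record$estimate, ]]
}
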