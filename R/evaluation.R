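#' Hamming distance between knowledge states
#'
#' Size of the symmetric difference between a true and an estimated state.
#'
#' @param K,Khat Character vectors of problems from the same domain.
#' @param domain Optional domain; when given, both states are checked
#'   against it.
#' @return Non-negative integer count.
#' @export
hamming <- function(K, Khat, domain = NULL) {
  if (!is.null(domain)) {
    bad <- setdiff(c(K, Khat), domain)
    if (length(bad)) stop("problems outside the domain: ", paste(bad, collapse = ", "))
  }
  length(setdiff(K, Khat)) + length(setdiff(Khat, K))
}

#' True-positive rate of final state recovery
#'
#' Proportion of subjects whose final estimated state equals the true state
#' exactly.
#'
#' @param estimates List of character vectors (estimated states).
#' @param truths List of character vectors (true states), same length.
#' @return A proportion in `[0, 1]`.
#' @export
true_positive_rate <- function(estimates, truths) {
  if (length(estimates) != length(truths)) stop("estimates and truths differ in length")
  mean(mapply(function(e, t) setequal(e, t), estimates, truths))
}

# per-problem careless/lucky rates implied by an MSPM parameter table:
# beta_q = 1 - P(reach goal from s0 | beta rows), eta_q = P(reach goal | eta
# rows). Absorption probabilities follow by backward induction on distance.
implied_item_params <- function(gs, params) {
  d <- gs$dist
  ord <- names(sort(d[d >= 1]))
  pg <- function(col) {
    p <- stats::setNames(rep(0, length(d)), names(d))
    p[gs$goal] <- 1
    for (i in ord) {
      succ <- sp_successors(gs, i)$to
      pr <- vapply(succ, function(j) unname(lookup_rates(params, i, j, gs$failure)[col]), 0)
      p[i] <- sum(pr * p[succ])
    }
    p
  }
  pbeta <- pg("beta")
  peta <- pg("eta")
  eps <- 1e-12
  tibble::tibble(
    problem = gs$domain$initial,
    beta = pmin(pmax(1 - pbeta[gs$domain$initial], eps), 1 - eps),
    eta = pmin(pmax(peta[gs$domain$initial], eps), 1 - eps)
  )
}

#' Run a simulation study
#'
#' Reproduces the simulation-study protocol: per condition, transition
#' parameters are generated at the condition's error level, true knowledge
#' states are sampled from a random distribution over the structure (shared
#' across conditions of the same structure), a full response cohort is
#' simulated under the condition's generative planning assumption, a
#' dichotomized copy is made, and each requested engine assesses every
#' subject adaptively (the `cmp` engine on the dichotomized data with item
#' parameters implied by the generating MSPM table, the `msp*` engines on
#' the full processes). Metrics are recorded at every step `m`; a subject's
#' likelihood is frozen once the termination criterion is reached, so the
#' proportion terminated is non-decreasing in `m`.
#'
#' @param gs A [goal_space()].
#' @param ks The [knowledge_structure()] assumed true.
#' @param conditions A data frame with columns `model` (`"msp1"`, `"msp2"`
#'   or `"msp3"`), `error` (maximum careless level `x`) and `n` (sample
#'   size); one row per condition.
#' @param engines Character vector among `"cmp"`, `"msp1"`, `"msp2"`,
#'   `"msp3"`.
#' @param threshold Termination threshold, default `.5` (the protocol's
#'   value; see [run_assessment()]).
#' @param seed Integer root seed; every stochastic component derives its own
#'   stream from it.
#' @return An object of class `pkst_study`: list with `metrics` (tibble:
#'   `condition`, `model`, `error`, `engine`, `m`, `mean_hamming`,
#'   `mean_entropy`, `prop_terminated`) and `summary` (tibble: `condition`,
#'   `model`, `error`, `engine`, `tpr`, `mean_questions`).
#' @export
run_study <- function(gs, ks, conditions, engines = c("cmp", "msp1", "msp2", "msp3"),
                      threshold = 0.5, seed = 1L) {
  conditions <- tibble::as_tibble(conditions)
  stopifnot(all(c("model", "error", "n") %in% names(conditions)))
  n_max <- max(conditions$n)
  draw <- sample_states(ks, n_max, seed = derive_seed(seed, 1L))
  sets <- state_sets(ks)
  metrics <- list()
  summaries <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions[ci, ]
    params <- generate_params(gs, cond$error, seed = derive_seed(seed, 100L + ci))
    truth_idx <- draw$states[seq_len(cond$n)]
    truths <- sets[truth_idx]
    cohort <- simulate_cohort(gs, params, truths, cond$model,
                              seed = derive_seed(seed, 200L + ci))
    ip <- implied_item_params(gs, params)
    for (engine in engines) {
      res <- assess_cohort(gs, ks, cohort, engine, params, ip, truths,
                           threshold, seed = derive_seed(seed, 300L + ci))
      res$metrics$condition <- ci
      res$metrics$model <- cond$model
      res$metrics$error <- cond$error
      res$summary$condition <- ci
      res$summary$model <- cond$model
      res$summary$error <- cond$error
      metrics[[length(metrics) + 1L]] <- res$metrics
      summaries[[length(summaries) + 1L]] <- res$summary
    }
  }
  structure(
    list(metrics = dplyr::relocate(dplyr::bind_rows(metrics),
                                   "condition", "model", "error"),
         summary = dplyr::relocate(dplyr::bind_rows(summaries),
                                   "condition", "model", "error"),
         conditions = conditions, threshold = threshold, seed = seed),
    class = "pkst_study"
  )
}

# assess every subject of a (simulated or replayed) cohort with one engine;
# per-step metrics use likelihoods frozen at each subject's termination step.
# With truths = NULL (external logs, true states unknown) the Hamming series
# is taken against each subject's own final estimate and the TPR is NA.
assess_cohort <- function(gs, ks, cohort, engine, params, item_params,
                          truths = NULL, threshold = 0.5, seed = 1L) {
  subjects <- unique(cohort$subject)
  n_sub <- length(subjects)
  n_q <- length(ks$domain)
  ham <- matrix(NA_real_, n_sub, n_q)
  ent <- matrix(NA_real_, n_sub, n_q)
  term_step <- integer(n_sub)
  estimates <- vector("list", n_sub)
  questions <- integer(n_sub)
  for (w in seq_len(n_sub)) {
    rows <- cohort[cohort$subject == subjects[w], ]
    responses <- if (engine == "cmp") {
      stats::setNames(as.list(rows$correct), rows$problem)
    } else {
      stats::setNames(rows$visited, rows$problem)
    }
    rec <- run_assessment(ks, responses, engine = engine, gs = gs,
                          params = params, item_params = item_params,
                          threshold = threshold, seed = derive_seed(seed, w),
                          stop_at_threshold = FALSE)
    adm <- rec$administered
    first_term <- which(adm$terminated)[1]
    stop_m <- if (is.na(first_term)) n_q else first_term
    term_step[w] <- if (is.na(first_term)) n_q + 1L else first_term
    questions[w] <- stop_m
    estimates[[w]] <- adm$modal_set[[n_q]]
    ref <- if (is.null(truths)) estimates[[w]] else truths[[w]]
    for (m in seq_len(n_q)) {
      mm <- min(m, stop_m)
      ham[w, m] <- hamming(ref, adm$modal_set[[mm]])
      ent[w, m] <- adm$entropy[mm]
    }
  }
  metrics <- tibble::tibble(
    engine = engine,
    m = seq_len(n_q),
    mean_hamming = colMeans(ham),
    mean_entropy = colMeans(ent),
    prop_terminated = vapply(seq_len(n_q), function(m) mean(term_step <= m), 0)
  )
  summary <- tibble::tibble(
    engine = engine,
    tpr = if (is.null(truths)) NA_real_ else true_positive_rate(estimates, truths),
    mean_questions = mean(questions)
  )
  list(metrics = metrics, summary = summary)
}

#' Replay a solution-process log through the assessment engines
#'
#' Runs each requested engine over an externally supplied (or previously
#' simulated) process log of the [simulate_cohort()] shape, producing the
#' same per-step metric series as [run_study()]. True states are unknown for
#' replayed data, so the Hamming series compares each subject's step-`m`
#' modal estimate with their final estimate, and no true-positive rate is
#' reported.
#'
#' @param gs A [goal_space()].
#' @param ks A [knowledge_structure()].
#' @param log Process log tibble with columns `subject`, `problem`,
#'   `visited` (list-column); a `correct` column is derived when absent.
#' @param params A [transition_params()] table used by the `msp*` updates
#'   (and to imply the `cmp` item parameters).
#' @param engines Engines to run.
#' @param threshold Termination threshold.
#' @param seed Integer seed for tie breaking.
#' @return A `pkst_study` object (see [run_study()]) with `tpr = NA`.
#' @export
replay_log <- function(gs, ks, log, params,
                       engines = c("cmp", "msp1", "msp2", "msp3"),
                       threshold = 0.5, seed = 1L) {
  if (!"correct" %in% names(log)) {
    log$correct <- vapply(log$visited, function(v) dichotomize(v, gs), 0L)
  }
  ip <- implied_item_params(gs, params)
  metrics <- list()
  summaries <- list()
  for (engine in engines) {
    res <- assess_cohort(gs, ks, log, engine, params, ip, truths = NULL,
                         threshold = threshold, seed = seed)
    res$metrics$condition <- 1L
    res$summary$condition <- 1L
    metrics[[length(metrics) + 1L]] <- res$metrics
    summaries[[length(summaries) + 1L]] <- res$summary
  }
  structure(
    list(metrics = dplyr::bind_rows(metrics),
         summary = dplyr::bind_rows(summaries),
         conditions = NULL, threshold = threshold, seed = seed),
    class = "pkst_study"
  )
}

#' Plot the metric series of a simulation study
#'
#' @param object A `pkst_study` from [run_study()].
#' @param metric One of `"mean_hamming"`, `"mean_entropy"`,
#'   `"prop_terminated"`.
#' @param ... Unused.
#' @return A ggplot: metric against the number of problems asked, one line
#'   per engine, faceted by condition.
#' @method autoplot pkst_study
#' @export
autoplot.pkst_study <- function(object, metric = "mean_hamming", ...) {
  stopifnot(metric %in% c("mean_hamming", "mean_entropy", "prop_terminated"))
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$m, y = .data[[metric]],
                               colour = .data$engine)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ condition, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "problems asked (m)", y = metric, colour = "engine") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
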