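#' Read and write problem spaces and goal spaces as JSON
#'
#' The schema stores `states`, `operations` and the labeled edge list
#' (direction always initial state to successor); goal spaces additionally
#' record the `goal` and `failure` markers and the `drop_one_move` flag, and
#' are rebuilt from the underlying space so all derived structure is
#' regenerated on read. Probabilities and all numbers round-trip exactly
#' (17 significant digits).
#'
#' @param x A [problem_space()] or [goal_space()].
#' @param path File path.
#' @return `write_space_json()` returns `path` invisibly;
#'   `read_space_json()` returns the reconstructed object.
#' @export
write_space_json <- function(x, path) {
  if (inherits(x, "goal_space")) {
    payload <- list(
      type = "goal_space",
      states = x$space$states, operations = x$space$operations,
      edges = x$space$edges, goal = x$goal, failure = x$failure,
      drop_one_move = x$drop_one_move
    )
  } else {
    stopifnot(inherits(x, "problem_space"))
    payload <- list(type = "problem_space", states = x$states,
                    operations = x$operations, edges = x$edges)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_space_json
#' @export
read_space_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("states", "edges")) {
    if (is.null(obj[[f]])) stop("space file ", path, " lacks field '", f, "'")
  }
  sp <- problem_space(obj$edges, states = obj$states, operations = obj$operations)
  if (identical(obj$type, "goal_space")) {
    goal_space(sp, obj$goal, drop_one_move = isTRUE(obj$drop_one_move),
               failure = obj$failure)
  } else {
    sp
  }
}

#' Read and write knowledge structures
#'
#' JSON files store the ordered domain and one bit-string per state
#' (`"01001"`, positions following the recorded domain order); CSV files
#' store the 0/1 membership matrix with problems as columns.
#'
#' @param ks A [knowledge_structure()].
#' @param path File path.
#' @return Writers return `path` invisibly; readers the structure.
#' @export
write_structure_json <- function(ks, path) {
  bits <- apply(ks$membership, 1L, function(r) paste(as.integer(r), collapse = ""))
  jsonlite::write_json(list(domain = ks$domain, states = bits), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_structure_json
#' @export
read_structure_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$domain) || is.null(obj$states)) {
    stop("structure file ", path, " must have fields 'domain' and 'states'")
  }
  n <- length(obj$domain)
  if (any(nchar(obj$states) != n)) stop("bit-string length mismatch in ", path)
  memb <- t(vapply(strsplit(obj$states, ""), function(b) b == "1", logical(n)))
  knowledge_structure(obj$domain, memb)
}

#' @rdname write_structure_json
#' @export
write_structure_csv <- function(ks, path) {
  df <- as.data.frame(ks$membership * 1L)
  names(df) <- ks$domain
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_structure_json
#' @export
read_structure_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  knowledge_structure(names(df), as.matrix(df) == 1L)
}

#' Read and write transition-parameter tables as CSV
#'
#' Column layout `i, j, beta, eta`, one row per on-path elementary
#' transition.
#'
#' @param params A [transition_params()] table.
#' @param path File path.
#' @param gs Optional [goal_space()] for validation on read.
#' @return Writer returns `path` invisibly; reader the validated table.
#' @export
write_params_csv <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params_csv
#' @export
read_params_csv <- function(path, gs = NULL) {
  df <- utils::read.csv(path)
  need <- c("i", "j", "beta", "eta")
  if (!all(need %in% names(df))) {
    stop("params file ", path, " must have columns ", paste(need, collapse = ", "))
  }
  transition_params(df, gs)
}

#' Read and write solution-process logs as JSON lines
#'
#' One JSON object per line: `{"subject": w, "problem": q, "visited":
#' [states...], "terminal": "goal"|"failure"}`. On read, each consecutive
#' state pair can be validated against a goal space's elementary pairs.
#'
#' @param log A tibble with columns `subject`, `problem`, `visited`
#'   (list-column), `terminal` (as produced by [simulate_cohort()]).
#' @param path File path.
#' @param gs Optional [goal_space()]; when given, processes with
#'   non-elementary jumps are rejected naming the offending pair.
#' @return Writer returns `path` invisibly; reader the log tibble (with a
#'   recomputed `correct` column when `gs` is given).
#' @export
write_processes_jsonl <- function(log, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_len(nrow(log))) {
    writeLines(jsonlite::toJSON(list(
      subject = log$subject[k], problem = log$problem[k],
      visited = log$visited[[k]], terminal = log$terminal[k]
    ), auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' @rdname write_processes_jsonl
#' @export
read_processes_jsonl <- function(path, gs = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  rows <- lapply(seq_along(lines), function(k) {
    obj <- jsonlite::fromJSON(lines[k], simplifyVector = TRUE)
    for (f in c("subject", "problem", "visited", "terminal")) {
      if (is.null(obj[[f]])) stop("line ", k, ": missing field '", f, "'")
    }
    visited <- as.character(obj$visited)
    if (!is.null(gs)) {
      ep <- elementary_pairs(gs)
      ok <- paste(ep$i, ep$j)
      for (t in seq_len(length(visited) - 1L)) {
        if (!paste(visited[t], visited[t + 1L]) %in% ok) {
          stop("line ", k, ": non-elementary jump (", visited[t], ", ",
               visited[t + 1L], ")")
        }
      }
    }
    tibble::tibble(subject = obj$subject, problem = obj$problem,
                   visited = list(visited), terminal = obj$terminal)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(gs)) {
    out$correct <- vapply(out$visited, function(v) dichotomize(v, gs), 0L)
  }
  out
}

#' Read a study configuration from YAML
#'
#' Expected top-level fields: `conditions` (list of `model`/`error`/`n`
#' records), `engines`, `threshold` (optional) and `seed`.
#'
#' @param path File path.
#' @return A list ready to splice into [run_study()]: `conditions` tibble,
#'   `engines`, `threshold`, `seed`.
#' @export
read_study_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$conditions)) stop("study config ", path, " lacks 'conditions'")
  conditions <- dplyr::bind_rows(lapply(cfg$conditions, function(cond) {
    # YAML 1.1 resolves a bare key `n` to a boolean; map it back
    names(cond)[names(cond) %in% c("FALSE", "no")] <- "n"
    tibble::as_tibble(cond)
  }))
  list(conditions = conditions,
       engines = cfg$engines %||% c("cmp", "msp1", "msp2", "msp3"),
       threshold = cfg$threshold %||% 0.5,
       seed = cfg$seed %||% 1L)
}
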