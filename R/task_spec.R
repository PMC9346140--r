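#' Define a monitoring-task specification
#'
#' A task specification describes a dynamic interactive task as seen by the
#' gaze model: the areas of interest (AOIs) an operator can fixate, how often
#' information inside each AOI changes, and how valuable that information is
#' to the concurrent subtasks.
#'
#' @param aoi Character vector of AOI names, in display order. The order is
#'   part of the contract: it fixes the state-bit layout and downstream
#'   tie-breaking (lowest index wins a tie).
#' @param bandwidth Named numeric vector (one entry per AOI) giving the
#'   probability, in `[0, 1]`, that the AOI's information updates during one
#'   decision period.
#' @param subtasks Data frame with columns `name` (character) and `value`
#'   (positive integer) listing the concurrent subtasks and their priorities.
#' @param relevance Numeric matrix with one row per subtask and one column
#'   per AOI (dimnames required), entries in `[0, 1]`, giving the relevance
#'   of each AOI to each subtask.
#' @param redundancy Named list mapping an AOI to a character vector of
#'   *additional* AOIs whose information is acquired and maintained while
#'   that AOI is fixated (e.g. an instrument panel rendered inside a flight
#'   tunnel display). May be empty.
#' @param horizon Positive integer, the number of decision points `N`.
#' @param period_s Positive number, seconds per decision period.
#' @param name Optional label for the task (used in printouts and exports).
#'
#' @return An object of class `task_spec`.
#'
#' @examples
#' spec <- task_spec(
#'   aoi = c("A", "B"),
#'   bandwidth = c(A = 0.3, B = 0.6),
#'   subtasks = data.frame(name = "watch", value = 1L),
#'   relevance = matrix(c(1, 0.5), 1, 2,
#'     dimnames = list("watch", c("A", "B"))
#'   ),
#'   horizon = 10, period_s = 0.5
#' )
#' spec
#' @export
task_spec <- function(aoi, bandwidth, subtasks, relevance,
                      redundancy = list(), horizon, period_s,
                      name = NULL) {
  spec <- structure(
    list(
      name = name %||% "task",
      aoi = as.character(aoi),
      bandwidth = bandwidth,
      subtasks = tibble::as_tibble(subtasks),
      relevance = relevance,
      redundancy = redundancy,
      horizon = as.integer(horizon),
      period_s = as.numeric(period_s)
    ),
    class = "task_spec"
  )
  validate_task_spec(spec)
}

#' @export
print.task_spec <- function(x, ...) {
  cat("<task_spec> ", x$name, "\n", sep = "")
  cat("  AOIs (", length(x$aoi), "): ",
    paste(sprintf("%s[%.2f]", x$aoi, x$bandwidth[x$aoi]), collapse = ", "),
    "\n",
    sep = ""
  )
  cat("  subtasks: ",
    paste(sprintf("%s=%d", x$subtasks$name, x$subtasks$value), collapse = ", "),
    "\n",
    sep = ""
  )
  if (length(x$redundancy)) {
    for (k in names(x$redundancy)) {
      cat("  redundancy: ", k, " covers ",
        paste(x$redundancy[[k]], collapse = ", "), "\n",
        sep = ""
      )
    }
  }
  cat("  horizon: ", x$horizon, " decision points x ", x$period_s, " s\n",
    sep = ""
  )
  invisible(x)
}

validate_task_spec <- function(spec) {
  fail <- function(msg) {
    rlang::abort(msg, class = "gazemdp_error_validation")
  }
  n <- length(spec$aoi)
  if (n < 1) fail("a task_spec needs at least one AOI")
  if (anyDuplicated(spec$aoi)) fail("AOI names must be unique")

  bw <- spec$bandwidth
  if (is.null(names(bw)) || !setequal(names(bw), spec$aoi)) {
    fail("`bandwidth` must be named with exactly the declared AOIs")
  }
  spec$bandwidth <- bw <- as.numeric(bw[spec$aoi]) |> stats::setNames(spec$aoi)
  if (anyNA(bw) || any(bw < 0 | bw > 1)) {
    fail("every `bandwidth` must lie in [0, 1]")
  }

  st <- spec$subtasks
  if (!all(c("name", "value") %in% names(st))) {
    fail("`subtasks` needs columns `name` and `value`")
  }
  if (nrow(st) < 1 || anyDuplicated(st$name)) {
    fail("`subtasks` must list at least one uniquely named subtask")
  }
  if (anyNA(st$value) || any(st$value < 1) ||
    any(st$value != as.integer(st$value))) {
    fail("subtask `value` must be an integer >= 1")
  }
  spec$subtasks$value <- as.integer(st$value)

  rel <- spec$relevance
  if (!is.matrix(rel) || is.null(rownames(rel)) || is.null(colnames(rel))) {
    fail("`relevance` must be a matrix with subtask rownames and AOI colnames")
  }
  if (!setequal(rownames(rel), st$name) || !setequal(colnames(rel), spec$aoi)) {
    fail("`relevance` dimnames must match the declared subtasks and AOIs")
  }
  rel <- rel[st$name, spec$aoi, drop = FALSE]
  if (anyNA(rel) || any(rel < 0 | rel > 1)) {
    fail("every `relevance` must lie in [0, 1]")
  }
  spec$relevance <- rel

  red <- spec$redundancy
  if (length(red)) {
    if (is.null(names(red)) || !all(names(red) %in% spec$aoi)) {
      fail("`redundancy` keys must be declared AOIs")
    }
    for (k in names(red)) {
      cov <- red[[k]]
      if (k %in% cov) fail("a redundancy set must not contain its own AOI")
      if (!all(cov %in% spec$aoi)) {
        fail("redundancy sets may reference only declared AOIs")
      }
    }
    # drop empty sets so length(redundancy) == 0 means "none"
    spec$redundancy <- red[lengths(red) > 0]
  }

  if (is.na(spec$horizon) || spec$horizon < 1) fail("`horizon` must be >= 1")
  if (is.na(spec$period_s) || spec$period_s <= 0) fail("`period_s` must be > 0")
  spec
}

#' Number of AOIs in a task specification
#' @param spec A [task_spec()].
#' @return Integer scalar.
#' @export
n_aoi <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  length(spec$aoi)
}

# AOIs covered while fixating each AOI: itself plus its redundancy set.
covered_aois <- function(spec, aoi) {
  union(aoi, spec$redundancy[[aoi]])
}

#' Read a task specification from a YAML file
#'
#' The on-disk schema is a flat YAML document with keys `name`, `aoi`
#' (ordered list), `bandwidth`, `subtasks` (list of `name`/`value` pairs),
#' `relevance` (map subtask -> map AOI -> value), optional `redundancy`
#' (map AOI -> list of covered AOIs), `horizon` and `period_s`. AOI order in
#' the file is preserved.
#'
#' @param path Path to a YAML task file.
#' @return A [task_spec()].
#' @seealso [write_task_spec()], [flight_condition()]
#' @export
read_task_spec <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("no such task file: ", path),
      class = "gazemdp_error_parse"
    )
  }
  doc <- tryCatch(yaml::read_yaml(path), error = function(e) {
    rlang::abort(paste0("cannot parse task file: ", conditionMessage(e)),
      class = "gazemdp_error_parse"
    )
  })
  need <- c("aoi", "bandwidth", "subtasks", "relevance", "horizon", "period_s")
  missing <- setdiff(need, names(doc))
  if (length(missing)) {
    rlang::abort(
      paste0("task file is missing field(s): ", paste(missing, collapse = ", ")),
      class = "gazemdp_error_parse"
    )
  }
  aoi <- as.character(unlist(doc$aoi))
  subtasks <- tibble::tibble(
    name = purrr::map_chr(doc$subtasks, "name"),
    value = purrr::map_int(doc$subtasks, \(s) as.integer(s$value))
  )
  rel <- matrix(0, nrow(subtasks), length(aoi),
    dimnames = list(subtasks$name, aoi)
  )
  for (s in names(doc$relevance)) {
    if (!s %in% subtasks$name) {
      rlang::abort(paste0("relevance refers to unknown subtask: ", s),
        class = "gazemdp_error_parse"
      )
    }
    row <- doc$relevance[[s]]
    bad <- setdiff(names(row), aoi)
    if (length(bad)) {
      rlang::abort(paste0("relevance refers to unknown AOI: ", bad[1]),
        class = "gazemdp_error_parse"
      )
    }
    rel[s, names(row)] <- as.numeric(unlist(row))
  }
  red <- purrr::map(doc$redundancy %||% list(), \(v) as.character(unlist(v)))
  task_spec(
    aoi = aoi,
    bandwidth = unlist(doc$bandwidth)[aoi],
    subtasks = subtasks,
    relevance = rel,
    redundancy = red,
    horizon = doc$horizon,
    period_s = doc$period_s,
    name = doc$name %||% basename(path)
  )
}

#' Write a task specification to a YAML file
#'
#' @param spec A [task_spec()].
#' @param path Output path.
#' @return `path`, invisibly. Round-tripping through
#'   [read_task_spec()] reproduces the spec exactly.
#' @export
write_task_spec <- function(spec, path) {
  stopifnot(inherits(spec, "task_spec"))
  doc <- list(
    name = spec$name,
    aoi = as.list(spec$aoi),
    bandwidth = as.list(spec$bandwidth),
    subtasks = purrr::pmap(spec$subtasks, \(name, value) {
      list(name = name, value = value)
    }),
    relevance = purrr::set_names(
      purrr::map(spec$subtasks$name, \(s) as.list(spec$relevance[s, ])),
      spec$subtasks$name
    ),
    horizon = spec$horizon,
    period_s = spec$period_s
  )
  if (length(spec$redundancy)) {
    doc$redundancy <- purrr::map(spec$redundancy, as.list)
  }
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}
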