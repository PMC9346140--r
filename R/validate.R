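#' Fixation proportions of simulated scanpaths
#'
#' Pools every fixation of every sequence and normalizes the per-AOI counts
#' by the total number of fixations.
#'
#' @param scanpaths An [sa_scanpath_set][simulate_scanpaths()] or a single
#'   [sa_scanpath][simulate_scanpath()].
#' @return A tibble with columns `aoi` (declared order) and `prob`,
#'   summing to 1.
#' @export
fixation_proportions <- function(scanpaths) {
  spec <- spec_of(scanpaths)
  acts <- actions_of(scanpaths)
  if (length(acts) == 0) {
    rlang::abort("no fixations to tabulate", class = "gazemdp_error_contract")
  }
  counts <- tabulate(acts, nbins = n_aoi(spec))
  tibble::tibble(aoi = spec$aoi, prob = counts / sum(counts))
}

#' Shift proportions between AOIs
#'
#' Tabulates every consecutive fixation pair of every sequence into
#' unordered AOI pair categories (self-pairs included; `n(n+1)/2`
#' categories for `n` AOIs), normalized by the total number of pairs.
#'
#' @inheritParams fixation_proportions
#' @return A tibble with columns `pair` (e.g. `"SVS-IP"`; order follows the
#'   declared AOI order), `aoi_a`, `aoi_b` and `prob`, summing to 1.
#' @export
shift_proportions <- function(scanpaths) {
  spec <- spec_of(scanpaths)
  acts <- actions_of(scanpaths, matrix = TRUE)
  if (ncol(acts) < 2) {
    rlang::abort("sequences must have length >= 2 to have shifts",
      class = "gazemdp_error_contract"
    )
  }
  n <- n_aoi(spec)
  from <- acts[, -ncol(acts), drop = FALSE]
  to <- acts[, -1, drop = FALSE]
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  idx <- (lo - 1L) * n + hi # unordered-pair bin
  counts <- tabulate(idx, nbins = n * n)
  pairs <- pair_categories(spec)
  tibble::tibble(
    pair = paste(spec$aoi[pairs$a], spec$aoi[pairs$b], sep = "-"),
    aoi_a = spec$aoi[pairs$a],
    aoi_b = spec$aoi[pairs$b],
    prob = counts[(pairs$a - 1L) * n + pairs$b] / sum(counts)
  )
}

pair_categories <- function(spec) {
  n <- n_aoi(spec)
  a <- rep(seq_len(n), times = n:1)
  b <- unlist(lapply(seq_len(n), \(i) i:n))
  list(a = a, b = b)
}

spec_of <- function(x) {
  if (inherits(x, "sa_scanpath_set")) {
    return(x$spec)
  }
  if (inherits(x, "sa_scanpath")) {
    return(attr(x, "spec"))
  }
  rlang::abort("expected an sa_scanpath or sa_scanpath_set",
    class = "gazemdp_error_contract"
  )
}

actions_of <- function(x, matrix = FALSE) {
  if (inherits(x, "sa_scanpath_set")) {
    return(x$actions)
  }
  spec <- attr(x, "spec")
  a <- match(x$aoi, spec$aoi)
  if (matrix) matrix(a, nrow = 1) else a
}

#' Shift probabilities implied by a fixation distribution
#'
#' Converts fixation probabilities into the shift probabilities of a
#' sequence with independently drawn fixations: the unordered pair `{i, j}`
#' has probability `2 * p_i * p_j` for `i != j` and `p_i^2` for the
#' self-pair. This is how observed shift probabilities are derived from
#' observed fixation distributions when only the latter are reported.
#'
#' @param fixation A tibble with columns `aoi` and a probability column
#'   (the first numeric column is used), or a named numeric vector.
#' @return A tibble with columns `pair`, `aoi_a`, `aoi_b`, `prob`. The
#'   probabilities sum to `(sum(p))^2`, i.e. to 1 when `p` is a
#'   distribution.
#' @examples
#' observed_shift_probs(c(SVS = 0.66, ND = 0.18))
#' @export
observed_shift_probs <- function(fixation) {
  if (is.data.frame(fixation)) {
    num <- names(fixation)[vapply(fixation, is.numeric, logical(1))][1]
    p <- stats::setNames(fixation[[num]], fixation$aoi)
  } else {
    p <- fixation
  }
  if (is.null(names(p)) || anyNA(p) || any(p < 0 | p > 1)) {
    rlang::abort("`fixation` must give named probabilities in [0, 1]",
      class = "gazemdp_error_contract"
    )
  }
  n <- length(p)
  a <- rep(seq_len(n), times = n:1)
  b <- unlist(lapply(seq_len(n), \(i) i:n))
  tibble::tibble(
    pair = paste(names(p)[a], names(p)[b], sep = "-"),
    aoi_a = names(p)[a],
    aoi_b = names(p)[b],
    prob = ifelse(a == b, p[a]^2, 2 * p[a] * p[b])
  )
}

#' Pearson product-moment correlation
#'
#' Thin validation wrapper around [stats::cor()]: requires at least three
#' paired points and non-constant vectors, the conditions under which a
#' model-vs-observation correlation is meaningful.
#'
#' @param x,y Numeric vectors of equal length `>= 3`.
#' @return The correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    rlang::abort("`x` and `y` must be equal-length vectors of length >= 3",
      class = "gazemdp_error_contract"
    )
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rlang::abort("correlation is undefined for a constant vector",
      class = "gazemdp_error_undefined"
    )
  }
  stats::cor(x, y)
}

#' Run the eight-condition validation battery
#'
#' For every built-in flight-display condition: solve the chosen fixation
#' policy, simulate `replications` scanpaths over the full task horizon,
#' and compute predicted fixation and shift proportions. Predictions are
#' then correlated against the observed fixation distributions (and against
#' the shift probabilities they imply, see [observed_shift_probs()]), per
#' condition and pooled over all conditions.
#'
#' @param policy `"dp"` (optimal, backwards induction) or `"greedy"`
#'   (one-step baseline).
#' @param replications Scanpaths per condition (default 1000).
#' @param seed Integer seed; every condition's simulation derives its own
#'   stream from it, so the whole battery is reproducible.
#' @param conditions Conditions to run (default: all eight).
#' @return An object of class `sa_battery` with tibble fields:
#'   `fixation` (`condition`, `aoi`, `predicted`, `observed`),
#'   `shift` (`condition`, `pair`, `predicted`, `observed`),
#'   `correlations` (`condition`, `fixation_r`, `shift_r`; the `"overall"`
#'   row pools all conditions), and metadata (`policy`, `replications`,
#'   `seed`).
#' @examples
#' \donttest{
#' bat <- run_battery("dp", replications = 50, seed = 1)
#' glance(bat)
#' }
#' @export
run_battery <- function(policy = c("dp", "greedy"), replications = 1000,
                        seed = 1L, conditions = condition_names) {
  policy <- match.arg(policy)
  if (replications < 1) {
    rlang::abort("`replications` must be >= 1",
      class = "gazemdp_error_contract"
    )
  }
  if (replications < 30) {
    rlang::warn(paste0(
      "only ", replications, " replications; proportion estimates will ",
      "carry substantial sampling error"
    ))
  }
  fix_rows <- list()
  shift_rows <- list()
  for (i in seq_along(conditions)) {
    cond <- conditions[i]
    cnd <- flight_condition(cond)
    pol <- switch(policy,
      dp = solve_policy(cnd$spec, keep_q = FALSE),
      greedy = greedy_policy(cnd$spec)
    )
    sims <- simulate_scanpaths(cnd$spec, pol,
      n_seq = replications,
      seed = seed + (i - 1L)
    )
    fix_rows[[cond]] <- fixation_proportions(sims) |>
      dplyr::left_join(cnd$observed, by = "aoi") |>
      dplyr::transmute(
        condition = cond, aoi = .data$aoi,
        predicted = .data$prob,
        observed = .data$observed_fixation_prob
      )
    obs_shift <- observed_shift_probs(
      stats::setNames(
        cnd$observed$observed_fixation_prob,
        cnd$observed$aoi
      )
    )
    shift_rows[[cond]] <- shift_proportions(sims) |>
      dplyr::left_join(
        dplyr::select(obs_shift, "pair", observed = "prob"),
        by = "pair"
      ) |>
      dplyr::transmute(
        condition = cond, pair = .data$pair,
        predicted = .data$prob, observed = .data$observed
      )
  }
  fixation <- purrr::list_rbind(fix_rows)
  shift <- purrr::list_rbind(shift_rows)
  per_cond <- tibble::tibble(
    condition = conditions,
    fixation_r = purrr::map_dbl(conditions, \(cc) {
      d <- dplyr::filter(fixation, .data$condition == cc)
      pearson_r(d$predicted, d$observed)
    }),
    shift_r = purrr::map_dbl(conditions, \(cc) {
      d <- dplyr::filter(shift, .data$condition == cc)
      pearson_r(d$predicted, d$observed)
    })
  )
  overall <- tibble::tibble(
    condition = "overall",
    fixation_r = pearson_r(fixation$predicted, fixation$observed),
    shift_r = pearson_r(shift$predicted, shift$observed)
  )
  structure(
    list(
      fixation = fixation, shift = shift,
      correlations = dplyr::bind_rows(per_cond, overall),
      policy = policy, replications = as.integer(replications),
      seed = as.integer(seed)
    ),
    class = "sa_battery"
  )
}

#' @export
print.sa_battery <- function(x, ...) {
  ov <- dplyr::filter(x$correlations, .data$condition == "overall")
  cat("<sa_battery> ", x$policy, " policy, ", x$replications,
    " sequences/condition, seed ", x$seed, "\n",
    sep = ""
  )
  cat(sprintf(
    "  overall fixation r = %.3f, overall shift r = %.3f\n",
    ov$fixation_r, ov$shift_r
  ))
  print(x$correlations, n = Inf)
  invisible(x)
}

#' Tidy a validation battery
#'
#' @param x An [sa_battery][run_battery()].
#' @param type `"fixation"` (default), `"shift"` or `"correlations"`.
#' @param ... Unused.
#' @return The requested tibble.
#' @export
tidy.sa_battery <- function(x, type = c("fixation", "shift", "correlations"),
                            ...) {
  type <- match.arg(type)
  x[[type]]
}

#' @rdname tidy.sa_battery
#' @export
glance.sa_battery <- function(x, ...) {
  ov <- dplyr::filter(x$correlations, .data$condition == "overall")
  tibble::tibble(
    policy = x$policy,
    replications = x$replications,
    seed = x$seed,
    n_conditions = nrow(x$correlations) - 1L,
    fixation_r = ov$fixation_r,
    fixation_r2 = ov$fixation_r^2,
    shift_r = ov$shift_r
  )
}
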