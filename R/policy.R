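#' Optimal fixation policy by backwards induction
#'
#' Solves the finite-horizon MDP for the fixation policy that maximizes the
#' expected total situation-awareness reward over the task horizon. The
#' action-value recursion is
#' `Q_t(s, a) = r(s, a) + sum_{s'} P(s' | s, a) * max_{a'} Q_{t+1}(s', a')`
#' with the boundary condition `Q_N = 0`, evaluated backwards from the
#' terminal stage. The decision rule at each stage is the arg-max action,
#' with ties broken by the lowest AOI index in declared order.
#'
#' @param spec A [task_spec()].
#' @param horizon Number of decision points; defaults to `spec$horizon`.
#' @param keep_q Keep the full stage-indexed action-value array (size
#'   `2^n x n x horizon`)? Default `TRUE`.
#' @return An object of class `sa_policy` with fields `rules`
#'   (`2^n x horizon` integer matrix of optimal action indices, column
#'   `t + 1` holding the rule at decision moment `t`), `q` (the action-value
#'   array, or `NULL`), `kind = "dp"`, and the governing `spec`.
#' @examples
#' pol <- solve_policy(flight_condition("DSV")$spec, horizon = 5)
#' tidy(pol)
#' @export
solve_policy <- function(spec, horizon = spec$horizon, keep_q = TRUE) {
  stopifnot(inherits(spec, "task_spec"))
  n <- n_aoi(spec)
  check_enum_guard(n)
  N <- as.integer(horizon)
  if (is.na(N) || N < 1) {
    rlang::abort("`horizon` must be >= 1", class = "gazemdp_error_contract")
  }
  S <- 2^n
  P <- lapply(seq_len(n), \(a) transition_matrix(spec, a))
  R <- reward_matrix(spec)

  rules <- matrix(0L, S, N)
  q <- if (keep_q) array(0, dim = c(S, n, N)) else NULL
  v_next <- numeric(S) # max_a Q_N(s, a) = 0
  for (t in (N - 1):0) {
    Q <- R
    for (a in seq_len(n)) Q[, a] <- Q[, a] + P[[a]] %*% v_next
    rules[, t + 1] <- max.col(Q, ties.method = "first")
    v_next <- Q[cbind(seq_len(S), rules[, t + 1])]
    if (keep_q) q[, , t + 1] <- Q
  }
  structure(
    list(spec = spec, rules = rules, q = q, kind = "dp", horizon = N),
    class = "sa_policy"
  )
}

#' One-step greedy baseline policy
#'
#' The step-by-step baseline directs the next fixation to the AOI with the
#' maximal expected amount of new information, without lookahead: the rule
#' picks `argmax_a sum over covered, currently-unknown AOIs of bandwidth`,
#' ties broken by lowest AOI index. The rule is the same at every decision
#' moment.
#'
#' @inheritParams solve_policy
#' @return An `sa_policy` with `kind = "greedy"` and `q = NULL`.
#' @export
greedy_policy <- function(spec, horizon = spec$horizon) {
  stopifnot(inherits(spec, "task_spec"))
  n <- n_aoi(spec)
  check_enum_guard(n)
  N <- as.integer(horizon)
  if (is.na(N) || N < 1) {
    rlang::abort("`horizon` must be >= 1", class = "gazemdp_error_contract")
  }
  S <- 2^n
  bits <- codes_to_bits(0:(S - 1), n)
  gain <- matrix(0, S, n)
  for (a in seq_len(n)) {
    cov <- match(covered_aois(spec, spec$aoi[a]), spec$aoi)
    gain[, a] <- (1 - bits[, cov, drop = FALSE]) %*% spec$bandwidth[cov]
  }
  rule <- max.col(gain, ties.method = "first")
  structure(
    list(
      spec = spec,
      rules = matrix(rule, S, N),
      q = NULL, kind = "greedy", horizon = N
    ),
    class = "sa_policy"
  )
}

#' @export
print.sa_policy <- function(x, ...) {
  st <- policy_stationarity(x)
  cat("<sa_policy> ", x$kind, " policy for ", x$spec$name,
    ": ", nrow(x$rules), " states x ", x$horizon, " moments\n",
    sep = ""
  )
  cat(
    "  stationary over moments 0..", st$stationary_until,
    " (", st$n_distinct_rules, " distinct rule(s))\n",
    sep = ""
  )
  invisible(x)
}

#' Decision rule of a policy at one moment
#'
#' @param policy An [sa_policy][solve_policy()].
#' @param moment Decision moment `t` in `0..horizon-1` (default 0, the
#'   maximal-lookahead rule).
#' @return A tibble with columns `state` (bit string) and `action`
#'   (AOI name).
#' @export
policy_rule <- function(policy, moment = 0) {
  stopifnot(inherits(policy, "sa_policy"))
  t <- as.integer(moment)
  if (is.na(t) || t < 0 || t >= policy$horizon) {
    rlang::abort("`moment` must lie in 0..horizon-1",
      class = "gazemdp_error_contract"
    )
  }
  tibble::tibble(
    state = sa_states(policy$spec)$state,
    action = policy$spec$aoi[policy$rules[, t + 1]]
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fixation policy
#'
#' @param x An [sa_policy][solve_policy()].
#' @param moment Decision moment whose rule to return (default 0). Use
#'   `moment = NULL` to return the rules of all moments in long format.
#' @param ... Unused.
#' @return A tibble with columns `state`, `action` (and `moment` when
#'   `moment = NULL`).
#' @export
tidy.sa_policy <- function(x, moment = 0, ...) {
  if (is.null(moment)) {
    states <- sa_states(x$spec)$state
    return(tidyr::expand_grid(
      moment = 0:(x$horizon - 1),
      state = states
    ) |>
      dplyr::mutate(
        action = x$spec$aoi[x$rules[cbind(
          match(.data$state, states),
          .data$moment + 1L
        )]]
      ))
  }
  policy_rule(x, moment)
}

#' @rdname tidy.sa_policy
#' @export
glance.sa_policy <- function(x, ...) {
  st <- policy_stationarity(x)
  tibble::tibble(
    kind = x$kind,
    condition = x$spec$name,
    n_aoi = n_aoi(x$spec),
    n_states = nrow(x$rules),
    horizon = x$horizon,
    stationary_until = st$stationary_until,
    n_distinct_rules = st$n_distinct_rules,
    value_unaware = if (is.null(x$q)) {
      NA_real_
    } else {
      max(x$q[1, , 1]) # expected total reward from the fully unaware state
    }
  )
}

#' Stationarity of a policy's decision rules
#'
#' Backwards induction can yield the same decision rule at every moment far
#' from the horizon while the last few stages differ (there is no future to
#' plan for). This report makes that structure explicit.
#'
#' @param policy An [sa_policy][solve_policy()].
#' @return A list with `stationary_until` (largest `t*` such that the rules
#'   at moments `0..t*` are all identical to the rule at 0),
#'   `n_distinct_rules` (number of distinct per-moment rules over the whole
#'   horizon), and `changing_moments` (moments whose rule differs from the
#'   rule at moment 0).
#' @export
policy_stationarity <- function(policy) {
  stopifnot(inherits(policy, "sa_policy"))
  rules <- policy$rules
  same_as_0 <- apply(rules == rules[, 1], 2, all)
  first_diff <- which(!same_as_0)[1]
  list(
    stationary_until = if (is.na(first_diff)) {
      policy$horizon - 1L
    } else {
      first_diff - 2L
    },
    n_distinct_rules = nrow(unique(t(rules))),
    changing_moments = which(!same_as_0) - 1L
  )
}
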