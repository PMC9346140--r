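# Situation-awareness states are bit vectors, one bit per AOI (1 = the
# operator is conscious of that AOI's current information). Internally a
# state is an integer code in 0..2^n-1 with the FIRST declared AOI as the
# most significant bit, so code 0 is the fully unaware state and the
# enumeration order matches reading the bit vector left to right.

MAX_ENUM_AOI <- 12L # dense tabular enumeration guard (2^12 states)
MAX_SCALAR_AOI <- 20L # scalar bit-vector operations guard

check_enum_guard <- function(n, limit = MAX_ENUM_AOI) {
  if (n > limit) {
    rlang::abort(
      sprintf(
        "state space with %d AOIs (2^%d states) exceeds the enumeration guard (n <= %d)",
        n, n, limit
      ),
      class = "gazemdp_error_capacity"
    )
  }
  invisible(n)
}

bit_weights <- function(n) 2^((n - 1):0)

# integer code -> 0/1 matrix (one row per code), first AOI = MSB
codes_to_bits <- function(code, n) {
  m <- vapply(
    seq_len(n),
    \(k) bitwAnd(code %/% 2^(n - k), 1L),
    integer(length(code))
  )
  matrix(m, nrow = length(code), ncol = n)
}

bits_to_code <- function(bits) {
  bits <- rbind(bits)
  as.integer(bits %*% bit_weights(ncol(bits)))
}

check_bits <- function(bits, spec, what = "state") {
  n <- n_aoi(spec)
  if (length(bits) != n || anyNA(bits) || !all(bits %in% c(0, 1))) {
    rlang::abort(
      sprintf("`%s` must be a 0/1 vector of length %d", what, n),
      class = "gazemdp_error_contract"
    )
  }
  as.integer(bits)
}

check_aoi <- function(aoi, spec) {
  if (is.character(aoi)) {
    idx <- match(aoi, spec$aoi)
    if (is.na(idx)) {
      rlang::abort(paste0("unknown AOI: ", aoi),
        class = "gazemdp_error_contract"
      )
    }
    return(idx)
  }
  aoi <- as.integer(aoi)
  if (length(aoi) != 1 || is.na(aoi) || aoi < 1 || aoi > n_aoi(spec)) {
    rlang::abort("`aoi` must name or index a declared AOI",
      class = "gazemdp_error_contract"
    )
  }
  aoi
}

# integer masks of the covered set {a} U redundancy(a), per action
cover_masks <- function(spec) {
  n <- n_aoi(spec)
  w <- bit_weights(n)
  vapply(seq_len(n), function(a) {
    cov <- match(covered_aois(spec, spec$aoi[a]), spec$aoi)
    as.integer(sum(w[cov]))
  }, integer(1))
}

#' Enumerate all situation-awareness states
#'
#' @param spec A [task_spec()].
#' @return A tibble with `2^n` rows: `state` (bit string such as `"01101"`,
#'   first declared AOI leftmost) and one 0/1 column per AOI.
#' @export
sa_states <- function(spec) {
  n <- n_aoi(spec)
  check_enum_guard(n)
  bits <- codes_to_bits(0:(2^n - 1), n)
  colnames(bits) <- spec$aoi
  dplyr::bind_cols(
    tibble::tibble(state = apply(bits, 1, paste, collapse = "")),
    tibble::as_tibble(bits)
  )
}

format_bits <- function(bits) paste(bits, collapse = "")

#' Probability of one information-update vector
#'
#' During each decision period the information inside AOI `m` updates
#' independently with probability `bandwidth[m]`. The probability of a whole
#' update vector `u` is the product over AOIs of `bandwidth[m]` where
#' `u[m] = 1` and `1 - bandwidth[m]` where `u[m] = 0`.
#'
#' @param spec A [task_spec()].
#' @param update 0/1 vector of length `n_aoi(spec)` (1 = that AOI's
#'   information updated).
#' @return A probability.
#' @examples
#' dsv <- flight_condition("DSV")$spec
#' update_vector_probability(dsv, c(0, 0, 0, 0, 0)) # 0.0281219
#' @export
update_vector_probability <- function(spec, update) {
  stopifnot(inherits(spec, "task_spec"))
  u <- check_bits(update, spec, "update")
  bw <- spec$bandwidth
  prod(ifelse(u == 1, bw, 1 - bw))
}

#' Distribution over all information-update vectors
#'
#' @param spec A [task_spec()].
#' @return A tibble with `2^n` rows: `update` (bit string), one 0/1 column
#'   per AOI, and `prob`. Probabilities sum to 1.
#' @export
update_distribution <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  n <- n_aoi(spec)
  check_enum_guard(n)
  bits <- codes_to_bits(0:(2^n - 1), n)
  bw <- spec$bandwidth
  prob <- apply(bits, 1, \(u) prod(ifelse(u == 1, bw, 1 - bw)))
  colnames(bits) <- spec$aoi
  dplyr::bind_cols(
    tibble::tibble(update = apply(bits, 1, format_bits)),
    tibble::as_tibble(bits),
    tibble::tibble(prob = prob)
  )
}

#' Intermediate state after a fixation
#'
#' Fixating an AOI immediately makes the operator conscious of its
#' information (and, through display redundancy, of every AOI it covers),
#' before the period's random updates land.
#'
#' @param spec A [task_spec()].
#' @param state 0/1 awareness vector.
#' @param aoi Fixated AOI (name or index).
#' @return The intermediate 0/1 awareness vector.
#' @examples
#' dsv <- flight_condition("DSV")$spec
#' intermediate_state(dsv, c(0, 1, 1, 0, 1), "SVS") # 1 1 1 0 1
#' @export
intermediate_state <- function(spec, state, aoi) {
  stopifnot(inherits(spec, "task_spec"))
  s <- check_bits(state, spec)
  a <- check_aoi(aoi, spec)
  cov <- match(covered_aois(spec, spec$aoi[a]), spec$aoi)
  s[cov] <- 1L
  s
}

#' Apply an information update to an intermediate state
#'
#' An update of AOI `m` makes its previous information stale: the awareness
#' bit drops to 0 unless `m` is the fixated AOI or covered by it, which is
#' monitored throughout the period and therefore stays known.
#'
#' @param spec A [task_spec()].
#' @param intermediate Intermediate 0/1 awareness vector (see
#'   [intermediate_state()]).
#' @param aoi Fixated AOI (name or index).
#' @param update 0/1 information-update vector for the period.
#' @return The awareness vector at the next decision point.
#' @export
apply_update <- function(spec, intermediate, aoi, update) {
  stopifnot(inherits(spec, "task_spec"))
  inter <- check_bits(intermediate, spec, "intermediate")
  u <- check_bits(update, spec, "update")
  a <- check_aoi(aoi, spec)
  cov <- match(covered_aois(spec, spec$aoi[a]), spec$aoi)
  out <- inter
  out[u == 1L] <- 0L
  out[cov] <- 1L
  out
}

#' Transition probability between situation-awareness states
#'
#' Sums [update_vector_probability()] over every update vector that carries
#' the post-fixation intermediate state to `next_state`.
#'
#' @param spec A [task_spec()].
#' @param state Current 0/1 awareness vector.
#' @param aoi Fixated AOI (name or index).
#' @param next_state Candidate next 0/1 awareness vector.
#' @return A probability (0 when `next_state` is unreachable).
#' @examples
#' dsv <- flight_condition("DSV")$spec
#' transition_probability(dsv, c(0, 1, 1, 0, 1), "SVS", c(1, 0, 1, 0, 1))
#' @export
transition_probability <- function(spec, state, aoi, next_state) {
  stopifnot(inherits(spec, "task_spec"))
  n <- n_aoi(spec)
  if (n > MAX_SCALAR_AOI) check_enum_guard(n, MAX_SCALAR_AOI)
  s <- check_bits(state, spec)
  s_next <- check_bits(next_state, spec, "next_state")
  a <- check_aoi(aoi, spec)
  cov_mask <- cover_masks(spec)[a]
  dist <- next_state_distribution(
    spec, bits_to_code(s), a, cov_mask
  )
  p <- dist[match(bits_to_code(s_next), dist$code), "prob"]
  if (is.na(p)) 0 else as.numeric(p)
}

# distribution over next-state codes from one (state code, action);
# enumerates update vectors restricted to non-covered AOIs (covered AOIs'
# updates never change the outcome, so their probability marginalises out)
next_state_distribution <- function(spec, s_code, a, cov_mask) {
  n <- n_aoi(spec)
  inter <- bitwOr(s_code, cov_mask)
  free <- which(bitwAnd(cov_mask %/% 2^(n - seq_len(n)), 1L) == 0L)
  bw <- unname(spec$bandwidth)
  if (length(free) == 0) {
    return(data.frame(code = inter, prob = 1))
  }
  w <- bit_weights(n)
  fbits <- codes_to_bits(0:(2^length(free) - 1), length(free))
  # update code restricted to free AOIs
  u_code <- as.integer(fbits %*% w[free])
  p <- apply(fbits, 1, \(u) prod(ifelse(u == 1, bw[free], 1 - bw[free])))
  nxt <- bitwOr(bitwAnd(inter, bitwNot(u_code)), cov_mask)
  agg <- rowsum(p, nxt)
  out <- data.frame(code = as.integer(rownames(agg)), prob = as.numeric(agg))
  out[out$prob > 0, , drop = FALSE]
}

#' Full transition table
#'
#' Enumerates the transition distribution for every (state, action) pair.
#' For `n` AOIs this is the `2^n x 2^n x n` transition array of the MDP,
#' reported sparsely (zero-probability transitions are omitted).
#'
#' @param spec A [task_spec()].
#' @return A tibble with columns `state`, `action`, `next_state`
#'   (bit strings) and `prob`. Each (state, action) group sums to 1.
#' @export
transition_table <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  n <- n_aoi(spec)
  check_enum_guard(n)
  cm <- cover_masks(spec)
  states <- 0:(2^n - 1)
  fmt <- function(code) {
    apply(codes_to_bits(code, n), 1, format_bits)
  }
  rows <- purrr::map(seq_len(n), function(a) {
    purrr::map(states, function(s) {
      d <- next_state_distribution(spec, s, a, cm[a])
      tibble::tibble(
        state = fmt(s), action = spec$aoi[a],
        next_state = fmt(d$code), prob = d$prob
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  dplyr::arrange(
    rows,
    .data$state, match(.data$action, spec$aoi), .data$next_state
  )
}

# dense S x S transition matrix for one action (rows = current state code+1)
transition_matrix <- function(spec, a) {
  n <- n_aoi(spec)
  S <- 2^n
  cm <- cover_masks(spec)[a]
  P <- matrix(0, S, S)
  for (s in 0:(S - 1)) {
    d <- next_state_distribution(spec, s, a, cm)
    P[s + 1, d$code + 1] <- d$prob
  }
  P
}

#' Reward for fixating an AOI
#'
#' The situation-awareness reward of a fixation is the value of the
#' information gained: the sum over subtasks of subtask value times
#' subtask-AOI relevance, collected only when the operator is currently
#' unaware of that AOI's information (otherwise nothing new is learned and
#' the reward is 0). The reward is stage-independent.
#'
#' @param spec A [task_spec()].
#' @param state Current 0/1 awareness vector.
#' @param aoi Fixated AOI (name or index).
#' @return A non-negative number.
#' @examples
#' dsv <- flight_condition("DSV")$spec
#' reward(dsv, c(0, 0, 0, 0, 0), "IP") # 3.5
#' @export
reward <- function(spec, state, aoi) {
  stopifnot(inherits(spec, "task_spec"))
  s <- check_bits(state, spec)
  a <- check_aoi(aoi, spec)
  if (s[a] == 1L) {
    return(0)
  }
  sum(spec$subtasks$value * spec$relevance[, a])
}

# S x n matrix of rewards (rows = state code + 1)
reward_matrix <- function(spec) {
  n <- n_aoi(spec)
  S <- 2^n
  aoi_value <- as.numeric(spec$subtasks$value %*% spec$relevance)
  bits <- codes_to_bits(0:(S - 1), n)
  # reward only while the fixated AOI's bit is 0
  (1 - bits) * rep(aoi_value, each = S)
}

#' Full reward table
#'
#' @param spec A [task_spec()].
#' @return A tibble with columns `state`, `action`, `reward`, one row per
#'   (state, action) pair.
#' @export
reward_table <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  n <- n_aoi(spec)
  check_enum_guard(n)
  R <- reward_matrix(spec)
  st <- sa_states(spec)$state
  tidyr::expand_grid(state = st, action = spec$aoi) |>
    dplyr::mutate(
      reward = R[cbind(
        match(.data$state, st),
        match(.data$action, spec$aoi)
      )]
    )
}
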