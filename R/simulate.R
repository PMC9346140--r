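#' Sample information-update vectors
#'
#' Draws update vectors for one decision period: each AOI updates
#' independently with its bandwidth probability. Uses the current R random
#' stream; call `set.seed()` (or pass `seed` to the simulation wrappers)
#' for reproducibility.
#'
#' @param spec A [task_spec()].
#' @param n Number of vectors to draw.
#' @return An `n x n_aoi(spec)` 0/1 integer matrix with AOI column names.
#' @export
sample_update <- function(spec, n = 1) {
  stopifnot(inherits(spec, "task_spec"))
  k <- n_aoi(spec)
  m <- matrix(
    stats::rbinom(n * k, 1L, rep(spec$bandwidth, each = n)),
    nrow = n, ncol = k, dimnames = list(NULL, spec$aoi)
  )
  m
}

# vectorized one-period state step on integer codes
step_codes <- function(s_code, cov_mask, u_code) {
  inter <- bitwOr(s_code, cov_mask)
  bitwOr(bitwAnd(inter, bitwNot(bitwAnd(u_code, bitwNot(cov_mask)))), cov_mask)
}

#' Simulate one fixation sequence (scanpath)
#'
#' Rolls the task forward from an initial awareness state under a fixation
#' policy: at each decision moment the policy picks the AOI to fixate, the
#' fixation (and display redundancy) makes the covered information known,
#' and the period's random updates then knock out awareness of the AOIs
#' that changed.
#'
#' @param spec A [task_spec()].
#' @param policy An [sa_policy][solve_policy()] for this spec.
#' @param s0 Initial 0/1 awareness vector (default: fully unaware).
#' @param seed Integer seed; the sequence is fully reproducible from it.
#' @return An object of class `sa_scanpath`: a tibble with one row per
#'   decision moment `0..horizon-1` and columns `moment`, `aoi` (fixated
#'   AOI), `state` (awareness bit string *before* the fixation), `update`
#'   (bit string of the period's information updates) and `reward`
#'   (immediate reward collected). The awareness state after the final
#'   period is in `attr(, "final_state")`; the seed and spec ride along as
#'   attributes.
#' @examples
#' dsv <- flight_condition("DSV")
#' pol <- solve_policy(dsv$spec, horizon = 20)
#' path <- simulate_scanpath(dsv$spec, pol, seed = 1)
#' head(path)
#' @export
simulate_scanpath <- function(spec, policy, s0 = NULL, seed = 1L) {
  stopifnot(inherits(spec, "task_spec"), inherits(policy, "sa_policy"))
  n <- n_aoi(spec)
  N <- policy$horizon
  s0 <- if (is.null(s0)) integer(n) else check_bits(s0, spec, "s0")
  cm <- cover_masks(spec)
  R <- reward_matrix(spec)
  w <- bit_weights(n)

  set.seed(seed)
  s <- bits_to_code(s0)
  actions <- integer(N)
  states <- integer(N)
  updates <- integer(N)
  rewards <- numeric(N)
  for (t in seq_len(N)) {
    a <- policy$rules[s + 1L, t]
    u <- as.integer(sample_update(spec) %*% w)
    states[t] <- s
    actions[t] <- a
    updates[t] <- u
    rewards[t] <- R[s + 1L, a]
    s <- step_codes(s, cm[a], u)
  }
  out <- tibble::tibble(
    moment = 0:(N - 1),
    aoi = spec$aoi[actions],
    state = apply(codes_to_bits(states, n), 1, format_bits),
    update = apply(codes_to_bits(updates, n), 1, format_bits),
    reward = rewards
  )
  structure(out,
    class = c("sa_scanpath", class(out)),
    spec = spec, seed = seed,
    final_state = as.integer(codes_to_bits(s, n))
  )
}

#' Simulate a batch of fixation sequences
#'
#' Generates many independent scanpaths under one policy, vectorized across
#' replications. Only the fixation choices and total rewards are kept,
#' which is what the validation statistics need; use [simulate_scanpath()]
#' for a single fully traced sequence.
#'
#' @inheritParams simulate_scanpath
#' @param n_seq Number of independent sequences.
#' @return An object of class `sa_scanpath_set`: a list with `actions`
#'   (`n_seq x horizon` integer matrix of fixated AOI indices),
#'   `total_reward` (length-`n_seq` numeric), the `spec`, the policy
#'   `kind`, and the `seed`.
#' @export
simulate_scanpaths <- function(spec, policy, n_seq = 1000, s0 = NULL,
                               seed = 1L) {
  stopifnot(inherits(spec, "task_spec"), inherits(policy, "sa_policy"))
  n <- n_aoi(spec)
  N <- policy$horizon
  n_seq <- as.integer(n_seq)
  if (is.na(n_seq) || n_seq < 1) {
    rlang::abort("`n_seq` must be >= 1", class = "gazemdp_error_contract")
  }
  s0 <- if (is.null(s0)) integer(n) else check_bits(s0, spec, "s0")
  cm <- cover_masks(spec)
  R <- reward_matrix(spec)
  w <- bit_weights(n)

  set.seed(seed)
  s <- rep(bits_to_code(s0), n_seq)
  actions <- matrix(0L, n_seq, N)
  total <- numeric(n_seq)
  for (t in seq_len(N)) {
    a <- policy$rules[s + 1L, t]
    u <- as.integer(sample_update(spec, n_seq) %*% w)
    actions[, t] <- a
    total <- total + R[cbind(s + 1L, a)]
    s <- step_codes(s, cm[a], u)
  }
  structure(
    list(
      actions = actions, total_reward = total,
      spec = spec, kind = policy$kind, seed = seed
    ),
    class = "sa_scanpath_set"
  )
}

#' @export
print.sa_scanpath_set <- function(x, ...) {
  cat("<sa_scanpath_set> ", nrow(x$actions), " sequences x ",
    ncol(x$actions), " moments (", x$spec$name, ", ", x$kind,
    " policy, seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Delay-to-notice records of a scanpath
#'
#' An information update in an AOI that is not covered by the concurrent
#' fixation leaves the operator unaware until a later fixation covers that
#' AOI again. The delay to notice is the number of decision periods from
#' the update to that fixation, times the period duration. Updates of the
#' currently fixated (or covered) AOI are observed immediately and generate
#' no record. If the same AOI updates again before being noticed, the
#' earlier record is closed as superseded at the later update, so at most
#' one interval per AOI is open at a time; intervals still open at the
#' horizon are censored.
#'
#' @param scanpath An [sa_scanpath][simulate_scanpath()].
#' @return A tibble with columns `aoi`, `update_stage` (period index of the
#'   update), `noticed_moment` (decision moment of the covering fixation;
#'   `NA` for censored records), `delay_s`, and `status` (`"noticed"`,
#'   `"superseded"` or `"censored"`).
#' @export
delay_records <- function(scanpath) {
  stopifnot(inherits(scanpath, "sa_scanpath"))
  spec <- attr(scanpath, "spec")
  n <- n_aoi(spec)
  N <- nrow(scanpath)
  acts <- match(scanpath$aoi, spec$aoi)
  upd <- do.call(rbind, lapply(
    strsplit(scanpath$update, ""),
    as.integer
  ))
  covers <- lapply(seq_len(n), \(a) {
    match(covered_aois(spec, spec$aoi[a]), spec$aoi)
  })

  open <- rep(NA_integer_, n) # update stage of the open interval, per AOI
  rec <- list()
  emit <- function(m, stage, moment, status) {
    rec[[length(rec) + 1]] <<- tibble::tibble(
      aoi = spec$aoi[m], update_stage = stage,
      noticed_moment = moment,
      delay_s = if (is.na(moment)) NA_real_ else (moment - stage) * spec$period_s,
      status = status
    )
  }
  for (t in seq_len(N)) { # decision moment t - 1, period t - 1
    cov <- covers[[acts[t]]]
    # a fixation at this moment notices any open interval it covers
    for (m in intersect(cov, which(!is.na(open)))) {
      emit(m, open[m], t - 1L, "noticed")
      open[m] <- NA_integer_
    }
    # updates landing during this period open (or supersede) intervals,
    # except in AOIs covered by the concurrent fixation
    for (m in setdiff(which(upd[t, ] == 1L), cov)) {
      if (!is.na(open[m])) emit(m, open[m], t - 1L, "superseded")
      open[m] <- t - 1L
    }
  }
  for (m in which(!is.na(open))) emit(m, open[m], NA_integer_, "censored")
  if (!length(rec)) {
    return(tibble::tibble(
      aoi = character(), update_stage = integer(),
      noticed_moment = integer(), delay_s = numeric(), status = character()
    ))
  }
  purrr::list_rbind(rec) |>
    dplyr::arrange(.data$update_stage, .data$aoi)
}
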