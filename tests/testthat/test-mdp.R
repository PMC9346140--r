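
test_that("update-vector probabilities are Bernoulli products", {
  dsv <- flight_condition("DSV")$spec
  expect_equal(
    update_vector_probability(dsv, c(0, 0, 0, 0, 0)), 0.0281219,
    tolerance = 1e-9
  )
  expect_equal(
    update_vector_probability(dsv, c(1, 1, 0, 0, 0)), 0.1956069,
    tolerance = 1e-9
  )
  dist <- update_distribution(dsv)
  expect_equal(
    dist$prob[match(names(dsv_update_probs), dist$update)],
    unname(dsv_update_probs),
    tolerance = 1e-9
  )
  expect_equal(sum(dist$prob), 1, tolerance = 1e-12)

  # degenerate product: nothing ever updates
  frozen <- toy_spec(bw = c(A = 0, B = 0))
  expect_equal(update_vector_probability(frozen, c(0, 0)), 1)
  expect_equal(update_vector_probability(frozen, c(1, 0)), 0)

  expect_error(
    update_vector_probability(dsv, c(0, 1)),
    class = "gazemdp_error_contract"
  )
})

test_that("update distributions normalize for random specs", {
  set.seed(41)
  for (i in 1:5) {
    spec <- random_spec(sample(1:4, 1))
    expect_equal(sum(update_distribution(spec)$prob), 1, tolerance = 1e-12)
  }
})

test_that("fixation yields the intermediate state, redundancy included", {
  dsv <- flight_condition("DSV")$spec
  expect_equal(
    intermediate_state(dsv, c(0, 1, 1, 0, 1), "SVS"),
    c(1L, 1L, 1L, 0L, 1L)
  )
  expect_equal(
    intermediate_state(dsv, rep(1, 5), "ND"),
    rep(1L, 5)
  )
  tsv <- flight_condition("TSV")$spec
  expect_equal(
    intermediate_state(tsv, c(0, 0, 0, 0, 0), "SVS"),
    c(1L, 1L, 0L, 0L, 0L)
  )
  # but not vice versa: fixating IP does not cover the SVS
  expect_equal(
    intermediate_state(tsv, c(0, 0, 0, 0, 0), "IP"),
    c(0L, 1L, 0L, 0L, 0L)
  )
})

test_that("updates knock out awareness except where monitored", {
  dsv <- flight_condition("DSV")$spec
  expect_equal(
    apply_update(dsv, c(1, 1, 1, 0, 1), "SVS", c(1, 1, 0, 0, 0)),
    c(1L, 0L, 1L, 0L, 1L)
  )
  expect_equal(
    apply_update(dsv, c(1, 1, 1, 0, 1), "SVS", c(0, 0, 0, 0, 0)),
    c(1L, 1L, 1L, 0L, 1L)
  )
  # the fixated AOI stays known through its own update
  expect_equal(
    apply_update(dsv, c(1, 0, 0, 0, 0), "SVS", c(1, 0, 0, 0, 0)),
    c(1L, 0L, 0L, 0L, 0L)
  )
  # covered AOIs inherit the continuously-monitored rule
  tsv <- flight_condition("TSV")$spec
  expect_equal(
    apply_update(tsv, c(1, 1, 0, 0, 0), "SVS", c(0, 1, 0, 0, 0)),
    c(1L, 1L, 0L, 0L, 0L)
  )
})

test_that("transition probabilities sum update vectors reaching the state", {
  dsv <- flight_condition("DSV")$spec
  s <- c(0, 1, 1, 0, 1)
  # one full row of the DSV transition array at the printed precision
  row <- list(
    c(1, 0, 0, 0, 0) ~ 0.0729, c(1, 0, 0, 0, 1) ~ 0.0729,
    c(1, 0, 1, 0, 0) ~ 0.3321, c(1, 0, 1, 0, 1) ~ 0.3321,
    c(1, 1, 0, 0, 0) ~ 0.0171, c(1, 1, 0, 0, 1) ~ 0.0171,
    c(1, 1, 1, 0, 0) ~ 0.0779, c(1, 1, 1, 0, 1) ~ 0.0779
  )
  for (f in row) {
    expect_equal(
      transition_probability(dsv, s, "SVS", eval(f[[2]])),
      eval(f[[3]]),
      tolerance = 1e-9
    )
  }
  # unreachable: an unknown, un-updated AOI cannot become known
  expect_equal(transition_probability(dsv, s, "SVS", c(1, 0, 0, 1, 0)), 0)
  # law of total probability over the full table
  tab <- transition_table(dsv)
  sums <- tab |>
    dplyr::summarise(p = sum(.data$prob), .by = c("state", "action"))
  expect_equal(sums$p, rep(1, 32 * 5), tolerance = 1e-12)
  expect_equal(nrow(sums), 32 * 5)
  # absorption: the fixated AOI is always known in the next state
  a_pos <- match(tab$action, dsv$aoi)
  expect_true(all(substr(tab$next_state, a_pos, a_pos) == "1"))
})

test_that("transition tables match the plain-loop enumeration oracle", {
  set.seed(99)
  for (i in 1:3) {
    spec <- random_spec(3)
    tab <- transition_table(spec)
    for (s_str in c("000", "101", "110")) {
      s <- as.integer(strsplit(s_str, "")[[1]])
      for (a in seq_len(3)) {
        oracle <- oracle_transitions(spec, s, a)
        got <- tab |>
          dplyr::filter(.data$state == s_str, .data$action == spec$aoi[a])
        expect_setequal(got$next_state, names(oracle))
        expect_equal(
          got$prob,
          unlist(oracle[got$next_state], use.names = FALSE),
          tolerance = 1e-12
        )
      }
    }
  }
  # redundancy-aware: covered AOI held known in every reachable next state
  tsv <- flight_condition("TSV")$spec
  tab <- transition_table(tsv) |> dplyr::filter(.data$action == "SVS")
  expect_true(all(substr(tab$next_state, 1, 2) == "11"))
})

test_that("zero bandwidth makes transitions deterministic", {
  frozen <- toy_spec(bw = c(A = 0, B = 0, C = 0), values = c(1L, 1L))
  tab <- transition_table(frozen)
  expect_true(all(tab$prob == 1))
  got <- tab |> dplyr::filter(.data$state == "010", .data$action == "A")
  expect_equal(got$next_state, "110")
  # single AOI: always known after fixation
  one <- toy_spec(bw = c(A = 0.3), values = 1L)
  t1 <- transition_table(one)
  expect_equal(nrow(t1), 2)
  expect_true(all(t1$next_state == "1"))
})

test_that("rewards follow value x relevance on unknown AOIs only", {
  dsv <- flight_condition("DSV")$spec
  # aoi values implied by subtask values 3/2/1 and the relevance table
  value <- c(SVS = 4, IP = 3.5, ND = 2.5, DL = 2, OW = 0.5)
  expect_equal(reward(dsv, c(0, 0, 0, 0, 0), "IP"), 3.5)
  expect_equal(reward(dsv, c(1, 1, 0, 0, 0), "ND"), 2.5)
  tab <- reward_table(dsv)
  bits_of <- function(st, k) as.integer(substr(st, k, k))
  expected <- (1 - bits_of(tab$state, match(tab$action, dsv$aoi))) *
    value[tab$action]
  expect_equal(tab$reward, unname(expected))
  # aware branch is always 0, whatever the rest of the state
  for (a in dsv$aoi) {
    s <- as.integer(runif(5) < 0.5)
    s[match(a, dsv$aoi)] <- 1L
    expect_equal(reward(dsv, s, a), 0)
  }
  # bounds: never negative, never above the total subtask value
  expect_true(all(tab$reward >= 0 & tab$reward <= sum(dsv$subtasks$value)))
  expect_true(all(tab$reward[tab$state == "11111"] == 0))
})

test_that("the enumeration guard rejects oversized state spaces", {
  bw <- stats::setNames(rep(0.1, 13), paste0("A", 1:13))
  rel <- matrix(1, 1, 13, dimnames = list("t", names(bw)))
  big <- task_spec(
    aoi = names(bw), bandwidth = bw,
    subtasks = data.frame(name = "t", value = 1L),
    relevance = rel, horizon = 2, period_s = 0.5
  )
  expect_error(transition_table(big), class = "gazemdp_error_capacity")
  expect_error(solve_policy(big), class = "gazemdp_error_capacity")
})
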