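test_that("update sampling follows the bandwidths", {
  frozen <- toy_spec(bw = c(A = 0, B = 0))
  set.seed(1)
  expect_true(all(sample_update(frozen, 50) == 0L))
  sure <- toy_spec(bw = c(A = 1, B = 0))
  set.seed(1)
  u <- sample_update(sure, 50)
  expect_true(all(u[, "A"] == 1L) && all(u[, "B"] == 0L))

  # DSV: empirical frequency of the no-update vector ~ its exact probability
  dsv <- flight_condition("DSV")$spec
  set.seed(123)
  draws <- sample_update(dsv, 1e5)
  f <- mean(rowSums(draws) == 0)
  expect_equal(f, 0.0281219, tolerance = 0.002 / 0.0281219)
})

test_that("scanpaths are reproducible and internally consistent", {
  spec <- flight_condition("TSV")$spec
  pol <- solve_policy(spec, horizon = 40, keep_q = FALSE)
  p1 <- simulate_scanpath(spec, pol, seed = 11)
  p2 <- simulate_scanpath(spec, pol, seed = 11)
  expect_identical(tibble::as_tibble(p1), tibble::as_tibble(p2))
  p3 <- simulate_scanpath(spec, pol, seed = 12)
  expect_false(identical(p1$update, p3$update))

  # every recorded transition replays through the one-period dynamics, and
  # every action matches the policy rule for the recorded state
  s <- integer(5)
  for (t in seq_len(nrow(p1))) {
    expect_equal(paste(s, collapse = ""), p1$state[t])
    a <- match(p1$aoi[t], spec$aoi)
    expect_equal(spec$aoi[pol$rules[sum(s * 2^(4:0)) + 1, t]], p1$aoi[t])
    u <- as.integer(strsplit(p1$update[t], "")[[1]])
    expect_equal(p1$reward[t], reward(spec, s, p1$aoi[t]))
    s <- oracle_next_state(spec, s, a, u)
  }
  expect_equal(attr(p1, "final_state"), s)
})

test_that("batch simulation agrees with the single-path generator", {
  spec <- flight_condition("DSV")$spec
  pol <- solve_policy(spec, horizon = 30, keep_q = FALSE)
  single <- simulate_scanpath(spec, pol, seed = 4)
  batch <- simulate_scanpaths(spec, pol, n_seq = 1, seed = 4)
  expect_equal(spec$aoi[batch$actions[1, ]], single$aoi)
  expect_equal(batch$total_reward, sum(single$reward))
})

test_that("without information updates every AOI pays out exactly once", {
  frozen <- toy_spec(
    bw = c(A = 0, B = 0, C = 0),
    values = c(2L, 1L),
    rel = matrix(c(1, 0.5, 0, 0.5, 1, 1), 2, 3,
      byrow = TRUE, dimnames = list(c("task1", "task2"), c("A", "B", "C"))
    ),
    horizon = 6
  )
  pol <- solve_policy(frozen)
  path <- simulate_scanpath(frozen, pol, seed = 1)
  empty_rewards <- vapply(
    frozen$aoi,
    \(a) reward(frozen, c(0, 0, 0), a),
    numeric(1)
  )
  expect_equal(sum(path$reward), sum(empty_rewards))
})

test_that("DSV scanpaths start by fixating the SVS from full unawareness", {
  spec <- flight_condition("DSV")$spec
  pol <- solve_policy(spec, keep_q = FALSE)
  path <- simulate_scanpath(spec, pol, seed = 3)
  expect_equal(nrow(path), 960)
  expect_equal(path$aoi[1], "SVS")
  expect_equal(path$state[1], "00000")
})

test_that("per-period reward estimates tighten with more replications", {
  spec <- flight_condition("DSV")$spec
  pol <- solve_policy(spec, horizon = 60, keep_q = FALSE)
  means <- function(n, seed) {
    mean(simulate_scanpaths(spec, pol, n_seq = n, seed = seed)$total_reward)
  }
  small <- vapply(1:8, \(s) means(10, s), numeric(1))
  large <- vapply(1:8, \(s) means(160, 100 + s), numeric(1))
  expect_lt(stats::sd(large), stats::sd(small))
})

test_that("delay extraction reproduces the worked raster example", {
  spec <- flight_condition("DSV")$spec
  n <- 5
  no_upd <- rep(list(integer(n)), 8)
  upd <- no_upd
  # ND (third AOI) updates during stage 3; first ND fixation at moment 6
  upd[[4]] <- c(0L, 0L, 1L, 0L, 0L) # period index 3 (moments are 0-based)
  acts <- c("SVS", "IP", "SVS", "IP", "SVS", "IP", "ND", "SVS")
  path <- make_scanpath(spec, acts, upd)
  rec <- delay_records(path)
  nd <- rec[rec$aoi == "ND", ]
  expect_equal(nd$update_stage, 3L)
  expect_equal(nd$noticed_moment, 6L)
  expect_equal(nd$delay_s, 1.5)
  expect_equal(nd$status, "noticed")
})

test_that("delay records handle monitored, superseded and censored updates", {
  spec <- flight_condition("DSV")$spec
  n <- 5
  mk <- function(acts, upd) delay_records(make_scanpath(spec, acts, upd))

  # update of the fixated AOI: observed live, no record
  upd <- rep(list(integer(n)), 3)
  upd[[2]] <- c(1L, 0L, 0L, 0L, 0L)
  rec <- mk(c("SVS", "SVS", "SVS"), upd)
  expect_equal(nrow(rec), 0)

  # update of a covered AOI is likewise monitored (tunnel-separate display)
  tsv <- flight_condition("TSV")$spec
  upd2 <- rep(list(integer(n)), 2)
  upd2[[1]] <- c(0L, 1L, 0L, 0L, 0L)
  rec2 <- delay_records(make_scanpath(tsv, c("SVS", "SVS"), upd2))
  expect_equal(nrow(rec2), 0)

  # never refixated before the horizon: censored, delay undefined
  upd3 <- rep(list(integer(n)), 3)
  upd3[[1]] <- c(0L, 0L, 1L, 0L, 0L)
  rec3 <- mk(c("SVS", "IP", "SVS"), upd3)
  expect_equal(rec3$status, "censored")
  expect_true(is.na(rec3$delay_s))

  # a second update before noticing closes the first interval
  upd4 <- rep(list(integer(n)), 6)
  upd4[[2]] <- c(0L, 0L, 1L, 0L, 0L)
  upd4[[4]] <- c(0L, 0L, 1L, 0L, 0L)
  rec4 <- mk(c("SVS", "IP", "SVS", "IP", "ND", "SVS"), upd4)
  nd4 <- rec4[rec4$aoi == "ND", ]
  expect_equal(nd4$status, c("superseded", "noticed"))
  expect_equal(nd4$update_stage, c(1L, 3L))
  expect_equal(nd4$noticed_moment, c(3L, 4L))
  expect_equal(nd4$delay_s, c(1, 0.5))

  # delays from simulated paths are never negative; censoring only at the end
  pol <- solve_policy(spec, horizon = 50, keep_q = FALSE)
  sim_rec <- delay_records(simulate_scanpath(spec, pol, seed = 9))
  expect_true(all(sim_rec$delay_s[sim_rec$status != "censored"] >= 0))
  cens <- sim_rec[sim_rec$status == "censored", ]
  open_after <- vapply(
    cens$update_stage,
    \(st) any(sim_rec$noticed_moment > st & sim_rec$aoi == cens$aoi[
      cens$update_stage == st
    ] & sim_rec$status == "noticed"),
    logical(1)
  )
  expect_false(any(open_after))
})
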