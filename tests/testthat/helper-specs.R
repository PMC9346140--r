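# small task specs and an independent plain-loop oracle used across tests

toy_spec <- function(bw = c(A = 0.3, B = 0.6), values = c(2L, 1L),
                     rel = NULL, redundancy = list(), horizon = 5,
                     name = "toy") {
  aoi <- names(bw)
  subtasks <- data.frame(
    name = paste0("task", seq_along(values)),
    value = values
  )
  if (is.null(rel)) {
    rel <- matrix(1, length(values), length(aoi),
      dimnames = list(subtasks$name, aoi)
    )
  }
  task_spec(
    aoi = aoi, bandwidth = bw, subtasks = subtasks, relevance = rel,
    redundancy = redundancy, horizon = horizon, period_s = 0.5, name = name
  )
}

random_spec <- function(n, horizon = 3) {
  aoi <- LETTERS[seq_len(n)]
  rel <- matrix(round(stats::runif(2 * n), 2), 2, n,
    dimnames = list(c("task1", "task2"), aoi)
  )
  toy_spec(
    bw = stats::setNames(round(stats::runif(n), 2), aoi),
    values = c(3L, 1L), rel = rel, horizon = horizon,
    name = paste0("rand", n)
  )
}

# plain-loop oracle for one-period dynamics, independent of the bit-twiddling
# code path in the package
oracle_next_state <- function(spec, s, a_idx, u) {
  cov <- match(union(spec$aoi[a_idx], spec$redundancy[[spec$aoi[a_idx]]]),
    spec$aoi
  )
  inter <- s
  inter[cov] <- 1L
  nxt <- inter
  for (m in seq_along(s)) {
    if (m %in% cov) {
      nxt[m] <- 1L
    } else if (u[m] == 1) nxt[m] <- 0L
  }
  nxt
}

oracle_update_prob <- function(spec, u) {
  p <- 1
  for (m in seq_along(u)) {
    bw <- spec$bandwidth[[spec$aoi[m]]]
    p <- p * if (u[m] == 1) bw else 1 - bw
  }
  p
}

# exhaustive transition distribution by looping over all update vectors
oracle_transitions <- function(spec, s, a_idx) {
  n <- length(spec$aoi)
  out <- new.env()
  for (code in 0:(2^n - 1)) {
    u <- as.integer(intToBits(code))[n:1] # first AOI most significant
    nxt <- paste(oracle_next_state(spec, s, a_idx, u), collapse = "")
    p <- oracle_update_prob(spec, u)
    out[[nxt]] <- (if (is.null(out[[nxt]])) 0 else out[[nxt]]) + p
  }
  as.list(out)
}

# brute-force optimal expected total reward by expectimax recursion over raw
# bit vectors (independent of the solver's matrix formulation)
oracle_value <- function(spec, s, t, N) {
  if (t >= N) {
    return(0)
  }
  n <- length(spec$aoi)
  best <- -Inf
  for (a in seq_len(n)) {
    q <- reward(spec, s, spec$aoi[a])
    for (code in 0:(2^n - 1)) {
      u <- as.integer(intToBits(code))[n:1]
      p <- oracle_update_prob(spec, u)
      if (p > 0) {
        q <- q + p * oracle_value(spec, oracle_next_state(spec, s, a, u), t + 1, N)
      }
    }
    best <- max(best, q)
  }
  best
}

# rebuild a scanpath object from explicit action/update traces (for delay
# tests with hand-constructed histories)
make_scanpath <- function(spec, actions, updates, s0 = NULL) {
  n <- length(spec$aoi)
  s <- if (is.null(s0)) integer(n) else as.integer(s0)
  states <- character(length(actions))
  for (t in seq_along(actions)) {
    states[t] <- paste(s, collapse = "")
    a <- match(actions[t], spec$aoi)
    s <- oracle_next_state(spec, s, a, updates[[t]])
  }
  out <- tibble::tibble(
    moment = seq_along(actions) - 1L,
    aoi = actions,
    state = states,
    update = vapply(updates, paste, "", collapse = ""),
    reward = NA_real_
  )
  structure(out,
    class = c("sa_scanpath", class(out)),
    spec = spec, seed = NA_integer_, final_state = s
  )
}

condition_codes <- c("TOV", "TOI", "TSV", "TSI", "DOV", "DOI", "DSV", "DSI")

# Frozen DSV update-vector distribution (bandwidths 0.62/0.81/0.18/0.05/0.50;
# probability of vector u is the product of bw or 1-bw per AOI). Values match
# hand products exactly at the printed 7-decimal precision.
dsv_update_probs <- c(
  "00000" = 0.0281219, "00001" = 0.0281219,
  "00010" = 0.0014801, "00011" = 0.0014801,
  "00100" = 0.0061731, "00101" = 0.0061731,
  "00110" = 0.0003249, "00111" = 0.0003249,
  "01000" = 0.1198881, "01001" = 0.1198881,
  "01010" = 0.0063099, "01011" = 0.0063099,
  "01100" = 0.0263169, "01101" = 0.0263169,
  "01110" = 0.0013851, "01111" = 0.0013851,
  "10000" = 0.0458831, "10001" = 0.0458831,
  "10010" = 0.0024149, "10011" = 0.0024149,
  "10100" = 0.0100719, "10101" = 0.0100719,
  "10110" = 0.0005301, "10111" = 0.0005301,
  "11000" = 0.1956069, "11001" = 0.1956069,
  "11010" = 0.0102951, "11011" = 0.0102951,
  "11100" = 0.0429381, "11101" = 0.0429381,
  "11110" = 0.0022599, "11111" = 0.0022599
)
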