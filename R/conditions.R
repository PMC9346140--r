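# The eight flight-display conditions of the simulated curved-approach task:
# Tunnel/Datalink x Overlay/Separate x VMC/IMC. Five AOIs: the synthetic
# vision system (SVS), instrument panel (IP), navigation display (ND),
# datalink box (DL) and the outside world (OW). Subtasks follow the aviation
# priority hierarchy: aviate (3) > navigate (2) > hazard awareness (1).

condition_names <- c("TOV", "TOI", "TSV", "TSI", "DOV", "DOI", "DSV", "DSI")
flight_aois <- c("SVS", "IP", "ND", "DL", "OW")

# Per-period information-update probabilities. IP carries no information in
# the overlay conditions (it sits on the SVS), and the outside world is
# obscured under IMC, so those bandwidths are 0.
condition_bandwidth <- matrix(
  c(
    # TOV   TOI   TSV   TSI   DOV   DOI   DSV   DSI
    0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, 0.62, # SVS
    0.00, 0.00, 0.81, 0.81, 0.00, 0.00, 0.81, 0.81, # IP
    0.18, 0.18, 0.18, 0.18, 0.18, 0.18, 0.18, 0.18, # ND
    0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, 0.05, # DL
    0.50, 0.00, 0.50, 0.00, 0.50, 0.00, 0.50, 0.00 # OW
  ),
  nrow = 5, byrow = TRUE,
  dimnames = list(flight_aois, condition_names)
)

# Relevance of each AOI to each subtask, by condition. Zero rows for IP in
# the overlay conditions (no information there) and for OW to aviate /
# navigate (the outside world serves hazard awareness only, and only when
# visible).
condition_relevance <- local({
  rel <- list()
  for (cond in condition_names) {
    m <- matrix(0, 3, 5, dimnames = list(c("AV", "NAV", "HAZ"), flight_aois))
    tunnel <- substr(cond, 1, 1) == "T"
    separate <- substr(cond, 2, 2) == "S"
    vmc <- substr(cond, 3, 3) == "V"
    m["AV", "SVS"] <- 1
    # the SVS supports navigation through the tunnel or the overlaid panel;
    # only the datalink-separate displays leave it without navigation content
    m["NAV", "SVS"] <- if (tunnel || !separate) 1 else 0
    m["HAZ", "SVS"] <- 1
    if (separate) {
      if (tunnel) {
        m["NAV", "IP"] <- 0.5
      } else {
        m["AV", "IP"] <- 0.5
        m["NAV", "IP"] <- 1
      }
    }
    m["NAV", "ND"] <- if (tunnel) 0.5 else 1
    m["HAZ", "ND"] <- 0.5
    m["NAV", "DL"] <- if (tunnel) 0 else 1
    m["HAZ", "OW"] <- if (vmc) 0.5 else 0
    rel[[cond]] <- m
  }
  rel
})

# Experimentally observed fixation proportions per AOI (two-decimal printed
# values from the flight-simulation study).
condition_observed <- matrix(
  c(
    # TOV   TOI   TSV   TSI   DOV   DOI   DSV   DSI
    0.66, 0.80, 0.68, 0.71, 0.65, 0.68, 0.29, 0.33, # SVS
    0.00, 0.00, 0.05, 0.07, 0.00, 0.00, 0.28, 0.27, # IP
    0.18, 0.14, 0.15, 0.12, 0.17, 0.18, 0.24, 0.26, # ND
    0.03, 0.04, 0.04, 0.04, 0.09, 0.11, 0.11, 0.09, # DL
    0.12, 0.02, 0.07, 0.06, 0.10, 0.03, 0.07, 0.06 # OW
  ),
  nrow = 5, byrow = TRUE,
  dimnames = list(flight_aois, condition_names)
)

#' Built-in flight-display conditions
#'
#' Returns the task specification and the experimentally observed fixation
#' distribution for one of the eight flight-display conditions of the
#' curved-approach simulation study. Condition codes combine `T`unnel vs
#' `D`atalink guidance, `O`verlay vs `S`eparate instrument panel, and
#' `V`MC vs `I`MC (outside world visible vs obscured).
#'
#' In the tunnel-separate conditions (`TSV`, `TSI`) the flight tunnel on the
#' SVS duplicates the instrument panel, so fixating SVS also acquires IP
#' information (`redundancy: SVS -> IP`, one-directional). In the overlay
#' conditions the panel sits on the SVS and its original location carries no
#' information (IP bandwidth and relevance 0).
#'
#' @param name One of `"TOV"`, `"TOI"`, `"TSV"`, `"TSI"`, `"DOV"`, `"DOI"`,
#'   `"DSV"`, `"DSI"`.
#' @return A list with elements `spec` (a [task_spec()] with horizon 960 and
#'   0.5 s decision periods) and `observed` (a tibble with columns `aoi`,
#'   `observed_fixation_prob`).
#' @examples
#' dsv <- flight_condition("DSV")
#' dsv$spec
#' dsv$observed
#' @export
flight_condition <- function(name) {
  if (length(name) != 1 || !name %in% condition_names) {
    rlang::abort(
      paste0(
        "unknown condition ", deparse(name), "; valid names: ",
        paste(condition_names, collapse = ", ")
      ),
      class = "gazemdp_error_lookup"
    )
  }
  tunnel <- substr(name, 1, 1) == "T"
  separate <- substr(name, 2, 2) == "S"
  spec <- task_spec(
    aoi = flight_aois,
    bandwidth = condition_bandwidth[, name],
    subtasks = tibble::tibble(
      name = c("AV", "NAV", "HAZ"),
      value = c(3L, 2L, 1L)
    ),
    relevance = condition_relevance[[name]],
    redundancy = if (tunnel && separate) list(SVS = "IP") else list(),
    horizon = 960L,
    period_s = 0.5,
    name = name
  )
  observed <- tibble::tibble(
    aoi = flight_aois,
    observed_fixation_prob = unname(condition_observed[, name])
  )
  list(spec = spec, observed = observed)
}

#' Observed fixation distributions for all built-in conditions
#'
#' @return A tibble with columns `condition`, `aoi`,
#'   `observed_fixation_prob` (40 rows: 8 conditions x 5 AOIs).
#' @export
observed_fixations <- function() {
  tidyr::expand_grid(
    condition = condition_names,
    aoi = flight_aois
  ) |>
    dplyr::mutate(
      observed_fixation_prob =
        condition_observed[cbind(.data$aoi, .data$condition)]
    )
}
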