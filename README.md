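# gazemdp

Where does an experienced operator look next? In dynamic interactive tasks
— flying an instrument approach, supervising a plant control room — the
display is divided into a handful of areas of interest (AOIs) whose
information changes stochastically, and the operator's *situation awareness*
(SA) is, at its simplest, knowing what is currently shown in each of them.
`gazemdp` models the resulting scanning behavior as a finite-horizon Markov
decision process and is aimed at human-factors researchers who want to
derive, simulate and validate SA-driven gaze policies.

## The model

* **State.** SA is a bit vector $s = (i_1, \dots, i_n)$, one bit per AOI:
  $i_k = 1$ when the operator is conscious of the information in AOI $k$,
  giving $2^n$ states.
* **Action.** A fixation on one AOI for one decision period (0.5 s by
  default). Fixating AOI $k$ immediately sets $i_k = 1$; on displays where
  one AOI duplicates another (e.g. a flight tunnel that renders the
  instrument panel), the covered AOI's bit is set too.
* **Dynamics.** During each period the information in AOI $m$ updates
  independently with probability $BW_m$, its *bandwidth* (the expectancy
  term). An update makes previously acquired information stale, dropping
  $i_m$ to 0 — except in the fixated (and covered) AOIs, which are
  monitored continuously. Transition probabilities are products of
  Bernoulli terms summed over the update vectors that reach the target
  state.
* **Reward.** Fixating AOI $k$ while unaware of it pays
  $r = \sum_{\text{subtask}} V_{\text{subtask}} \cdot rel_{\text{subtask},k}$
  — subtask priority times subtask–AOI relevance (the value term) — and
  pays 0 if the AOI is already known.
* **Policy.** Backwards induction on
  $Q_t(s,a) = r(s,a) + \sum_{s'} P(s' \mid s,a)\, \max_{a'} Q_{t+1}(s',a')$,
  $Q_N \equiv 0$, yields the fixation policy that maximizes expected total
  reward over the task horizon. A one-step greedy baseline (largest summed
  bandwidth over covered, currently unknown AOIs) is included for
  comparison.

Eight flight-display conditions from a simulated curved-approach study —
tunnel/datalink guidance × overlaid/separate instrument panel × VMC/IMC —
ship as fixtures, with bandwidths, subtask values (aviate 3, navigate 2,
hazard awareness 1), relevance tables and the observed fixation
distributions.

## A worked example

```r
library(gazemdp)

dsv <- flight_condition("DSV")      # datalink / separate panel / VMC
policy <- solve_policy(dsv$spec)
policy
#> <sa_policy> dp policy for DSV: 32 states x 960 moments
#>   stationary over moments 0..943 (6 distinct rule(s))
head(tidy(policy), 4)
#> # A tibble: 4 × 2
#>   state action
#>   <chr> <chr>
#> 1 00000 SVS
#> 2 00001 SVS
#> 3 00010 SVS
#> 4 00011 SVS
```

From total unawareness (`00000`) the optimal first fixation is the SVS,
the highest-value AOI. The rule is identical at all but the last 16 of the
960 decision moments. Simulating one 8-minute flight:

```r
path <- simulate_scanpath(dsv$spec, policy, seed = 42)
head(tibble::as_tibble(path), 5)
#> # A tibble: 5 × 5
#>   moment aoi   state update reward
#>    <int> <chr> <chr> <chr>   <dbl>
#> 1      0 SVS   00000 00001     4
#> 2      1 IP    10000 11001     3.5
#> 3      2 SVS   01000 11100     4
#> 4      3 IP    10000 00001     3.5
#> 5      4 ND    11000 01100     2.5
head(delay_records(path), 3)
#> # A tibble: 3 × 5
#>   aoi   update_stage noticed_moment delay_s status
#>   <chr>        <int>          <int>   <dbl> <chr>
#> 1 OW               0              1     0.5 superseded
#> 2 OW               1              3     1   superseded
#> 3 SVS              1              2     0.5 noticed
```

Each row of the scanpath records the pre-fixation SA state, the period's
information updates and the reward collected; `delay_records()` turns the
trace into delay-to-notice times (an AOI updating at stage $t$ and first
covered again at moment $t'$ went unnoticed for $(t'-t) \times 0.5$ s).
`autoplot(path)` draws the known/unknown × updated raster.

The validation battery simulates all (or selected) conditions and
correlates predictions with the observed gaze distributions:

```r
bat <- run_battery("dp", replications = 200, seed = 1,
                   conditions = c("DSV", "DSI"))
glance(bat)
#> # A tibble: 1 × 7
#>   policy replications  seed n_conditions fixation_r fixation_r2 shift_r
#>   <chr>         <int> <int>        <int>      <dbl>       <dbl>   <dbl>
#> 1 dp              200     1            2      0.787       0.620   0.644
```

`fixation_r` is the Pearson correlation between predicted and observed
per-AOI fixation probabilities pooled over the selected conditions
(`shift_r` likewise for unordered fixation-shift pairs, with observed
shift probabilities derived as $P_{ij} = 2 P_i P_j$, $P_{ii} = P_i^2$).
`autoplot(bat)` draws the predicted-versus-observed scatter.

A thin command-line interface wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "gazemdp.R", package = "gazemdp"))')" \
  solve --condition DSV --out out/
```

with verbs `solve`, `baseline`, `simulate` and `validate`.

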