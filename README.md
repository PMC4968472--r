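# corvnet

Social-network analysis and network-based diffusion analysis (NBDA) for
animal groups, built around the question ethologists keep asking of captive
and wild social species: **when one individual learns a new skill, along
which social ties does the information spread?**

The package covers the full workflow used in studies of information
transmission in corvid groups and similar systems:

- **Ingest** — parse CSV event logs of dyadic interactions collected by
  all-occurrence sampling (affiliative and agonistic behaviours) and scan
  sampling (proximity), with trial-day exclusion and strict vocabulary
  validation.
- **Networks** — weighted directed social networks; observation networks
  normalized by opportunity (Y/X: fraction of another's task solutions an
  individual actually watched); density; out/in-strength, eigenvector and
  Stephenson–Zelen information centrality with group-relative ranks; sex-
  and rank-similarity matrices.
- **Dominance** — linear hierarchies from retreat matrices by the I&SI
  method (lexicographic minimization of the number, then strength, of
  inconsistencies).
- **MRQAP** — multiple regression of one network on several predictor
  networks with double-Dekker semipartialling node-permutation inference.
- **OADA** — order-of-acquisition diffusion analysis: at each acquisition
  event the probability that naive individual *i* is next is proportional to

  ```
  R_i = (1 + s * T_i) * exp(beta' x_i),   T_i = sum_j a_ij * w_j * z_j
  ```

  where `a_ij` is the network connection from *i* to informed individual
  *j*, `w_j` an optional transmission weight (how often *j* performs the
  behaviour), `z_j` the informed indicator, `s` the social-transmission
  rate per unit connection and `x_i` individual-level variables (sex,
  social rank). Model sets over networks, weight flags and ILV subsets are
  compared by AICc; Akaike weights yield per-network **support ratios**
  (evidence for transmission along that network relative to asocial
  learning) and the estimated **%ST**, the proportion of acquisition
  events attributable to social transmission, `mean_k[ s T / (1 + s T) ]`.
- **Synthetic data** — a seeded generator for whole groups (latent dyadic
  bonds, kin structure, dominance, proximity scans), diffusions drawn from
  the OADA hazard model with known `s`, and observation counts driven by
  affiliation — so every stage can be validated against known ground truth.
- **Pipeline** — `run_pipeline()` orchestrates networks → ranks → MRQAP →
  centrality/order correlations → OADA into a deterministic, seeded report
  bundle with JSON export.

## Worked example

```r
library(corvnet)

cfg <- group_config(seed = 1)                  # 12 subadults, 98 days
g   <- generate_group(cfg)
nets <- build_group_networks(g$log, components = FALSE)
nets$affiliative
#> <social_network 'affiliative': n = 12, directed, density = 0.197>

sim <- simulate_diffusion(scale_network(nets$affiliative), s = 7.76,
                          demonstrator = cfg$demonstrator,
                          use_weights = FALSE, seed = 2)
sim$data
#> <diffusion_data: 11 acquisition events, 12 individuals, seeded: S01>

fit <- fit_oada(sim$data, scale_network(nets$affiliative), use_weights = FALSE)
glance(fit)
#> # A tibble: 1 x 9
#>   network     use_weights ilvs  s_hat logLik     k     m  AICc converged
#>   <chr>       <lgl>       <chr> <dbl>  <dbl> <int> <int> <dbl> <lgl>
#> 1 affiliative FALSE       ""     6.48  -13.4     1    11  29.2 TRUE

set <- fit_oada_set(sim$data, nets[c("affiliative", "agonistic", "proximity")],
                    with_and_without_weights = FALSE)
support_ratio(set, "affiliative")
#> [1] 15.35525
percent_social(fit, level = NULL)
#> # A tibble: 1 x 4
#>     pst lower upper n_events
#>   <dbl> <dbl> <dbl>    <int>
#> 1  70.1    NA    NA       11
```

Reading: the diffusion was simulated on the group's affiliative network
with a true transmission rate of 7.76 per unit connection; from the order
of first solutions alone the fit recovers `s_hat = 6.48`, the affiliative
network carries about 15 times more Akaike-weight support than asocial
learning, and an estimated 70% of the acquisitions were socially
transmitted.

`autoplot()` methods exist for networks, centrality tables and OADA model
sets; `tidy()`/`glance()` return tibbles for every fitted object.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full two-group analysis from scratch — generating both
synthetic groups, building their networks and dominance ranks, running the
five-predictor MRQAP on the observation network and the OADA model set
with support ratios and %ST — and writes the JSON report to `--out`.
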