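# Synthetic-data generator: seeded group interaction streams, dominance
# interactions, diffusions from the OADA hazard model, and observation
# counts, all with recorded ground truth so every downstream stage can be
# validated without field data.
#
# The generative world mirrors a captive corvid study: two aviary groups
# (12 subadults with 7 females, 10 juveniles split into sibling groups),
# 98 observation days, scan samples of proximity at 15-min intervals during
# daily observation sessions, one trained demonstrator seeded with the task
# solution, and repeated solving by informed birds.

#' Group configuration for the synthetic generator
#'
#' @param n Group size.
#' @param n_female Number of females.
#' @param age_class `"subadult"` or `"juvenile"`.
#' @param kin_groups Integer vector of length `n` assigning sibling groups
#'   (`NA` = no known kin); defaults to none.
#' @param demonstrator Id of the trained individual (default the first
#'   female).
#' @param days Observation days (default 98).
#' @param scans_per_day Proximity scans per day; 15-min scans over roughly
#'   an hour of daily observation give 4.
#' @param p_bond Probability that a non-kin dyad carries a latent bond;
#'   selective groups have most dyads unbonded. Kin dyads are always bonded.
#' @param rate_affiliative Affiliative events per dyad per day per unit
#'   bond strength.
#' @param rate_agonistic Agonistic events per dyad per day.
#' @param bond_shape,bond_rate Gamma parameters of the latent bond strength
#'   of bonded dyads.
#' @param kin_boost Multiplier on the latent bond within sibling groups.
#' @param p_upset Probability that the subordinate wins an agonistic bout
#'   (0 gives a perfectly linear hierarchy).
#' @param seed Integer seed; all randomness in [generate_group()] flows
#'   from it.
#' @return A list of class `group_config`.
#' @export
group_config <- function(n = 12, n_female = 7, age_class = "subadult",
                         kin_groups = rep(NA_integer_, n),
                         demonstrator = NULL, days = 98, scans_per_day = 4,
                         p_bond = 0.25, rate_affiliative = 0.08,
                         rate_agonistic = 0.02,
                         bond_shape = 2, bond_rate = 1, kin_boost = 3,
                         p_upset = 0.1, seed = 1L) {
  if (n_female > n) abort("`n_female` cannot exceed `n`")
  if (length(kin_groups) != n) abort("`kin_groups` must have length `n`")
  ids <- sprintf("%s%02d", toupper(substr(age_class, 1, 1)), seq_len(n))
  sex <- c(rep("F", n_female), rep("M", n - n_female))
  demonstrator <- demonstrator %||% ids[which(sex == "F")[1]]
  if (!(demonstrator %in% ids)) abort("`demonstrator` must be one of the generated ids")
  structure(list(n = n, ids = ids, sex = sex, age_class = age_class,
                 kin_groups = kin_groups, demonstrator = demonstrator,
                 days = days, scans_per_day = scans_per_day,
                 p_bond = p_bond, rate_affiliative = rate_affiliative,
                 rate_agonistic = rate_agonistic,
                 bond_shape = bond_shape, bond_rate = bond_rate,
                 kin_boost = kin_boost, p_upset = p_upset, seed = seed),
            class = "group_config")
}

#' Juvenile-group preset
#'
#' Ten juveniles (5 female) in three sibling groups, mirroring a
#' kin-structured aviary group.
#' @param seed Integer seed.
#' @param ... Overrides passed to [group_config()].
#' @export
juvenile_group_config <- function(seed = 1L, ...) {
  group_config(n = 10, n_female = 5, age_class = "juvenile",
               kin_groups = c(1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L),
               seed = seed, ...)
}

#' Generate a synthetic group's event log
#'
#' Latent symmetric bond strengths are drawn per dyad: a dyad is bonded
#' with probability `p_bond` (kin dyads always, with a boosted bond), and
#' only bonded dyads interact affiliatively, which keeps the networks as
#' sparse as selective animal groups really are. Affiliative events arrive
#' as Poisson counts per dyad per day at bond-scaled rates (direction
#' random, split between physical contact and sharing); agonistic events
#' follow a latent linear hierarchy with upset probability `p_upset` (the
#' loser retreats); proximity scans record sitting close / same branch with
#' probability increasing in a proximity propensity that mixes the bond
#' with its own sparse noise, so the proximity network correlates with the
#' affiliative one without duplicating it.
#'
#' @param config A [group_config()].
#' @return List with `log` ([event_log()]), `bonds` (latent dyadic bond
#'   matrix), `latent_rank` (true dominance order, most dominant first),
#'   and `config`.
#' @export
generate_group <- function(config) {
  ids <- config$ids
  n <- config$n
  with_seed(config$seed, {
    bonds <- matrix(0, n, n, dimnames = list(ids, ids))
    ut <- upper.tri(bonds)
    kin_same <- outer(config$kin_groups, config$kin_groups,
                      function(a, b) !is.na(a) & !is.na(b) & a == b)[ut]
    bonded <- kin_same | (runif(sum(ut)) < config$p_bond)
    b <- ifelse(bonded,
                rgamma(sum(ut), shape = config$bond_shape, rate = config$bond_rate),
                0)
    b[kin_same] <- b[kin_same] * config$kin_boost
    bonds[ut] <- b
    bonds <- bonds + t(bonds)

    latent_rank <- sample(ids)  # true dominance order, position 1 = top

    days <- as.Date("2012-09-01") + seq_len(config$days) - 1
    ev <- list()

    # affiliative: per-dyad total over the study, Poisson with bond-scaled
    # daily rate, then spread over random days and directions
    pair_idx <- which(ut, arr.ind = TRUE)
    aff_rate <- config$rate_affiliative * bonds[ut]
    n_aff <- rpois(length(aff_rate), aff_rate * config$days)
    for (d in which(n_aff > 0)) {
      cnt <- n_aff[d]
      a <- ids[pair_idx[d, 1]]; r <- ids[pair_idx[d, 2]]
      flip <- runif(cnt) < 0.5
      ev[[length(ev) + 1]] <- tibble::tibble(
        day = sample(days, cnt, replace = TRUE),
        actor = ifelse(flip, a, r), receiver = ifelse(flip, r, a),
        behaviour = sample(c("physical_contact", "share"), cnt,
                           replace = TRUE, prob = c(0.6, 0.4)),
        record_kind = "all_occurrence")
    }

    # agonistic: the latent-dominant individual threatens; loser retreats
    pos <- match(ids, latent_rank)
    n_ago <- rpois(length(aff_rate), config$rate_agonistic * config$days)
    for (d in which(n_ago > 0)) {
      cnt <- n_ago[d]
      i <- pair_idx[d, 1]; j <- pair_idx[d, 2]
      dom <- if (pos[i] < pos[j]) ids[i] else ids[j]
      sub <- setdiff(ids[c(i, j)], dom)
      upset <- runif(cnt) < config$p_upset
      ev[[length(ev) + 1]] <- tibble::tibble(
        day = sample(days, cnt, replace = TRUE),
        actor = ifelse(upset, sub, dom), receiver = ifelse(upset, dom, sub),
        behaviour = "agonistic", record_kind = "all_occurrence")
    }

    # proximity scans: propensity mixes the bond with its own sparse noise
    n_scans <- config$days * config$scans_per_day
    prox_noise <- ifelse(runif(sum(ut)) < 0.3,
                         rgamma(sum(ut), shape = 2, rate = 1), 0)
    prox <- 0.6 * bonds[ut] + prox_noise
    p_sit <- 1 - exp(-0.02 * prox)
    p_branch <- 1 - exp(-0.012 * prox)
    n_sit <- rbinom(length(p_sit), n_scans, p_sit)
    n_branch <- rbinom(length(p_branch), n_scans, p_branch)
    for (d in which(n_sit + n_branch > 0)) {
      a <- ids[pair_idx[d, 1]]; r <- ids[pair_idx[d, 2]]
      cnt <- n_sit[d] + n_branch[d]
      ev[[length(ev) + 1]] <- tibble::tibble(
        day = sample(days, cnt, replace = TRUE),
        actor = a, receiver = r,
        behaviour = rep(c("sit_close", "same_branch"), c(n_sit[d], n_branch[d])),
        record_kind = "scan")
    }

    events <- if (length(ev)) dplyr::bind_rows(ev) else
      tibble::tibble(day = as.Date(character()), actor = character(),
                     receiver = character(), behaviour = character(),
                     record_kind = character())
    individuals <- tibble::tibble(
      id = ids, sex = config$sex, age_class = config$age_class,
      kin_group = config$kin_groups,
      trained = ids == config$demonstrator)
    list(log = event_log(individuals, events,
                         group_id = config$age_class),
         bonds = bonds, latent_rank = latent_rank, config = config)
  })
}

#' Simulate a diffusion from the OADA hazard model
#'
#' Continuous-time competing-hazards simulation: each naive individual i
#' acquires at rate `lambda0 * (1 + s * sum_j a_ij w_j(t) z_j(t)) *
#' exp(beta' x_i)`; informed individuals keep solving at `solve_rate` per
#' day so transmission weights grow over time. The demonstrator starts
#' informed with 10 solutions (trained to criterion before the group phase).
#'
#' @param network Generative [social_network()].
#' @param s True social-transmission parameter (>= 0).
#' @param demonstrator Seeded id.
#' @param beta,ilvs Optional ILV effects (as in [oada_loglik()]).
#' @param lambda0 Baseline asocial rate per day (cancels in OADA; default 1).
#' @param solve_rate Further solutions per informed individual per day.
#' @param use_weights Whether the generative social rate uses transmission
#'   weights (default `TRUE`).
#' @param demonstrator_solves Initial solution count of the demonstrator.
#' @param seed Integer seed (fixed seed gives bit-identical output).
#' @return List with `data` (a [diffusion_data()]) and `truth` (list:
#'   `s`, `beta`, `network_label`, `p_social` per event, `pst_true`
#'   = 100 * mean generative social probability).
#' @export
simulate_diffusion <- function(network, s, demonstrator, beta = NULL,
                               ilvs = NULL, lambda0 = 1, solve_rate = 2,
                               use_weights = TRUE, demonstrator_solves = 10,
                               seed = 1L) {
  if (s < 0) abort("`s` must be nonnegative")
  ids <- network$labels
  if (!all(demonstrator %in% ids)) abort("demonstrator must be in the network")
  n <- length(ids)
  W <- network$W
  mult <- if (is.null(beta) || is.null(ilvs)) setNames(rep(1, n), ids) else
    exp(as.numeric(as.matrix(ilvs)[ids, , drop = FALSE] %*% beta))

  with_seed(seed, {
    informed <- ids %in% demonstrator
    solves <- setNames(ifelse(informed, demonstrator_solves, 0), ids)
    order_out <- character(0)
    scb <- NULL
    p_social <- numeric(0)
    while (any(!informed)) {
      w <- if (use_weights) solves else as.numeric(informed)
      Texp <- as.numeric(W %*% (w * informed))  # T_i = sum_j a_ij w_j z_j
      rate <- lambda0 * (1 + s * Texp) * mult
      rate[informed] <- 0
      solve_rates <- ifelse(informed, solve_rate, 0)
      total <- sum(rate) + sum(solve_rates)
      pick <- sample.int(n + n, 1, prob = c(rate, solve_rates))
      if (pick <= n) {  # acquisition event
        i <- pick
        order_out <- c(order_out, ids[i])
        scb <- rbind(scb, solves)
        p_social <- c(p_social, s * Texp[i] / (1 + s * Texp[i]))
        informed[i] <- TRUE
        solves[i] <- 1  # the first solution itself
      } else {          # a further solve by an informed individual
        j <- pick - n
        solves[j] <- solves[j] + 1
      }
    }
    rownames(scb) <- NULL
    data <- diffusion_data(order = order_out, ids = ids,
                           seeded = demonstrator,
                           solve_counts_before = scb,
                           solve_counts_final = solves)
    list(data = data,
         truth = list(s = s, beta = beta, network_label = network$behaviour,
                      p_social = p_social,
                      pst_true = 100 * mean(p_social)))
  })
}

#' Simulate observation counts from a diffusion
#'
#' For every solution by an informed individual j before naive i's first
#' solution, i is within observation range with probability
#' `plogis(intercept + slope * min(a_ij / mean nonzero a, cap))`: a
#' logistic link on the tie rescaled to unit mean so `slope` has the same
#' meaning whatever the counting scale. `slope = 0` makes observation
#' independent of affiliation.
#'
#' @param network Affiliative [social_network()] driving observation.
#' @param data A [diffusion_data()] carrying `solve_counts_final`.
#' @param slope,intercept Logistic-link parameters.
#' @param cap Upper bound on the rescaled tie inside the link.
#' @param seed Integer seed.
#' @return List with `obs` and `solves_before` count matrices (rows =
#'   observers, columns = solvers), ready for [normalize_observation()].
#' @export
simulate_observations <- function(network, data, slope = 4, intercept = -4,
                                  cap = 2, seed = 1L) {
  ids <- data$ids
  n <- length(ids)
  W <- network$W[ids, ids]
  a_scaled <- if (any(W > 0)) pmin(W / mean(W[W > 0]), cap) else W
  solves_before <- matrix(0L, n, n, dimnames = list(ids, ids))
  final <- data$solve_counts_final %||% apply(data$solve_counts_before, 2, max)
  for (i in seq_len(n)) {
    id <- ids[i]
    if (id %in% data$seeded) next                    # informed at t0: observed nobody as naive
    k <- match(id, data$order)
    solves_before[i, ] <- if (!is.na(k)) data$solve_counts_before[k, ids] else
      as.integer(final[ids])                         # never solved: whole study
  }
  diag(solves_before) <- 0L
  with_seed(seed, {
    p <- stats::plogis(intercept + slope * a_scaled)
    obs <- matrix(rbinom(n * n, solves_before, p), n, n, dimnames = list(ids, ids))
    list(obs = obs, solves_before = solves_before)
  })
}
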