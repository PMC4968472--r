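# Order-of-acquisition diffusion analysis (OADA). The likelihood uses only
# the order in which naive individuals first perform the behaviour: at each
# acquisition event the probability that a particular naive individual is
# next is its hazard divided by the summed hazard of all naive individuals,
# so the asocial baseline rate cancels and need not be estimated.
#
# Hazard of naive i at event k:
#   R_i(k) = (1 + s * T_i(k)) * exp(beta' x_i)
#   T_i(k) = sum_j a_ij * w_j(k) * z_j(k)
# with z_j(k) = 1 iff j was informed before event k and w_j(k) the
# transmission weight (cumulative number of j's solutions before event k, or
# 1 when weights are off). s >= 0 is the social-transmission rate per unit
# network connection relative to the asocial rate; individual-level
# variables (ILVs) act multiplicatively on the whole rate, so the asocial
# model is a clean nested null.

#' Construct diffusion data
#'
#' The order of first solutions in one group, with the bookkeeping OADA
#' needs: who was seeded (the trained demonstrator, informed at time zero),
#' how often each individual had solved before each acquisition event, and
#' who (if anyone) was moved out of observation range part-way through.
#'
#' @param order Character vector of acquirer ids, first solver first. Seeded
#'   ids never appear; individuals that never solved simply do not appear.
#' @param ids All individual ids in the group (the risk set).
#' @param seeded Ids informed at time zero.
#' @param solve_counts_before m x n matrix (events x individuals, columns
#'   named by id): number of solutions by each individual strictly before
#'   each acquisition event.
#' @param solve_counts_final Optional named vector of end-of-study solution
#'   totals (needed for `weight_mode = "total"` and observation simulation).
#' @param separated_from Optional named integer vector: from this event
#'   index onward the individual could no longer observe solvers (its social
#'   term is zeroed) though it remains in the risk set.
#' @return Object of class `diffusion_data`.
#' @export
diffusion_data <- function(order, ids, seeded, solve_counts_before,
                           solve_counts_final = NULL, separated_from = NULL) {
  order <- as.character(order); ids <- as.character(ids); seeded <- as.character(seeded)
  if (!all(seeded %in% ids)) abort("seeded ids must be among `ids`")
  if (!all(order %in% ids)) abort(sprintf("unknown id in order: %s",
                                          toString(setdiff(order, ids))))
  if (length(intersect(order, seeded))) abort("seeded individuals cannot appear in the acquisition order")
  if (anyDuplicated(order)) abort("each individual acquires at most once")
  m <- length(order); n <- length(ids)
  SCB <- as.matrix(solve_counts_before)
  if (nrow(SCB) != m) abort("solve_counts_before must have one row per acquisition event")
  if (is.null(colnames(SCB))) {
    if (ncol(SCB) != n) abort("solve_counts_before must have one column per individual")
    colnames(SCB) <- ids
  }
  SCB <- SCB[, ids, drop = FALSE]
  if (any(SCB < 0)) abort("solve counts must be nonnegative")
  if (m > 1 && any(apply(SCB, 2, diff) < 0)) abort("solve counts must be non-decreasing over events")
  # a naive individual has, by definition, zero solutions
  for (k in seq_len(m)) {
    naive <- setdiff(ids, c(seeded, if (k > 1) order[seq_len(k - 1)]))
    if (any(SCB[k, naive] != 0)) abort("naive individuals must have zero solve counts")
  }
  if (!is.null(separated_from) && !all(names(separated_from) %in% ids)) {
    abort("separated_from names must be individual ids")
  }
  structure(list(order = order, ids = ids, seeded = seeded,
                 solve_counts_before = SCB,
                 solve_counts_final = solve_counts_final,
                 separated_from = separated_from),
            class = "diffusion_data")
}

#' @export
print.diffusion_data <- function(x, ...) {
  cat(sprintf("<diffusion_data: %d acquisition events, %d individuals, seeded: %s>\n",
              length(x$order), length(x$ids), toString(x$seeded)))
  invisible(x)
}

# Per-event social exposure matrix T (m x n): T[k, i] = sum_j a_ij w_j(k) z_j(k).
social_exposure <- function(data, network, use_weights,
                            weight_mode = "cumulative") {
  ids <- data$ids
  m <- length(data$order); n <- length(ids)
  if (m == 0) return(matrix(0, 0, n, dimnames = list(NULL, ids)))
  W <- network$W[ids, ids, drop = FALSE]
  informed <- matrix(0, m, n, dimnames = list(NULL, ids))
  for (k in seq_len(m)) {
    informed[k, c(data$seeded, if (k > 1) data$order[seq_len(k - 1)])] <- 1
  }
  w <- if (!use_weights) {
    informed
  } else if (weight_mode == "cumulative") {
    data$solve_counts_before[, ids, drop = FALSE] * informed
  } else {  # end-of-study totals
    totals <- data$solve_counts_final %||% apply(data$solve_counts_before, 2, max)
    informed * matrix(totals[ids], m, n, byrow = TRUE)
  }
  Tm <- w %*% t(W)
  colnames(Tm) <- ids
  if (!is.null(data$separated_from)) {
    for (id in names(data$separated_from)) {
      k0 <- data$separated_from[[id]]
      if (k0 <= m) Tm[seq(k0, m), id] <- 0
    }
  }
  Tm
}

# Naive indicator per event (m x n).
naive_matrix <- function(data) {
  ids <- data$ids
  m <- length(data$order)
  naive <- matrix(TRUE, m, length(ids), dimnames = list(NULL, ids))
  naive[, data$seeded] <- FALSE
  for (k in seq_len(m)) {
    if (k > 1) naive[k, data$order[seq_len(k - 1)]] <- FALSE
  }
  naive
}

# ILV linear predictor exp(beta' x_i) as a length-n named vector.
ilv_multiplier <- function(data, ilvs, beta) {
  ids <- data$ids
  if (is.null(ilvs) || is.null(beta) || length(beta) == 0) {
    return(setNames(rep(1, length(ids)), ids))
  }
  X <- as.matrix(ilvs)[ids, , drop = FALSE]
  exp(as.numeric(X %*% beta))
}

#' OADA log-likelihood
#'
#' @param data A [diffusion_data()] or a list of them (pooled diffusions sum
#'   their log-likelihood contributions).
#' @param network A [social_network()] or `NULL` for an asocial model.
#' @param s Social-transmission parameter (>= 0).
#' @param beta Numeric vector of ILV coefficients (length = `ncol(ilvs)`).
#' @param ilvs Numeric matrix of individual-level variables, rows named by
#'   id (e.g. sex coded 0/1, social rank).
#' @param use_weights Multiply each informed individual's contribution by
#'   its transmission weight.
#' @param weight_mode `"cumulative"` (solutions before the event; default)
#'   or `"total"` (end-of-study totals).
#' @return Log-likelihood (0 for an empty order).
#' @export
oada_loglik <- function(data, network = NULL, s = 0, beta = NULL, ilvs = NULL,
                        use_weights = FALSE, weight_mode = c("cumulative", "total")) {
  weight_mode <- match.arg(weight_mode)
  if (s < 0) abort("`s` must be nonnegative")
  if (inherits(data, "diffusion_data")) data <- list(data)
  sum(vapply(data, function(d) {
    m <- length(d$order)
    if (m == 0) return(0)
    ids <- d$ids
    Tm <- if (is.null(network)) {
      matrix(0, m, length(ids), dimnames = list(NULL, ids))
    } else {
      social_exposure(d, network, use_weights, weight_mode)
    }
    mult <- ilv_multiplier(d, ilvs, beta)
    R <- (1 + s * Tm) * matrix(mult, m, length(ids), byrow = TRUE)
    naive <- naive_matrix(d)
    acq <- cbind(seq_len(m), match(d$order, ids))
    sum(log(R[acq]) - log(rowSums(R * naive)))
  }, 0))
}

# Precompute everything the likelihood needs per diffusion so optimization
# only does cheap matrix-vector work: exposure Tm, the naive risk-set
# indicator, the acquirer index, and the ILV design restricted to this
# group's ids.
oada_precompute <- function(data, network, use_weights, weight_mode, X) {
  lapply(data, function(d) {
    m <- length(d$order)
    ids <- d$ids
    Tm <- if (is.null(network)) matrix(0, m, length(ids)) else
      social_exposure(d, network, use_weights, weight_mode)
    list(Tm = Tm, naive = naive_matrix(d),
         acq = cbind(seq_len(m), match(d$order, ids)),
         X = if (is.null(X)) NULL else as.matrix(X)[ids, , drop = FALSE])
  })
}

oada_loglik_pre <- function(pre, s, beta) {
  sum(vapply(pre, function(p) {
    if (nrow(p$Tm) == 0) return(0)
    Rm <- 1 + s * p$Tm
    mult <- if (is.null(p$X) || length(beta) == 0) rep(1, ncol(p$Tm)) else
      exp(as.numeric(p$X %*% beta))
    num <- log(Rm[p$acq]) + log(mult[p$acq[, 2]])
    den <- log(as.numeric((Rm * p$naive) %*% mult))
    sum(num - den)
  }, 0))
}

#' Fit an OADA model
#'
#' Maximizes the order likelihood over s (constrained nonnegative, optimized
#' on a log scale with multi-start and boundary checking) and the ILV
#' coefficients. Deterministic: no RNG involved.
#'
#' @inheritParams oada_loglik
#' @param ilvs Numeric matrix of candidate ILVs (rows named by id); only the
#'   columns in `ilv_set` enter the model.
#' @param ilv_set Character subset of `colnames(ilvs)` (default none).
#' @param network_label Optional label stored with the fit (defaults to the
#'   network's behaviour label, or `"asocial"`).
#' @return Object of class `oada_fit` with elements `s_hat`, `beta_hat`,
#'   `logLik`, `k`, `m`, `AICc`, `converged` and the model specification needed to
#'   recompute (network, flags, data).
#' @export
fit_oada <- function(data, network = NULL, use_weights = FALSE, ilvs = NULL,
                     ilv_set = character(),
                     weight_mode = c("cumulative", "total"),
                     network_label = NULL) {
  weight_mode <- match.arg(weight_mode)
  if (inherits(data, "diffusion_data")) data <- list(data)
  m <- sum(vapply(data, function(d) length(d$order), 0L))
  if (m < 2) abort("need at least 2 acquisition events to fit")
  ilv_set <- as.character(ilv_set)
  if (length(ilv_set)) {
    if (is.null(ilvs)) abort("`ilvs` matrix required when `ilv_set` is nonempty")
    missing_ilv <- setdiff(ilv_set, colnames(ilvs))
    if (length(missing_ilv)) abort(sprintf("unknown ILV(s): %s", toString(missing_ilv)))
    X <- as.matrix(ilvs)[, ilv_set, drop = FALSE]
  } else X <- NULL
  p <- if (is.null(X)) 0L else ncol(X)
  has_s <- !is.null(network)

  pre <- oada_precompute(data, network, use_weights, weight_mode, X)
  ll <- function(s, beta) oada_loglik_pre(pre, s, beta)

  converged <- TRUE
  if (!has_s && p == 0) {
    s_hat <- 0; beta_hat <- numeric(0); logLik <- ll(0, NULL)
  } else if (!has_s) {
    opt <- stats::optim(rep(0, p), function(b) -ll(0, b), method = "BFGS",
                        control = list(reltol = 1e-12, maxit = 500))
    converged <- opt$convergence == 0
    s_hat <- 0; beta_hat <- setNames(opt$par, ilv_set); logLik <- -opt$value
  } else {
    # multi-start over s (log scale); beta jointly by BFGS
    best <- NULL
    for (s0 in c(0.1, 1, 10, 100)) {
      par0 <- c(log(s0), rep(0, p))
      opt <- tryCatch(
        stats::optim(par0, function(par) -ll(exp(par[1]), par[-1]),
                     method = "BFGS", control = list(reltol = 1e-12, maxit = 1000)),
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
    }
    if (is.null(best)) abort("OADA optimization failed from every start; check the data")
    converged <- best$convergence == 0
    s_hat <- exp(best$par[1])
    beta_hat <- setNames(best$par[-1], ilv_set)
    logLik <- -best$value
    # 1-D profile refinement of s at the fitted beta
    ref <- stats::optimise(function(u) -ll(exp(u), beta_hat),
                           interval = c(-25, 25), tol = 1e-10)
    if (-ref$objective > logLik) {
      s_hat <- exp(ref$minimum); logLik <- -ref$objective
    }
    # boundary check: the constrained MLE may sit at s = 0
    ll0 <- if (p > 0) {
      opt0 <- stats::optim(rep(0, p), function(b) -ll(0, b), method = "BFGS",
                           control = list(reltol = 1e-12, maxit = 500))
      -opt0$value
    } else ll(0, NULL)
    if (ll0 >= logLik - 1e-9) {
      s_hat <- 0; logLik <- max(logLik, ll0)
      if (p > 0) beta_hat <- setNames(opt0$par, ilv_set)
    }
  }

  k <- as.integer(has_s) + p
  aicc <- -2 * logLik + 2 * k + if (m - k - 1 > 0) 2 * k * (k + 1) / (m - k - 1) else Inf
  structure(list(s_hat = s_hat, beta_hat = beta_hat, logLik = logLik,
                 k = k, m = m, AICc = aicc, converged = converged,
                 network = network, use_weights = use_weights,
                 weight_mode = weight_mode, ilvs = X, ilv_set = ilv_set,
                 network_label = network_label %||%
                   (if (has_s) network$behaviour else "asocial"),
                 data = data, precomp = pre),
            class = "oada_fit")
}

#' @export
print.oada_fit <- function(x, ...) {
  cat(sprintf("<oada_fit: %s%s | s = %.4g, logLik = %.3f, k = %d, AICc = %.2f>\n",
              x$network_label,
              if (!is.null(x$network) && x$use_weights) " (weighted)" else "",
              x$s_hat, x$logLik, x$k, x$AICc))
  invisible(x)
}

#' Tidy an OADA fit
#'
#' @param x An `oada_fit`.
#' @param ... Unused.
#' @return One row per estimated parameter (`s` and any ILV coefficients).
#' @method tidy oada_fit
#' @export
tidy.oada_fit <- function(x, ...) {
  terms <- c(if (!is.null(x$network)) "s", names(x$beta_hat))
  est <- c(if (!is.null(x$network)) x$s_hat, unname(x$beta_hat))
  tibble::tibble(term = terms %||% character(), estimate = est %||% numeric())
}

#' @rdname tidy.oada_fit
#' @method glance oada_fit
#' @export
glance.oada_fit <- function(x, ...) {
  tibble::tibble(network = x$network_label, use_weights = x$use_weights,
                 ilvs = paste(x$ilv_set, collapse = "+"),
                 s_hat = if (!is.null(x$network)) x$s_hat else NA_real_,
                 logLik = x$logLik, k = x$k, m = x$m, AICc = x$AICc,
                 converged = x$converged)
}

#' Profile-likelihood confidence interval for s
#'
#' The interval is all s whose profile log-likelihood (with ILV coefficients
#' re-optimized at each s) lies within qchisq(level, 1)/2 of the maximum.
#' When the profile stays flat out to very large s the upper bound is
#' reported as right-open (`Inf` with `open_upper = TRUE`), which is common
#' for order data where large s values are barely distinguishable.
#'
#' @param fit An `oada_fit` with a network.
#' @param level Confidence level (default 0.95).
#' @param s_max Largest s probed before declaring the interval right-open.
#' @return Tibble with `lower`, `upper`, `open_upper`, `level`.
#' @export
profile_ci_s <- function(fit, level = 0.95, s_max = 1e7) {
  if (is.null(fit$network)) abort("profile CI for s requires a social model")
  p <- length(fit$beta_hat)
  pre <- fit$precomp
  pll <- function(s) {
    if (p == 0) {
      oada_loglik_pre(pre, s, numeric(0))
    } else {
      opt <- stats::optim(fit$beta_hat,
                          function(b) -oada_loglik_pre(pre, s, b),
                          method = "BFGS", control = list(reltol = 1e-10))
      -opt$value
    }
  }
  thr <- fit$logLik - qchisq(level, 1) / 2
  g <- function(s) pll(s) - thr

  lower <- if (g(0) >= 0) 0 else {
    # walk the left bracket end down until the profile drops below the cut
    lo <- max(fit$s_hat, 1e-10)
    while (g(lo) >= 0 && lo > 1e-12) lo <- lo / 10
    if (g(lo) >= 0) 0 else
      uniroot(g, c(lo, max(fit$s_hat, 1e-10)), tol = 1e-8)$root
  }
  open_upper <- FALSE
  upper <- if (g(s_max) >= 0) {
    open_upper <- TRUE
    Inf
  } else {
    uniroot(g, c(max(fit$s_hat, 1e-10), s_max), tol = 1e-6)$root
  }
  tibble::tibble(lower = lower, upper = upper, open_upper = open_upper,
                 level = level)
}

#' Enumerate an OADA candidate model set
#'
#' One social model per network x weight-flag x ILV subset (networks enter
#' singly, never jointly) plus one asocial model per ILV subset including
#' the empty null.
#'
#' @param networks Named list of [social_network()] objects.
#' @param ilv_pool Character vector of candidate ILV names.
#' @param with_and_without_weights If `TRUE` both weight flags are used,
#'   otherwise only weighted models.
#' @return Tibble of model specs (`network`, `use_weights`, `ilvs` list-col).
#' @export
enumerate_models <- function(networks, ilv_pool = character(),
                             with_and_without_weights = TRUE) {
  if (anyDuplicated(names(networks))) abort("duplicate network labels")
  subsets <- purrr::map(0:length(ilv_pool), function(sz) {
    if (sz == 0) list(character(0)) else
      apply(combn(ilv_pool, sz), 2, identity, simplify = FALSE)
  }) |> purrr::flatten()
  wflags <- if (with_and_without_weights) c(TRUE, FALSE) else TRUE
  social <- tidyr::expand_grid(network = names(networks) %||% character(),
                               use_weights = wflags,
                               ilvs = subsets)
  asocial <- tidyr::expand_grid(network = NA_character_, use_weights = FALSE,
                                ilvs = subsets)
  dplyr::bind_rows(social, asocial)
}

#' Fit a full OADA model set
#'
#' @param data A [diffusion_data()] or list of them (pooled).
#' @param networks Named list of candidate [social_network()] objects.
#' @param ilvs Numeric ILV matrix (rows named by id), or `NULL`.
#' @param ilv_pool ILV names entering the model set (default all columns of
#'   `ilvs`).
#' @param with_and_without_weights Fit both weight flags (default `TRUE`).
#' @param weight_mode Passed to [fit_oada()].
#' @return Object of class `oada_model_set`: tibble of per-model results
#'   (logLik, k, AICc, delta, akaike_weight) with the fit objects attached.
#' @export
fit_oada_set <- function(data, networks, ilvs = NULL,
                         ilv_pool = colnames(ilvs),
                         with_and_without_weights = TRUE,
                         weight_mode = c("cumulative", "total")) {
  weight_mode <- match.arg(weight_mode)
  specs <- enumerate_models(networks, ilv_pool %||% character(),
                            with_and_without_weights)
  fits <- vector("list", nrow(specs))
  for (i in seq_len(nrow(specs))) {
    net <- if (is.na(specs$network[i])) NULL else networks[[specs$network[i]]]
    fits[[i]] <- fit_oada(data, network = net,
                          use_weights = specs$use_weights[i],
                          ilvs = ilvs, ilv_set = specs$ilvs[[i]],
                          weight_mode = weight_mode,
                          network_label = if (is.na(specs$network[i])) "asocial"
                                          else specs$network[i])
  }
  tab <- purrr::map_dfr(fits, glance)
  tab$akaike_weight <- akaike_weights(tab$AICc)
  tab$delta_AICc <- tab$AICc - min(tab$AICc)
  tab <- tab[order(tab$AICc), ]
  fits <- fits[order(purrr::map_dbl(fits, "AICc"))]
  structure(tab, fits = fits, class = c("oada_model_set", class(tab)))
}

#' @export
print.oada_model_set <- function(x, ...) {
  cat("OADA model set:", nrow(x), "models,", sum(x$network == "asocial"),
      "asocial\n")
  print(tibble::as_tibble(x), n = 10)
  nets <- setdiff(unique(x$network), "asocial")
  if (length(nets)) {
    cat("\nsupport ratios (network vs asocial):\n")
    for (nm in nets) cat(sprintf("  %-16s %8.2f\n", nm, support_ratio(x, nm)))
  }
  invisible(x)
}

#' Read / write diffusion data as CSV
#'
#' The interchange format is a pair of CSVs: an event table
#' (`event_index`, `acquirer_id`) and a per-event solve-count table
#' (`event_index`, one column per individual id with the counts before that
#' event). Ids absent from the order but present in the count table are the
#' remainder of the risk set; seeded ids are marked in the event table with
#' `event_index = 0`.
#'
#' @param data A [diffusion_data()].
#' @param events_path,counts_path Output CSV paths.
#' @return `write_diffusion_csv()` returns `data` invisibly;
#'   `read_diffusion_csv()` returns a [diffusion_data()].
#' @export
write_diffusion_csv <- function(data, events_path, counts_path) {
  ev <- tibble::tibble(event_index = c(rep(0L, length(data$seeded)),
                                       seq_along(data$order)),
                       acquirer_id = c(data$seeded, data$order))
  readr::write_csv(ev, events_path)
  cnt <- tibble::as_tibble(data$solve_counts_before)
  cnt <- dplyr::bind_cols(tibble::tibble(event_index = seq_along(data$order)), cnt)
  readr::write_csv(cnt, counts_path)
  invisible(data)
}

#' @rdname write_diffusion_csv
#' @export
read_diffusion_csv <- function(events_path, counts_path) {
  ev <- readr::read_csv(events_path, show_col_types = FALSE)
  cnt <- readr::read_csv(counts_path, show_col_types = FALSE)
  ids <- setdiff(names(cnt), "event_index")
  scb <- as.matrix(cnt[order(cnt$event_index), ids, drop = FALSE])
  rownames(scb) <- NULL
  diffusion_data(order = ev$acquirer_id[ev$event_index > 0][order(ev$event_index[ev$event_index > 0])],
                 ids = ids,
                 seeded = ev$acquirer_id[ev$event_index == 0],
                 solve_counts_before = scb)
}

#' Akaike weights
#'
#' `w_m = exp(-delta_m / 2) / sum exp(-delta / 2)` with
#' `delta_m = AICc_m - min(AICc)`; invariant to adding a constant to all
#' AICc values.
#'
#' @param x Numeric vector of AICc values, or an `oada_model_set`.
#' @return Numeric weights summing to 1.
#' @export
akaike_weights <- function(x) {
  aicc <- if (inherits(x, "oada_model_set")) x$AICc else as.numeric(x)
  if (!length(aicc)) abort("need at least one model")
  d <- aicc - min(aicc)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Network support ratio
#'
#' Summed Akaike weight of every model containing the network, divided by
#' the summed weight of the asocial models: how much more support the data
#' give social transmission along this network than asocial learning. As a
#' guideline, a likelihood-ratio p-value of 0.05 for one extra parameter
#' corresponds to a support ratio of about 2.5.
#'
#' @param set An `oada_model_set`.
#' @param network_label Label of the network of interest.
#' @return Nonnegative ratio (possibly `Inf` when asocial support underflows).
#' @export
support_ratio <- function(set, network_label) {
  w <- set$akaike_weight
  asocial <- sum(w[set$network == "asocial"])
  if (asocial == 0) {
    warn("asocial models have zero numerical support; support ratio is Inf")
    return(Inf)
  }
  sum(w[set$network == network_label]) / asocial
}

#' Total Akaike weight of an ILV
#'
#' @param set An `oada_model_set`.
#' @param ilv_label ILV name.
#' @return Percentage: 100 x summed weight of models containing the ILV.
#' @export
ilv_total_weight <- function(set, ilv_label) {
  has <- purrr::map_lgl(strsplit(set$ilvs, "+", fixed = TRUE),
                        function(v) ilv_label %in% v)
  100 * sum(set$akaike_weight[has])
}

#' Estimated proportion of socially transmitted acquisitions
#'
#' For each acquisition event the probability that the acquirer learned
#' socially rather than asocially is the social share of its hazard,
#' `s T / (1 + s T)`; %ST is 100 times the mean over events. The CI comes
#' from recomputing at the profile-CI bounds of s (ILV coefficients
#' re-optimized at each bound).
#'
#' @param fit An `oada_fit`.
#' @param level Confidence level for the CI (default 0.95); `NULL` skips it.
#' @return Tibble with `pst` (percent), `lower`, `upper`, `n_events`.
#' @export
percent_social <- function(fit, level = 0.95) {
  if (is.null(fit$network) || fit$s_hat == 0) {
    ne <- sum(vapply(fit$data, function(d) length(d$order), 0L))
    return(tibble::tibble(pst = 0, lower = NA_real_, upper = NA_real_,
                          n_events = ne))
  }
  pst_at <- function(s, beta) {
    p <- unlist(lapply(fit$precomp, function(pc) {
      Tk <- pc$Tm[pc$acq]
      s * Tk / (1 + s * Tk)
    }))
    100 * mean(p)
  }
  est <- pst_at(fit$s_hat, fit$beta_hat)
  lo <- up <- NA_real_
  if (!is.null(level)) {
    ci <- profile_ci_s(fit, level = level)
    reopt_beta <- function(s) {
      if (length(fit$beta_hat) == 0) return(numeric(0))
      stats::optim(fit$beta_hat,
                   function(b) -oada_loglik_pre(fit$precomp, s, b),
                   method = "BFGS")$par
    }
    lo <- pst_at(ci$lower, reopt_beta(ci$lower))
    up <- if (is.finite(ci$upper)) pst_at(ci$upper, reopt_beta(ci$upper)) else 100
  }
  tibble::tibble(pst = est, lower = lo, upper = up,
                 n_events = sum(vapply(fit$data, function(d) length(d$order), 0L)))
}
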