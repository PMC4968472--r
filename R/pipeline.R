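# Orchestration: event log -> networks -> dominance ranks -> MRQAP ->
# centrality/order correlations -> OADA model set -> report bundle.

#' Build the standard networks from an event log
#'
#' Composite affiliative (cell-wise sum of physical contact and share
#' counts), its two components, the agonistic network, composite proximity
#' (sitting close + same branch) and its two components. Interaction
#' networks are directed; scan-based proximity networks are undirected.
#'
#' @param log An [event_log()].
#' @param components Also return the component networks (default `TRUE`).
#' @return Named list of [social_network()] objects plus `dominance`
#'   (the directed agonistic count matrix, threats in rows, retreats in
#'   columns).
#' @export
build_group_networks <- function(log, components = TRUE) {
  nets <- list(
    affiliative = social_network(count_matrix(log, c("physical_contact", "share")),
                                 directed = TRUE, behaviour = "affiliative"),
    agonistic = social_network(count_matrix(log, "agonistic"),
                               directed = TRUE, behaviour = "agonistic"),
    proximity = social_network(count_matrix(log, c("sit_close", "same_branch"),
                                            directed = FALSE),
                               directed = FALSE, behaviour = "proximity"))
  if (components) {
    nets$physical_contact <- social_network(count_matrix(log, "physical_contact"),
                                            directed = TRUE, behaviour = "physical_contact")
    nets$share <- social_network(count_matrix(log, "share"),
                                 directed = TRUE, behaviour = "share")
    nets$sit_close <- social_network(count_matrix(log, "sit_close", directed = FALSE),
                                     directed = FALSE, behaviour = "sit_close")
    nets$same_branch <- social_network(count_matrix(log, "same_branch", directed = FALSE),
                                       directed = FALSE, behaviour = "same_branch")
  }
  nets$dominance <- count_matrix(log, "agonistic")
  nets
}

#' Kinship network from an attribute table
#'
#' Sibling ties get weight 1, all other dyads 0.
#'
#' @param individuals Tibble with `id` and `kin_group`.
#' @return Undirected binary [social_network()].
#' @export
kinship_network <- function(individuals) {
  kg <- individuals$kin_group
  W <- outer(kg, kg, function(a, b) as.numeric(!is.na(a) & !is.na(b) & a == b))
  diag(W) <- 0
  social_network(W, directed = FALSE, behaviour = "kinship",
                 labels = individuals$id)
}

#' Spearman rank correlation
#'
#' Average-rank ties; two-tailed p by exhaustive permutation of one ranking
#' for n <= 9 and by the t approximation otherwise.
#'
#' @param x,y Numeric vectors (ranks or orders) of equal length >= 3.
#' @return Tibble with `rho`, `p_value`, `n`, `method`; `rho = NA` with
#'   method `"undefined"` when an input is constant.
#' @export
spearman_rank <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 3) abort("need at least 3 paired observations")
  ok <- complete.cases(x, y)
  if (sum(ok) < 3) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = sum(ok),
                          method = "undefined"))
  }
  x <- x[ok]; y <- y[ok]; n <- length(x)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(tibble::tibble(rho = NA_real_, p_value = NA_real_, n = n,
                          method = "undefined"))
  }
  rho <- cor(rx, ry)
  if (n <= 9) {
    PM <- all_permutations(n)
    ryp <- matrix(ry[PM], nrow(PM), n)
    # only sum(rx * permuted ry) varies across permutations
    s_perm <- as.numeric(ryp %*% rx)
    rho_perm <- (s_perm / n - mean(rx) * mean(ry)) /
      (stats::sd(rx) * stats::sd(ry) * (n - 1) / n)
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
    method <- "exact_permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t_approximation"
  }
  tibble::tibble(rho = rho, p_value = p, n = n, method = method)
}

# All permutations of 1..n as an n! x n index matrix.
all_permutations <- function(n) {
  P <- matrix(1L, 1, 1)
  for (k in 2:n) {
    old <- P
    P <- matrix(0L, nrow(old) * k, k)
    row <- 1L
    for (pos in seq_len(k)) {
      block <- cbind(old[, seq_len(pos - 1), drop = FALSE], k,
                     old[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
      P[seq(row, row + nrow(old) - 1), ] <- block
      row <- row + nrow(old)
    }
  }
  P
}

#' Contact-frequency regression
#'
#' Ordinary least squares of each individual's task-contact frequency on
#' its observation frequency, social rank and sex, with overall and
#' per-term F statistics.
#'
#' @param df Data frame with columns `contacts`, `observations`, `rank`,
#'   `sex` (factor or 0/1).
#' @return List of class `contact_regression` with `terms` (tibble: term,
#'   estimate, F, p) and `overall` (tibble: F, df1, df2, p, r_squared);
#'   `zero_model = TRUE` when contacts carry no variance.
#' @export
contact_observation_regression <- function(df) {
  if (nrow(df) < 5) abort("need at least 5 individuals")
  if (stats::sd(df$contacts) == 0) {
    return(structure(list(terms = NULL, overall = NULL, zero_model = TRUE),
                     class = "contact_regression"))
  }
  if (is.character(df$sex)) df$sex <- as.numeric(factor(df$sex)) - 1
  fit <- lm(contacts ~ observations + rank + sex, data = df)
  if (any(is.na(coef(fit)))) abort("collinear predictors in contact regression")
  sm <- summary(fit)
  tt <- sm$coefficients[-1, , drop = FALSE]
  terms <- tibble::tibble(term = rownames(tt), estimate = unname(tt[, 1]),
                          F = unname(tt[, 3]^2),    # single-df term: F = t^2
                          p = unname(tt[, 4]))
  fstat <- sm$fstatistic
  overall <- tibble::tibble(F = unname(fstat[1]), df1 = unname(fstat[2]),
                            df2 = unname(fstat[3]),
                            p = pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE),
                            r_squared = sm$r.squared)
  structure(list(terms = terms, overall = overall, zero_model = FALSE),
            class = "contact_regression")
}

#' Pipeline configuration
#'
#' @param permutations MRQAP permutations (default 10000).
#' @param mrqap_seed,isi_seed Seeds for the stochastic stages.
#' @param isi_restarts Restarts of the dominance ranking heuristic.
#' @param include_components Run OADA on component networks as well.
#' @param with_and_without_weights Fit OADA models under both weight flags.
#' @param ilv_pool ILVs entering the OADA model set.
#' @param pst_level Confidence level for %ST (or `NULL` to skip the CI).
#' @param stages Which stages to run.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(permutations = 10000, mrqap_seed = 1L,
                            isi_restarts = 100, isi_seed = 1L,
                            include_components = FALSE,
                            with_and_without_weights = TRUE,
                            ilv_pool = c("sex", "rank"),
                            pst_level = 0.95,
                            stages = c("networks", "dominance", "mrqap",
                                       "correlations", "oada")) {
  structure(list(permutations = permutations, mrqap_seed = mrqap_seed,
                 isi_restarts = isi_restarts, isi_seed = isi_seed,
                 include_components = include_components,
                 with_and_without_weights = with_and_without_weights,
                 ilv_pool = ilv_pool, pst_level = pst_level, stages = stages),
            class = "pipeline_config")
}

#' Run the full analysis pipeline for one group
#'
#' Networks and densities, dominance ranks, the five-predictor MRQAP on the
#' observation network, Spearman correlations between centrality ranks and
#' solving order / observation-network centrality, and the OADA model set
#' with support ratios, ILV total weights and %ST. Deterministic given the
#' config seeds.
#'
#' @param log An [event_log()] for the group.
#' @param diffusion A [diffusion_data()] or list of them (pooled for OADA).
#' @param observation List with `obs` and `solves_before` matrices (as from
#'   [simulate_observations()]), or `NULL` to skip MRQAP.
#' @param config A [pipeline_config()].
#' @return List of class `report_bundle`.
#' @export
run_pipeline <- function(log, diffusion, observation = NULL,
                         config = pipeline_config()) {
  stages <- config$stages
  demonstrator <- log$individuals$id[log$individuals$trained]
  if (length(demonstrator) != 1) {
    abort("pipeline runs require exactly one trained demonstrator per group")
  }
  if (inherits(diffusion, "diffusion_data")) diffusion <- list(diffusion)
  report <- list(group_id = log$group_id,
                 meta = list(config = unclass(config), demonstrator = demonstrator))

  nets <- build_group_networks(log, components = TRUE)
  dom_matrix <- nets$dominance
  nets$dominance <- NULL

  if ("networks" %in% stages) {
    report$densities <- purrr::map_dfr(nets, function(nw) {
      tibble::tibble(network = nw$behaviour, directed = nw$directed,
                     density = net_density(nw))
    })
  }

  rank_order <- NULL
  ranks <- NULL
  if ("dominance" %in% stages) {
    rank_order <- isi_rank(dom_matrix, restarts = config$isi_restarts,
                           seed = config$isi_seed)
    ranks <- ranks_from_order(rank_order)
    report$dominance <- rank_order
  }

  obs_net <- NULL
  if (!is.null(observation)) {
    obs_net <- suppressMessages(
      normalize_observation(observation$obs, observation$solves_before))
    report$observation_density <- net_density(obs_net)
  }

  if ("mrqap" %in% stages && !is.null(obs_net)) {
    if (is.null(ranks)) {
      rank_order <- isi_rank(dom_matrix, restarts = config$isi_restarts,
                             seed = config$isi_seed)
      ranks <- ranks_from_order(rank_order)
    }
    sex_sim <- similarity_matrix(setNames(log$individuals$sex, log$individuals$id),
                                 "categorical", behaviour = "sex_similarity")
    rank_sim <- similarity_matrix(ranks[log$individuals$id], "rank",
                                  behaviour = "rank_similarity")
    report$mrqap <- run_observation_mrqap(
      obs_net, nets$affiliative, nets$agonistic, nets$proximity,
      sex_sim, rank_sim,
      permutations = config$permutations, seed = config$mrqap_seed)
  }

  if ("correlations" %in% stages) {
    # solving order variable: 1 = first solver; never-solvers tied after all
    # solvers at the maximum rank; demonstrator excluded
    ids_nd <- setdiff(log$individuals$id, demonstrator)
    ord <- diffusion[[1]]$order
    solve_order <- setNames(rep(length(ord) + 1, length(ids_nd)), ids_nd)
    solve_order[intersect(ord, ids_nd)] <- match(intersect(ord, ids_nd), ord)
    measures <- c("out_strength", "in_strength", "eigenvector", "information")
    social_nets <- nets[c("affiliative", "agonistic", "proximity")]
    cent <- purrr::map(social_nets, centrality_table, exclude = demonstrator)
    report$centrality <- cent
    rows <- list()
    for (nm in names(cent)) {
      ct <- cent[[nm]]
      for (ms in measures) {
        r <- setNames(ct[[paste0(ms, "_rank")]], ct$id)[ids_nd]
        sp <- spearman_rank(r, solve_order[ids_nd])
        rows[[length(rows) + 1]] <- dplyr::mutate(sp, network = nm, measure = ms,
                                                  comparison = "solving_order",
                                                  .before = 1)
      }
    }
    if (!is.null(obs_net)) {
      obs_cent <- centrality_table(obs_net, exclude = demonstrator)
      for (nm in names(cent)) {
        ct <- cent[[nm]]
        for (ms in measures) {
          r1 <- setNames(ct[[paste0(ms, "_rank")]], ct$id)[ids_nd]
          r2 <- setNames(obs_cent[[paste0(ms, "_rank")]], obs_cent$id)[ids_nd]
          sp <- spearman_rank(r1, r2)
          rows[[length(rows) + 1]] <- dplyr::mutate(sp, network = nm, measure = ms,
                                                    comparison = "observation_network",
                                                    .before = 1)
        }
      }
    }
    spearman_tab <- dplyr::bind_rows(rows)
    spearman_tab$p_adjusted <- stats::p.adjust(spearman_tab$p_value, "BH")
    report$spearman <- spearman_tab
  }

  if ("oada" %in% stages) {
    if (is.null(ranks)) {
      rank_order <- isi_rank(dom_matrix, restarts = config$isi_restarts,
                             seed = config$isi_seed)
      ranks <- ranks_from_order(rank_order)
    }
    cand <- nets[c("affiliative", "agonistic", "proximity")]
    if (config$include_components) {
      cand <- c(cand, nets[c("physical_contact", "share", "sit_close", "same_branch")])
    }
    if (any(!is.na(log$individuals$kin_group))) {
      cand$kinship <- kinship_network(log$individuals)
    }
    ilvs <- cbind(sex = as.numeric(log$individuals$sex == "F"),
                  rank = as.numeric(ranks[log$individuals$id]))
    rownames(ilvs) <- log$individuals$id
    set <- fit_oada_set(diffusion, cand, ilvs = ilvs,
                        ilv_pool = config$ilv_pool,
                        with_and_without_weights = config$with_and_without_weights)
    report$oada <- set
    report$support_ratios <- purrr::map_dfr(names(cand), function(nm) {
      tibble::tibble(network = nm, support_ratio = support_ratio(set, nm))
    })
    report$ilv_weights <- purrr::map_dfr(config$ilv_pool, function(v) {
      tibble::tibble(ilv = v, total_weight_pct = ilv_total_weight(set, v))
    })
    fits <- attr(set, "fits")
    social_fits <- purrr::keep(fits, ~ !is.null(.x$network))
    if (length(social_fits)) {
      best <- social_fits[[which.min(purrr::map_dbl(social_fits, "AICc"))]]
      report$best_social_fit <- best
      report$s_hat <- best$s_hat
      report$pst <- percent_social(best, level = config$pst_level)
    }
  }

  structure(report, class = "report_bundle")
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("<report_bundle for group '%s'>\n", x$group_id))
  if (!is.null(x$densities)) {
    cat("network densities:\n"); print(x$densities)
  }
  if (!is.null(x$mrqap)) {
    cat("\nMRQAP (observation network):\n"); print(tidy(x$mrqap))
  }
  if (!is.null(x$support_ratios)) {
    cat("\nOADA support ratios:\n"); print(x$support_ratios)
  }
  if (!is.null(x$pst)) {
    cat(sprintf("\ns = %.3f; estimated %%ST = %.1f%%\n", x$s_hat, x$pst$pst))
  }
  invisible(x)
}

#' Write a report bundle to JSON
#'
#' @param report A `report_bundle`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  out <- list(
    group_id = report$group_id,
    densities = report$densities,
    observation_density = report$observation_density,
    dominance = if (!is.null(report$dominance)) {
      list(order = report$dominance$order, I = report$dominance$I,
           SI = report$dominance$SI, unresolved = report$dominance$unresolved)
    },
    mrqap = if (!is.null(report$mrqap)) {
      list(coefficients = tidy(report$mrqap), model = glance(report$mrqap))
    },
    spearman = report$spearman,
    centrality = if (!is.null(report$centrality))
      lapply(report$centrality, tibble::as_tibble),
    oada = if (!is.null(report$oada)) tibble::as_tibble(report$oada),
    support_ratios = report$support_ratios,
    ilv_weights = report$ilv_weights,
    s_hat = report$s_hat,
    pst = report$pst,
    meta = report$meta)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
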