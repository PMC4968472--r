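# MRQAP with double-Dekker semipartialling: regress the off-diagonal cells
# of a dependent network on those of several predictor networks, then assess
# each coefficient against a null built by node-permuting that predictor's
# residual matrix (residualized on the other predictors) and refitting.
# Node permutations preserve the row/column dependence structure of network
# data that cell-level permutation would destroy.

#' Off-diagonal vectorization of a network
#'
#' The n(n-1) off-diagonal cells in fixed row-major order (row 1 cells
#' first, diagonal skipped). The inverse is [devectorize_offdiag()].
#'
#' @param net A [social_network()] or square matrix.
#' @return Numeric vector of length n(n-1).
#' @export
vectorize_offdiag <- function(net) {
  W <- if (inherits(net, "social_network")) net$W else as.matrix(net)
  assert_square(W)
  tW <- t(W)
  tW[t(row(W) != col(W))]
}

#' @rdname vectorize_offdiag
#' @param v Numeric vector of length n(n-1).
#' @param n Matrix dimension.
#' @return `devectorize_offdiag()`: n x n matrix with zero diagonal.
#' @export
devectorize_offdiag <- function(v, n) {
  if (length(v) != n * (n - 1)) abort("length(v) must equal n(n-1)")
  M <- matrix(0, n, n)
  tM <- t(M)
  tM[t(row(M) != col(M))] <- v
  t(tM)
}

as_net_matrix <- function(x) {
  if (inherits(x, "social_network")) x$W else as.matrix(x)
}

#' MRQAP with double-Dekker semipartialling
#'
#' Point estimates are ordinary least squares of the vectorized dependent
#' network on the vectorized predictors (with intercept); inference for each
#' predictor permutes the rows and columns of its residual matrix by a
#' common node permutation and records the refitted coefficient. The p-value
#' counts permuted coefficients at least as extreme as the observed one,
#' with the observed statistic included in the null set, so
#' p >= 1/(permutations + 1).
#'
#' @param y Dependent [social_network()] (or matrix).
#' @param x Named list of predictor networks/matrices sharing `y`'s labels.
#' @param permutations Node permutations per predictor (default 10000, as
#'   commonly used for this test).
#' @param seed Integer seed controlling the permutations.
#' @param tails `"two"` (|beta| comparison) or `"one_positive"`.
#' @return Object of class `mrqap_result`; see [tidy.mrqap_result()].
#' @export
mrqap_dsp <- function(y, x, permutations = 10000, seed = 1L,
                      tails = c("two", "one_positive")) {
  tails <- match.arg(tails)
  if (permutations < 1) abort("`permutations` must be >= 1")
  Y <- as_net_matrix(y)
  Xs <- lapply(x, as_net_matrix)
  if (is.null(names(Xs)) || any(names(Xs) == "")) {
    names(Xs) <- paste0("x", seq_along(Xs))
  }
  n <- nrow(Y)
  if (any(vapply(Xs, nrow, 0L) != n)) abort("all matrices must share the same individuals")

  yv <- vectorize_offdiag(Y)
  Xv <- vapply(Xs, vectorize_offdiag, numeric(n * (n - 1)))
  p <- ncol(Xv)

  # collinearity guard on the off-diagonal cells
  qrX <- qr(cbind(1, Xv))
  if (qrX$rank < p + 1) {
    cm <- abs(stats::cor(Xv))
    diag(cm) <- 0
    pair <- which(cm == max(cm), arr.ind = TRUE)[1, ]
    abort(sprintf("predictors are collinear on off-diagonal cells (e.g. '%s' and '%s')",
                  names(Xs)[pair[1]], names(Xs)[pair[2]]))
  }

  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xv), yv)
  beta_raw <- fit$coefficients[-1]
  r2 <- 1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
  zscore <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  beta_std <- stats::lm.fit(cbind(1, apply(Xv, 2, zscore)), zscore(yv))$coefficients[-1]

  pvals <- numeric(p)
  with_seed(seed, {
    for (k in seq_len(p)) {
      others <- cbind(1, Xv[, -k, drop = FALSE])
      qo <- qr(others)
      e_k <- qr.resid(qo, Xv[, k])          # semipartialled predictor
      ry <- qr.resid(qo, yv)                # FWL: only residuals matter
      E_k <- devectorize_offdiag(e_k, n)
      beta_obs <- sum(e_k * ry) / sum(e_k^2)
      exceed <- 0L
      for (b in seq_len(permutations)) {
        perm <- sample.int(n)
        e_perm <- vectorize_offdiag(E_k[perm, perm])
        re <- qr.resid(qo, e_perm)
        beta_perm <- sum(re * ry) / sum(re^2)
        hit <- if (tails == "two") abs(beta_perm) >= abs(beta_obs) else beta_perm >= beta_obs
        exceed <- exceed + as.integer(hit)
      }
      pvals[k] <- (1 + exceed) / (1 + permutations)
    }
  })

  out <- tibble::tibble(term = names(Xs),
                        estimate = unname(beta_raw),
                        std_estimate = unname(beta_std),
                        p_value = pvals)
  structure(list(coefficients = out,
                 intercept = unname(fit$coefficients[1]),
                 r_squared = r2, n = n,
                 permutations = permutations, seed = seed, tails = tails),
            class = "mrqap_result")
}

#' @export
print.mrqap_result <- function(x, ...) {
  cat(sprintf("MRQAP (double-Dekker semipartialling), n = %d, %d permutations, %s-tailed\n",
              x$n, x$permutations, x$tails))
  print(x$coefficients)
  cat(sprintf("R-squared: %.3f\n", x$r_squared))
  invisible(x)
}

#' Tidy an MRQAP result
#'
#' @param x An `mrqap_result`.
#' @param ... Unused.
#' @return Tibble with one row per predictor: `term`, `estimate` (raw OLS),
#'   `std_estimate` (z-scored cells), `p_value`.
#' @method tidy mrqap_result
#' @export
tidy.mrqap_result <- function(x, ...) x$coefficients

#' @rdname tidy.mrqap_result
#' @method glance mrqap_result
#' @export
glance.mrqap_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, n = x$n,
                 permutations = x$permutations, tails = x$tails, seed = x$seed)
}

#' Observation-network regression
#'
#' The standard five-predictor MRQAP asking which social factors predict who
#' watched whom: affiliative interactions, agonistic interactions,
#' proximity, sex similarity and social-rank similarity.
#'
#' @param observation Directed observation [social_network()] (normalized by
#'   opportunity; see [normalize_observation()]).
#' @param affiliative,agonistic,proximity Predictor networks.
#' @param sex_similarity,rank_similarity Similarity networks from
#'   [similarity_matrix()].
#' @param ... Passed to [mrqap_dsp()] (`permutations`, `seed`, `tails`).
#' @return An `mrqap_result` with predictors in the conventional order.
#' @export
run_observation_mrqap <- function(observation, affiliative, agonistic,
                                  proximity, sex_similarity, rank_similarity,
                                  ...) {
  preds <- list(affiliative = affiliative, agonistic = agonistic,
                proximity = proximity, sex = sex_similarity,
                rank = rank_similarity)
  if (any(vapply(preds, is.null, TRUE))) {
    abort("all five predictor networks are required (affiliative, agonistic, proximity, sex, rank)")
  }
  mrqap_dsp(observation, preds, ...)
}
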