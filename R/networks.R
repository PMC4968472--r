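# Weighted social networks: container, observation-network normalization,
# density and the three centrality measures (strength, eigenvector,
# Stephenson-Zelen information centrality), plus similarity matrices used as
# MRQAP predictors.

#' Construct a social network
#'
#' A weighted social network over a labelled set of individuals. `W[i, j]`
#' is the tie from i toward j (initiated interactions, or i's observation of
#' j); undirected networks must be symmetric. The diagonal is structurally
#' zero (self-ties are undefined).
#'
#' @param W Nonnegative numeric square matrix. Dimnames supply labels unless
#'   `labels` is given.
#' @param directed Logical.
#' @param behaviour Label describing what the ties measure (e.g.
#'   `"affiliative"`, `"physical_contact"`, `"observation"`).
#' @param labels Optional character vector of individual ids.
#' @return An object of class `social_network`.
#' @export
social_network <- function(W, directed = TRUE, behaviour = "network",
                           labels = NULL) {
  W <- as.matrix(W)
  assert_square(W)
  if (nrow(W) < 2) abort("a social network needs at least 2 individuals")
  if (any(W < 0)) abort("tie weights must be nonnegative")
  if (is.null(labels)) labels <- rownames(W)
  if (is.null(labels)) labels <- paste0("ind", seq_len(nrow(W)))
  if (length(labels) != nrow(W)) abort("`labels` length must match matrix size")
  storage.mode(W) <- "double"
  dimnames(W) <- list(labels, labels)
  diag(W) <- 0
  if (!directed && !isTRUE(all.equal(W, t(W)))) {
    abort("undirected networks must have a symmetric weight matrix")
  }
  structure(list(labels = labels, W = W, directed = directed,
                 behaviour = behaviour),
            class = "social_network")
}

#' @export
print.social_network <- function(x, ...) {
  cat(sprintf("<social_network '%s': n = %d, %s, density = %.3f>\n",
              x$behaviour, length(x$labels),
              if (x$directed) "directed" else "undirected",
              net_density(x)))
  invisible(x)
}

#' Edge-list view of a social network
#'
#' @param x A [social_network()].
#' @param ... Unused.
#' @return Tibble with `from`, `to`, `weight` for nonzero ties (each
#'   unordered pair once for undirected networks).
#' @method tidy social_network
#' @export
tidy.social_network <- function(x, ...) {
  W <- x$W
  keep <- if (x$directed) W > 0 else upper.tri(W) & W > 0
  idx <- which(keep, arr.ind = TRUE)
  tibble::tibble(from = x$labels[idx[, 1]], to = x$labels[idx[, 2]],
                 weight = W[idx]) |>
    dplyr::arrange(.data$from, .data$to)
}

# Symmetrize a directed matrix by summing orientations; preserves total weight.
symmetrized <- function(net) {
  if (net$directed) net$W + t(net$W) else net$W
}

#' Normalize observation counts by opportunity
#'
#' Naive individuals differ in how many solving events they could have
#' watched, so raw observation counts are divided by opportunity: if j solved
#' X times before i's first solution and i watched Y of them, the tie i -> j
#' is Y/X. Cells with no opportunity (j never solved before i) are 0.
#'
#' @param obs Integer matrix, `obs[i, j]` = times naive i observed j solve
#'   before i's own first solution.
#' @param solves_before Integer matrix, `solves_before[i, j]` = j's solutions
#'   before i's first solution.
#' @return A directed [social_network()] with weights in `[0, 1]`.
#' @export
normalize_observation <- function(obs, solves_before) {
  obs <- as.matrix(obs); solves_before <- as.matrix(solves_before)
  assert_square(obs, "obs"); assert_square(solves_before, "solves_before")
  if (any(obs < 0) || any(solves_before < 0)) abort("counts must be nonnegative")
  if (any(obs > solves_before)) {
    abort("obs[i,j] cannot exceed solves_before[i,j] (cannot watch more solutions than occurred)")
  }
  n_no_opp <- sum(solves_before == 0 & row(obs) != col(obs))
  if (n_no_opp > 0) {
    inform(sprintf("%d dyads had no observation opportunity; their ties are set to 0", n_no_opp))
  }
  W <- ifelse(solves_before > 0, obs / solves_before, 0)
  diag(W) <- 0
  social_network(W, directed = TRUE, behaviour = "observation",
                 labels = rownames(obs))
}

#' Rescale a network to unit mean connection
#'
#' Divides all weights by the mean nonzero off-diagonal weight, so a
#' "typical" tie has strength 1. Useful when a per-unit-connection
#' parameter (such as the social-transmission rate s) should be read on an
#' interpretable scale; OADA support ratios are invariant to this
#' rescaling.
#'
#' @param net A [social_network()].
#' @return A [social_network()] with rescaled weights.
#' @export
scale_network <- function(net) {
  W <- net$W
  nz <- W[W > 0]
  if (length(nz)) net$W <- W / mean(nz)
  net
}

#' Network density
#'
#' Proportion of possible ties present: nonzero off-diagonal cells over
#' n(n-1) ordered dyads (directed) or n(n-1)/2 unordered dyads (undirected).
#'
#' @param net A [social_network()].
#' @return Proportion in `[0, 1]`.
#' @export
net_density <- function(net) {
  W <- net$W
  n <- nrow(W)
  if (net$directed) {
    sum(W[row(W) != col(W)] > 0) / (n * (n - 1))
  } else {
    sum(W[upper.tri(W)] > 0) / (n * (n - 1) / 2)
  }
}

#' Strength (weighted degree)
#'
#' Out-strength is the summed weight of ties an individual initiates
#' (row sums), in-strength the summed weight it receives (column sums); the
#' two coincide for undirected networks.
#'
#' @param net A [social_network()].
#' @return Tibble with `id`, `out_strength`, `in_strength`.
#' @export
strength <- function(net) {
  tibble::tibble(id = net$labels,
                 out_strength = unname(rowSums(net$W)),
                 in_strength = unname(colSums(net$W)))
}

#' Eigenvector centrality
#'
#' Principal-eigenvector scores of the symmetrized weight matrix
#' (S = W + t(W) for directed input), computed by power iteration from a
#' uniform start vector and normalized to unit maximum. An individual is
#' central when it is strongly tied to other central individuals.
#'
#' @param net A [social_network()].
#' @param tol Relative convergence tolerance of the power iteration.
#' @return Tibble with `id`, `eigenvector`.
#' @export
eigenvector_centrality <- function(net, tol = 1e-10) {
  S <- symmetrized(net)
  n <- nrow(S)
  if (all(S == 0)) return(tibble::tibble(id = net$labels, eigenvector = rep(0, n)))
  if (!is_connected(S)) {
    warn("network is disconnected; eigenvector scores outside the dominant component are ~0")
  }
  # small shift keeps the iteration convergent when the spectrum has
  # symmetric extremes (e.g. bipartite graphs)
  shift <- max(rowSums(S)) * 1e-3
  v <- rep(1 / n, n)
  for (iter in seq_len(100000L)) {
    v_new <- S %*% v + shift * v
    v_new <- v_new / sqrt(sum(v_new^2))
    if (max(abs(v_new - v)) <= tol * max(abs(v_new))) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v <- as.numeric(v)
  v <- abs(v) / max(abs(v))
  tibble::tibble(id = net$labels, eigenvector = v)
}

is_connected <- function(S) {
  n <- nrow(S)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nb <- which(colSums(S[frontier, , drop = FALSE] > 0) > 0 & !seen)
    seen[nb] <- TRUE
    frontier <- nb
  }
  all(seen)
}

#' Stephenson-Zelen information centrality
#'
#' Measures how much information can reach an individual over all network
#' paths, not just the strongest one. With S the symmetrized weights,
#' D = diag(row sums), B = D - S + J (J all ones) and C = B^-1, the score is
#' 1 / (C_ii + (T - 2 R_i)/n) with T = trace-sum of C's diagonal and
#' R_i = i's row sum of C.
#'
#' @param net A [social_network()]; its symmetrization must be connected.
#' @return Tibble with `id`, `information`.
#' @export
information_centrality <- function(net) {
  S <- symmetrized(net)
  n <- nrow(S)
  if (!is_connected(S)) {
    abort(paste("information centrality requires a connected (symmetrized) network;",
                "restrict the network to its largest component first"))
  }
  B <- diag(rowSums(S)) - S + matrix(1, n, n)
  C <- solve(B)
  T_diag <- sum(diag(C))
  R <- rowSums(C)
  score <- 1 / (diag(C) + (T_diag - 2 * R) / n)
  tibble::tibble(id = net$labels, information = unname(score))
}

# Information centrality tolerant of disconnected networks: scores on the
# largest component, NA elsewhere (a node cut off from the main component
# has no defined information flow to it).
information_centrality_components <- function(net) {
  S <- symmetrized(net)
  if (is_connected(S)) return(information_centrality(net))
  comp <- components_of(S)
  main <- which(comp == which.max(tabulate(comp)))
  out <- tibble::tibble(id = net$labels, information = NA_real_)
  if (length(main) >= 2) {
    sub <- social_network(S[main, main, drop = FALSE], directed = FALSE,
                          behaviour = net$behaviour)
    sc <- information_centrality(sub)
    out$information[main] <- sc$information
    warn(sprintf("network '%s' is disconnected; information centrality computed on the largest component (%d of %d individuals)",
                 net$behaviour, length(main), length(net$labels)))
  }
  out
}

# Connected-component labels of a symmetric adjacency matrix.
components_of <- function(S) {
  n <- nrow(S)
  comp <- rep(0L, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0) next
    cur <- cur + 1L
    frontier <- start
    comp[start] <- cur
    while (length(frontier)) {
      nb <- which(colSums(S[frontier, , drop = FALSE] > 0) > 0 & comp == 0L)
      comp[nb] <- cur
      frontier <- nb
    }
  }
  comp
}

#' Group-relative centrality ranks
#'
#' Ranks a centrality vector within the group, rank 1 = most central, ties
#' averaged. The trained demonstrator is excluded from rank-correlation
#' analyses, hence the `exclude` argument.
#'
#' @param values Named numeric vector (names = ids) or tibble with `id` and
#'   one value column.
#' @param exclude Ids to drop before ranking.
#' @return Tibble with `id`, `value`, `rank` over the non-excluded set.
#' @export
rank_centralities <- function(values, exclude = character()) {
  if (is.data.frame(values)) {
    val_col <- setdiff(names(values), "id")[1]
    v <- setNames(values[[val_col]], values$id)
  } else {
    v <- values
  }
  if (is.null(names(v))) abort("`values` must carry individual ids as names")
  bad <- setdiff(exclude, names(v))
  if (length(bad)) abort(sprintf("unknown id(s) in `exclude`: %s", toString(bad)))
  v <- v[setdiff(names(v), exclude)]
  tibble::tibble(id = names(v), value = unname(v), rank = unname(rank_desc(v)))
}

#' Full centrality table for a network
#'
#' Computes out/in-strength, eigenvector and information centrality and
#' their group-relative ranks (1 = most central, average ties).
#'
#' @param net A [social_network()].
#' @param exclude Ids excluded from the ranking (e.g. the demonstrator).
#' @return Tibble of class `centrality_table`: one row per (non-excluded)
#'   individual with value and rank columns per measure.
#' @export
centrality_table <- function(net, exclude = character()) {
  tab <- strength(net) |>
    dplyr::left_join(eigenvector_centrality(net), by = "id") |>
    dplyr::left_join(information_centrality_components(net), by = "id") |>
    dplyr::filter(!(.data$id %in% exclude))
  out <- tab |>
    dplyr::mutate(dplyr::across(c("out_strength", "in_strength",
                                  "eigenvector", "information"),
                                rank_desc, .names = "{.col}_rank"))
  attr(out, "behaviour") <- net$behaviour
  class(out) <- c("centrality_table", class(out))
  out
}

#' Similarity matrix from an individual attribute
#'
#' Builds the homophily predictors used in the network regression:
#' categorical similarity is 1 for identical values and 0 otherwise (e.g.
#' same sex); rank similarity is linear in rank distance,
#' `(n - 1 - |r_i - r_j|) / (n - 1)`, i.e. 1 for adjacent-or-equal ranks and
#' 0 for the maximal separation.
#'
#' @param attribute Named vector of per-individual values (names = ids).
#' @param kind `"categorical"` or `"rank"` (for `"rank"`, values are ranks
#'   `1..n`).
#' @param behaviour Label for the resulting network.
#' @return An undirected [social_network()].
#' @export
similarity_matrix <- function(attribute, kind = c("categorical", "rank"),
                              behaviour = NULL) {
  kind <- match.arg(kind)
  if (is.null(names(attribute))) abort("`attribute` must be named by individual id")
  n <- length(attribute)
  W <- if (kind == "categorical") {
    outer(attribute, attribute, FUN = function(a, b) as.numeric(a == b))
  } else {
    r <- as.numeric(attribute)
    (n - 1 - abs(outer(r, r, "-"))) / (n - 1)
  }
  diag(W) <- 0
  social_network(W, directed = FALSE,
                 behaviour = behaviour %||% paste0(kind, "_similarity"),
                 labels = names(attribute))
}

#' Read / write a TSV adjacency matrix
#'
#' The interchange format for network matrices: a TSV with individual ids as
#' both header row and first column.
#'
#' @param net A [social_network()].
#' @param path File path.
#' @return `write_network()` returns `net` invisibly; `read_network()`
#'   returns a [social_network()].
#' @export
write_network <- function(net, path) {
  df <- tibble::as_tibble(net$W, .name_repair = "minimal")
  df <- dplyr::bind_cols(tibble::tibble(id = net$labels), df)
  readr::write_tsv(df, path)
  invisible(net)
}

#' @rdname write_network
#' @param directed,behaviour Metadata for the network being read.
#' @export
read_network <- function(path, directed = TRUE, behaviour = "network") {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  labels <- as.character(df[[1]])
  W <- as.matrix(df[, -1])
  social_network(W, directed = directed, behaviour = behaviour, labels = labels)
}
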