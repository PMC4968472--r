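# Linear dominance hierarchy by the I&SI method: find an order of
# individuals minimizing, lexicographically, the number of inconsistent
# dyads (I) and then their summed rank distance (SI). A dyad (i above j) is
# inconsistent iff j won the dyad by strict majority of retreats
# (D[j, i] > D[i, j]); tied dyads (including 0-0) are neither consistent nor
# inconsistent.

# (I, SI) objective for an order given the retreat matrix. `order_idx` is a
# permutation of row indices, position 1 = most dominant.
isi_objective <- function(D, order_idx) {
  Dp <- D[order_idx, order_idx, drop = FALSE]
  upper <- upper.tri(Dp)
  incons <- upper & (t(Dp) > Dp)   # lower-ranked beats higher-ranked
  I <- sum(incons)
  SI <- if (I > 0) sum(abs(row(Dp)[incons] - col(Dp)[incons])) else 0L
  c(I = I, SI = SI)
}

lex_better <- function(a, b) a[1] < b[1] || (a[1] == b[1] && a[2] < b[2])

# Local search from one start: all pairwise position swaps plus all
# single-element insertions (remove and reinsert elsewhere), accepting any
# strict lexicographic improvement, until a full sweep yields none. Swaps
# alone can strand the search in local optima that an insertion escapes.
isi_local_search <- function(D, order_idx) {
  best <- isi_objective(D, order_idx)
  n <- length(order_idx)
  repeat {
    improved <- FALSE
    for (a in seq_len(n - 1)) {
      for (b in seq(a + 1, n)) {
        cand <- order_idx
        cand[c(a, b)] <- cand[c(b, a)]
        obj <- isi_objective(D, cand)
        if (lex_better(obj, best)) {
          order_idx <- cand
          best <- obj
          improved <- TRUE
        }
      }
    }
    for (a in seq_len(n)) {
      for (b in seq_len(n)) {
        if (a == b) next
        cand <- append(order_idx[-a], order_idx[a], after = b - 1)
        obj <- isi_objective(D, cand)
        if (lex_better(obj, best)) {
          order_idx <- cand
          best <- obj
          improved <- TRUE
        }
      }
    }
    if (!improved) break
  }
  list(order = order_idx, obj = best)
}

#' I&SI dominance ranking
#'
#' Heuristic minimization of (I, SI) over orders: one start by descending
#' number of dyads won plus `restarts` random shuffles, each refined by
#' swap-based local search; the best order across starts is returned.
#'
#' @param D Nonnegative integer matrix; `D[i, j]` = times j retreated after
#'   i's threat (i dominates j). Dimnames supply ids.
#' @param restarts Number of random restarts (default 100).
#' @param seed Integer seed for the random restarts (required for
#'   reproducibility).
#' @return Object of class `rank_order`: list with `order` (ids, position
#'   1 = most dominant), `I`, `SI`, `unresolved` (TRUE when D carries no
#'   information), and the winning restart index.
#' @export
isi_rank <- function(D, restarts = 100, seed = 1L) {
  D <- as.matrix(D)
  assert_square(D, "D")
  n <- nrow(D)
  if (n < 2) abort("need at least 2 individuals to rank")
  if (any(D < 0)) abort("retreat counts must be nonnegative")
  labels <- rownames(D) %||% paste0("ind", seq_len(n))
  diag(D) <- 0

  wins <- rowSums(D > t(D))
  starts <- list(order(wins, decreasing = TRUE))
  starts <- c(starts, with_seed(seed, lapply(seq_len(restarts),
                                             function(i) sample.int(n))))
  best <- NULL
  best_start <- NA_integer_
  for (k in seq_along(starts)) {
    res <- isi_local_search(D, starts[[k]])
    if (is.null(best) || lex_better(res$obj, best$obj)) {
      best <- res
      best_start <- k
    }
  }
  structure(
    list(order = labels[best$order],
         I = unname(best$obj[1]), SI = unname(best$obj[2]),
         unresolved = all(D == 0), start_index = best_start,
         restarts = restarts, seed = seed),
    class = "rank_order"
  )
}

#' @export
print.rank_order <- function(x, ...) {
  cat(sprintf("<rank_order: %s | I = %d, SI = %d%s>\n",
              paste(x$order, collapse = " > "), x$I, x$SI,
              if (x$unresolved) " (unresolved: no agonistic data)" else ""))
  invisible(x)
}

#' Per-individual ranks from a dominance order
#'
#' @param order A `rank_order` from [isi_rank()] or a character vector of
#'   ids, most dominant first.
#' @return Named integer vector of ranks (1 = most dominant), usable as the
#'   social-rank covariate and for rank-similarity matrices.
#' @export
ranks_from_order <- function(order) {
  ids <- if (inherits(order, "rank_order")) order$order else as.character(order)
  setNames(seq_along(ids), ids)
}
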