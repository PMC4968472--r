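# Independent oracles and fixture builders. Everything here is written
# deliberately "dumb" (loops, closed forms, base R) and never calls the
# code path it checks.

# all permutations of 1..n, one per row (recursive construction)
perms_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_of(n - 1)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# (I, SI) of an order by direct double loop
isi_obj_slow <- function(D, ord) {
  n <- length(ord)
  I <- 0L; SI <- 0L
  for (a in seq_len(n - 1)) {
    for (b in seq(a + 1, n)) {
      i <- ord[a]; j <- ord[b]          # i ranked above j
      if (D[j, i] > D[i, j]) {
        I <- I + 1L
        SI <- SI + (b - a)
      }
    }
  }
  c(I = I, SI = SI)
}

# exhaustive lexicographic minimum of (I, SI)
brute_isi <- function(D) {
  n <- nrow(D)
  P <- perms_of(n)
  best <- c(Inf, Inf)
  for (r in seq_len(nrow(P))) {
    obj <- isi_obj_slow(D, P[r, ])
    if (obj[1] < best[1] || (obj[1] == best[1] && obj[2] < best[2])) best <- obj
  }
  best
}

# probability of one complete acquisition order under the OADA model,
# computed by explicit per-event loops (unweighted social term)
oada_order_prob_slow <- function(ord, ids, seeded, W, s, beta = NULL, X = NULL) {
  informed <- ids %in% seeded
  names(informed) <- ids
  prob <- 1
  for (i_k in ord) {
    naive <- ids[!informed]
    R <- sapply(naive, function(i) {
      Ti <- sum(W[i, ids[informed]])
      mult <- if (is.null(beta)) 1 else exp(sum(X[i, ] * beta))
      (1 + s * Ti) * mult
    })
    prob <- prob * R[[i_k]] / sum(R)
    informed[i_k] <- TRUE
  }
  prob
}

# diffusion_data for a complete order with all-zero solve counts (valid for
# unweighted models, where counts never enter the likelihood)
diffusion_for_order <- function(ord, ids, seeded) {
  diffusion_data(order = ord, ids = ids, seeded = seeded,
                 solve_counts_before = matrix(0, length(ord), length(ids),
                                              dimnames = list(NULL, ids)))
}

# random connected symmetric weighted graph
rand_connected_graph <- function(n, p_edge = 0.5) {
  repeat {
    W <- matrix(0, n, n)
    ut <- upper.tri(W)
    w <- ifelse(runif(sum(ut)) < p_edge, rgamma(sum(ut), 2, 1), 0)
    W[ut] <- w
    W <- W + t(W)
    # BFS connectivity check
    seen <- c(1L); frontier <- 1L
    while (length(frontier)) {
      nb <- setdiff(which(colSums(W[frontier, , drop = FALSE] > 0) > 0), seen)
      seen <- c(seen, nb); frontier <- nb
    }
    if (length(seen) == n) {
      dimnames(W) <- list(paste0("i", 1:n), paste0("i", 1:n))
      return(W)
    }
  }
}

# minimal valid attribute table
make_individuals <- function(ids, sex = NULL, trained_id = ids[1],
                             age_class = "subadult", kin = NA_integer_) {
  tibble::tibble(id = ids,
                 sex = sex %||% rep(c("F", "M"), length.out = length(ids)),
                 age_class = age_class,
                 kin_group = rep(kin, length.out = length(ids)),
                 trained = ids == trained_id)
}

make_events <- function(day, actor, receiver, behaviour,
                        record_kind = NULL) {
  record_kind <- record_kind %||%
    ifelse(behaviour %in% c("sit_close", "same_branch"), "scan", "all_occurrence")
  tibble::tibble(day = as.Date(day), actor = actor, receiver = receiver,
                 behaviour = behaviour, record_kind = record_kind)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
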