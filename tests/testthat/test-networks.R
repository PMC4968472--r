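test_that("observation normalization divides counts by opportunity", {
  ids <- c("A", "B", "C")
  obs <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  sol <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  obs["A", "B"] <- 3L; sol["A", "B"] <- 6L
  sol["A", "C"] <- 4L                       # watched none of 4 solutions
  # B never solved before C: zero opportunity cell stays zero, with a note
  expect_message(net <- normalize_observation(obs, sol), "no observation opportunity")
  expect_equal(net$W["A", "B"], 0.5)
  expect_equal(net$W["A", "C"], 0)
  expect_equal(net$W["C", "B"], 0)
  expect_true(net$directed)

  expect_error(normalize_observation(obs * -1L, sol), "nonnegative")
  obs2 <- obs; obs2["A", "B"] <- 10L
  expect_error(normalize_observation(obs2, sol), "cannot exceed")

  # bounded in [0, 1] for any valid counts
  set.seed(5)
  for (i in 1:20) {
    sol <- matrix(rpois(16, 4), 4, 4)
    obs <- matrix(rbinom(16, sol, 0.5), 4, 4)
    diag(obs) <- diag(sol) <- 0L
    W <- suppressMessages(normalize_observation(obs, sol))$W
    expect_true(all(W >= 0 & W <= 1))
  }
})

test_that("density counts present ties among possible dyads", {
  W3 <- matrix(1, 3, 3); diag(W3) <- 0
  expect_equal(net_density(social_network(W3, directed = TRUE)), 1)
  expect_equal(net_density(social_network(matrix(0, 4, 4), directed = TRUE)), 0)

  # 40 nonzero off-diagonal cells among 12*11 = 132
  set.seed(9)
  W <- matrix(0, 12, 12)
  off <- which(row(W) != col(W))
  W[sample(off, 40)] <- runif(40, 0.5, 3)
  net <- social_network(W, directed = TRUE)
  expect_equal(net_density(net), sum(W[off] > 0) / 132)
  expect_equal(net_density(net), 40 / 132)
  # density ignores the weight scale
  net10 <- social_network(W * 10, directed = TRUE)
  expect_equal(net_density(net10), net_density(net))

  # undirected: each unordered pair counted once
  Wu <- matrix(0, 4, 4); Wu[1, 2] <- Wu[2, 1] <- 2
  expect_equal(net_density(social_network(Wu, directed = FALSE)), 1 / 6)
})

test_that("strength sums initiated and received weights", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("A", "B", "C")), 2))
  W["A", "B"] <- 2; W["A", "C"] <- 1
  st <- strength(social_network(W, directed = TRUE))
  expect_equal(st$out_strength[st$id == "A"], 3)
  expect_equal(st$in_strength[st$id == "A"], 0)
  expect_equal(st$in_strength[st$id == "B"], 2)
  # conservation: total out = total in = total weight
  expect_equal(sum(st$out_strength), sum(st$in_strength))
  expect_equal(sum(st$out_strength), sum(W))

  sym <- social_network(W + t(W), directed = FALSE)
  sts <- strength(sym)
  expect_equal(sts$out_strength, sts$in_strength)
})

test_that("eigenvector centrality matches the eigen-decomposition oracle", {
  # ring of 4: all equal by symmetry
  ring <- matrix(0, 4, 4)
  for (i in 1:4) ring[i, i %% 4 + 1] <- ring[i %% 4 + 1, i] <- 1
  ec <- eigenvector_centrality(social_network(ring, directed = FALSE))
  expect_equal(ec$eigenvector, rep(1, 4))

  # star: leaf/center ratio is 1/sqrt(k) for k leaves
  star <- matrix(0, 4, 4); star[1, 2:4] <- star[2:4, 1] <- 1
  ec <- eigenvector_centrality(social_network(star, directed = FALSE))
  expect_equal(ec$eigenvector[1], 1)
  expect_equal(ec$eigenvector[2:4], rep(1 / sqrt(3), 3), tolerance = 1e-8)

  # scale invariance
  set.seed(31)
  W <- rand_connected_graph(6)
  e1 <- eigenvector_centrality(social_network(W, directed = FALSE))
  e2 <- eigenvector_centrality(social_network(W * 10, directed = FALSE))
  expect_equal(e1$eigenvector, e2$eigenvector, tolerance = 1e-8)

  # oracle property: random connected graphs vs direct eigen-decomposition
  for (i in 1:20) {
    n <- sample(3:8, 1)
    W <- rand_connected_graph(n)
    got <- eigenvector_centrality(social_network(W, directed = FALSE))$eigenvector
    ev <- eigen(W, symmetric = TRUE)$vectors[, 1]
    want <- abs(ev) / max(abs(ev))
    expect_equal(got, want, tolerance = 1e-6)
  }

  # directed input symmetrized as W + t(W)
  Wd <- matrix(0, 3, 3); Wd[1, 2] <- 4; Wd[2, 3] <- 2
  got <- eigenvector_centrality(social_network(Wd, directed = TRUE))$eigenvector
  S <- Wd + t(Wd)
  ev <- eigen(S, symmetric = TRUE)$vectors[, 1]
  expect_equal(got, abs(ev) / max(abs(ev)), tolerance = 1e-6)
})

test_that("information centrality follows the Stephenson-Zelen inverse", {
  # complete graph: all equal
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  ic <- information_centrality(social_network(K4, directed = FALSE))
  expect_equal(ic$information, rep(ic$information[1], 4))

  # path A-B-C: middle node most central, ends equal
  P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
  ic <- information_centrality(social_network(P, directed = FALSE))
  expect_gt(ic$information[2], ic$information[1])
  expect_equal(ic$information[1], ic$information[3], tolerance = 1e-10)

  # oracle: harmonic-mean form over pairwise information, same C = B^-1
  set.seed(13)
  for (i in 1:15) {
    n <- sample(3:8, 1)
    W <- rand_connected_graph(n)
    got <- information_centrality(social_network(W, directed = FALSE))$information
    B <- diag(rowSums(W)) - W + matrix(1, n, n)
    C <- solve(B)
    # harmonic mean of pairwise information 1/(C_ii + C_jj - 2 C_ij), with
    # the self term contributing zero resistance
    want <- sapply(1:n, function(i) {
      denom <- sum(sapply(setdiff(1:n, i),
                          function(j) C[i, i] + C[j, j] - 2 * C[i, j]))
      n / denom
    })
    expect_equal(got, want, tolerance = 1e-8)
  }

  # disconnected network refused with guidance
  D <- matrix(0, 4, 4); D[1, 2] <- D[2, 1] <- D[3, 4] <- D[4, 3] <- 1
  expect_error(information_centrality(social_network(D, directed = FALSE)),
               "largest component")
})

test_that("centrality ranking averages ties and honours exclusions", {
  v <- c(A = 5, B = 3, C = 1)
  expect_equal(rank_centralities(v)$rank, c(1, 2, 3))
  expect_equal(rank_centralities(c(A = 5, B = 5, C = 1))$rank, c(1.5, 1.5, 3))
  r <- rank_centralities(v, exclude = "A")
  expect_equal(r$id, c("B", "C"))
  expect_equal(r$rank, c(1, 2))
  expect_error(rank_centralities(v, exclude = "Z"), "unknown id")
})

test_that("similarity matrices encode homophily predictors", {
  sexes <- c(A = "F", B = "F", C = "M")
  S <- similarity_matrix(sexes, "categorical")
  expect_equal(S$W["A", "B"], 1)
  expect_equal(S$W["A", "C"], 0)
  expect_false(S$directed)

  # two individuals one rank apart: similarity 0 at n = 2
  expect_equal(similarity_matrix(c(A = 1, B = 2), "rank")$W["A", "B"], 0)
  R <- similarity_matrix(c(A = 1, B = 2, C = 3, D = 4), "rank")$W
  expect_equal(R["A", "B"], 2 / 3)   # adjacent ranks
  expect_equal(R["A", "D"], 0)       # maximal separation
  # ranks are a permutation, so off-diagonal rank similarity is always < 1
  expect_true(all(R[row(R) != col(R)] < 1))
})

test_that("network TSV round trip and edge-list view are faithful", {
  set.seed(2)
  W <- matrix(rpois(25, 1), 5, 5); diag(W) <- 0
  net <- social_network(W, directed = TRUE, behaviour = "affiliative",
                        labels = letters[1:5])
  f <- tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- read_network(f, directed = TRUE, behaviour = "affiliative")
  expect_equal(back$W, net$W)
  expect_equal(back$labels, net$labels)

  el <- tidy(net)
  expect_equal(nrow(el), sum(W > 0))
  expect_equal(sum(el$weight), sum(W))
})
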