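# ids and a small fully-specified world used throughout
small_world <- function(n = 4, seed = 99) {
  set.seed(seed)
  ids <- paste0("i", 1:n)
  W <- rand_connected_graph(n)
  dimnames(W) <- list(ids, ids)
  list(ids = ids, net = social_network(W, directed = FALSE, behaviour = "aff"))
}

test_that("the asocial null makes every order equally likely", {
  w <- small_world(4)
  naive <- w$ids[-1]
  d <- diffusion_for_order(naive, w$ids, seeded = w$ids[1])
  ll <- oada_loglik(d, network = NULL, s = 0)
  expect_equal(ll, -log(factorial(3)))
  # probability of each order is 1/m!
  expect_equal(exp(ll), 1 / 6)
})

test_that("order probabilities sum to one and match the slow oracle", {
  w <- small_world(5, seed = 23)
  seeded <- w$ids[1]
  naive <- w$ids[-1]
  P <- perms_of(4)
  set.seed(41)
  for (draw in 1:5) {
    s <- rexp(1, 1 / 5)
    X <- matrix(rnorm(5), 5, 1, dimnames = list(w$ids, "z"))
    beta <- rnorm(1)
    tot <- 0
    for (r in seq_len(nrow(P))) {
      ord <- naive[P[r, ]]
      d <- diffusion_for_order(ord, w$ids, seeded)
      ll <- oada_loglik(d, w$net, s = s, beta = beta, ilvs = X)
      tot <- tot + exp(ll)
      if (r == 1) {
        # direct product-of-ratios oracle for one fixed order
        expect_equal(exp(ll),
                     oada_order_prob_slow(ord, w$ids, seeded, w$net$W, s,
                                          beta = beta, X = X),
                     tolerance = 1e-12)
      }
    }
    expect_equal(tot, 1, tolerance = 1e-10)
  }
})

test_that("an isolated social path dominates as s grows", {
  ids <- c("D", "A", "B", "C")
  W <- matrix(0, 4, 4, dimnames = list(ids, ids))
  W["A", "D"] <- W["D", "A"] <- 1     # only A is connected to the demonstrator
  net <- social_network(W, directed = FALSE)
  d <- diffusion_for_order(c("A", "B", "C"), ids, "D")
  # first-event probability for A approaches 1
  p_first <- function(s) {
    R <- c(A = 1 + s, B = 1, C = 1)
    R[["A"]] / sum(R)
  }
  ll <- oada_loglik(d, net, s = 1e8)
  expect_equal(exp(ll), p_first(1e8) * 1 / 2, tolerance = 1e-6)
  expect_gt(p_first(1e8), 0.9999)
})

test_that("exposure bookkeeping honours weights, masks and locality", {
  ids <- c("A", "B", "C")
  W <- matrix(1, 3, 3); diag(W) <- 0; dimnames(W) <- list(ids, ids)
  net <- social_network(W, directed = FALSE)
  scb <- rbind(c(A = 10, B = 0, C = 0), c(A = 12, B = 1, C = 0))
  d <- diffusion_data(order = c("B", "C"), ids = ids, seeded = "A",
                      solve_counts_before = scb,
                      solve_counts_final = c(A = 15, B = 3, C = 1))
  Tm_cum <- corvnet:::social_exposure(d, net, use_weights = TRUE, "cumulative")
  expect_equal(unname(Tm_cum[1, "B"]), 10)       # A's 10 solves reach naive B
  expect_equal(unname(Tm_cum[2, "C"]), 12 + 1)   # A grew to 12, B adds 1
  Tm_tot <- corvnet:::social_exposure(d, net, use_weights = TRUE, "total")
  expect_equal(unname(Tm_tot[1, "B"]), 15)
  expect_equal(unname(Tm_tot[2, "C"]), 15 + 3)
  Tm_unw <- corvnet:::social_exposure(d, net, use_weights = FALSE)
  expect_equal(unname(Tm_unw[1, "B"]), 1)
  expect_equal(unname(Tm_unw[2, "C"]), 2)

  # separation zeroes the social term from the stated event onward
  d2 <- diffusion_data(order = c("B", "C"), ids = ids, seeded = "A",
                       solve_counts_before = scb,
                       separated_from = c(C = 2L))
  Tm <- corvnet:::social_exposure(d2, net, use_weights = FALSE)
  expect_equal(unname(Tm[2, "C"]), 0)
  expect_equal(unname(Tm[1, "C"]), 1)

  # locality: dropping a never-solver leaves others' exposures unchanged
  ids4 <- c(ids, "Z")
  W4 <- matrix(1, 4, 4); diag(W4) <- 0; dimnames(W4) <- list(ids4, ids4)
  scb4 <- cbind(scb, Z = c(0, 0))
  d4 <- diffusion_data(order = c("B", "C"), ids = ids4, seeded = "A",
                       solve_counts_before = scb4)
  Tm4 <- corvnet:::social_exposure(d4, social_network(W4, directed = FALSE),
                                   use_weights = TRUE, "cumulative")
  expect_equal(Tm4[, ids], Tm_cum)
})

test_that("diffusion data validates its invariants", {
  ids <- c("A", "B", "C")
  scb <- matrix(0, 2, 3, dimnames = list(NULL, ids))
  expect_error(diffusion_data(c("A", "B"), ids, "A", scb), "seeded")
  expect_error(diffusion_data(c("B", "B"), ids, "A", scb), "at most once")
  expect_error(diffusion_data(c("B", "X"), ids, "A", scb), "unknown id")
  bad <- scb; bad[, "C"] <- 2    # naive with nonzero solves (non-decreasing)
  expect_error(diffusion_data(c("B", "C"), ids, "A", bad), "naive")
  bad <- rbind(c(A = 5, B = 0, C = 0), c(A = 3, B = 1, C = 0))
  expect_error(diffusion_data(c("B", "C"), ids, "A", bad), "non-decreasing")
})

test_that("fitting recovers the asocial closed form and respects nesting", {
  w <- small_world(5, seed = 3)
  set.seed(6)
  sims <- lapply(1:6, function(i)
    simulate_diffusion(w$net, s = 3, demonstrator = w$ids[1],
                       use_weights = FALSE, seed = i)$data)
  aso <- fit_oada(sims, network = NULL)
  m_k <- unlist(lapply(sims, function(d) seq(length(d$ids) - 1, 2)))
  expect_equal(aso$logLik, -sum(log(m_k)))
  expect_equal(aso$k, 0L)
  expect_equal(aso$AICc, -2 * aso$logLik)   # null model: k = 0

  soc <- fit_oada(sims, w$net, use_weights = FALSE)
  expect_gte(soc$logLik, aso$logLik - 1e-8)
  expect_gte(soc$s_hat, 0)
  expect_equal(soc$k, 1L)
  # AICc definition
  m <- soc$m
  expect_equal(soc$AICc, -2 * soc$logLik + 2 + 4 / (m - 2))
})

test_that("ILV coefficients are recovered from asocial diffusions", {
  ids <- paste0("i", 1:6)
  W0 <- matrix(0, 6, 6, dimnames = list(ids, ids))
  W0[1, 2] <- W0[2, 1] <- 1e-12   # effectively empty network
  net0 <- social_network(W0, directed = FALSE)
  X <- matrix(rep(c(1, 0), each = 3), 6, 1, dimnames = list(ids, "sex"))
  sims <- lapply(1:40, function(i)
    simulate_diffusion(net0, s = 0, demonstrator = ids[1],
                       beta = 1.5, ilvs = X, seed = 100 + i)$data)
  fit <- fit_oada(sims, network = NULL, ilvs = X, ilv_set = "sex")
  expect_equal(unname(fit$beta_hat["sex"]), 1.5, tolerance = 0.5)
})

test_that("model enumeration counts specs and flags duplicates", {
  w <- small_world(4)
  nets <- list(a = w$net, b = w$net, c = w$net)
  specs <- enumerate_models(nets, c("sex", "rank"), TRUE)
  expect_equal(nrow(specs), 3 * 2 * 4 + 4)    # 24 social + 4 asocial
  specs1 <- enumerate_models(nets["a"], character(), FALSE)
  expect_equal(nrow(specs1), 2)               # 1 social + 1 null
  names(nets) <- c("a", "a", "c")
  expect_error(enumerate_models(nets, character()), "duplicate")
})

test_that("Akaike weights follow the closed form", {
  expect_equal(akaike_weights(c(100, 102)),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(round(akaike_weights(c(100, 102)), 3), c(0.731, 0.269))
  expect_equal(akaike_weights(c(5, 5, 5)), rep(1 / 3, 3))
  expect_equal(akaike_weights(42), 1)
  # invariance to a constant shift
  expect_equal(akaike_weights(c(10, 13, 17)), akaike_weights(c(110, 113, 117)))
})

test_that("support ratios and ILV weights aggregate model evidence", {
  fake_set <- function(network, ilvs, weight) {
    structure(tibble::tibble(network = network, ilvs = ilvs,
                             akaike_weight = weight),
              class = c("oada_model_set", class(tibble::tibble())))
  }
  # one social and one asocial model with equal support -> ratio 1
  s1 <- fake_set(c("aff", "asocial"), c("", ""), c(0.5, 0.5))
  expect_equal(support_ratio(s1, "aff"), 1)
  expect_equal(support_ratio(s1, "prox"), 0)
  # ILV bookkeeping
  s2 <- fake_set(c("aff", "aff", "asocial"), c("sex", "sex+rank", "sex"),
                 c(0.2, 0.3, 0.5))
  expect_equal(ilv_total_weight(s2, "sex"), 100)
  expect_equal(ilv_total_weight(s2, "rank"), 30)
  expect_equal(ilv_total_weight(s2, "kin"), 0)
  # zero asocial support
  s3 <- fake_set(c("aff", "asocial"), c("", ""), c(1, 0))
  expect_warning(expect_equal(support_ratio(s3, "aff"), Inf), "zero numerical")
})

test_that("percent social transmission follows s T / (1 + s T)", {
  # asocial fit: zero by definition
  w <- small_world(5, seed = 9)
  sims <- lapply(1:4, function(i)
    simulate_diffusion(w$net, s = 2, demonstrator = w$ids[1],
                       use_weights = FALSE, seed = i)$data)
  aso <- fit_oada(sims, network = NULL)
  expect_equal(percent_social(aso)$pst, 0)

  # single event with s T = 1 gives exactly 50%
  fit <- structure(list(s_hat = 1, beta_hat = numeric(0),
                        network = w$net, use_weights = FALSE,
                        weight_mode = "cumulative",
                        data = sims[1],
                        precomp = list(list(Tm = matrix(c(1, 0), 1, 2),
                                            acq = cbind(1, 1)))),
                   class = "oada_fit")
  expect_equal(percent_social(fit, level = NULL)$pst, 50)
})

test_that("the profile interval hits the boundary for asocial data", {
  w <- small_world(6, seed = 15)
  sims <- lapply(1:10, function(i)
    simulate_diffusion(w$net, s = 0, demonstrator = w$ids[1], seed = 50 + i)$data)
  fit <- fit_oada(sims, w$net, use_weights = FALSE)
  ci <- profile_ci_s(fit)
  expect_equal(ci$lower, 0)
  expect_gte(ci$upper, fit$s_hat)
})

test_that("model sets rank the generative network first", {
  cfg <- group_config(seed = 33)
  g <- generate_group(cfg)
  nets <- build_group_networks(g$log)
  aff <- scale_network(nets$affiliative)
  sims <- lapply(1:12, function(i)
    simulate_diffusion(aff, s = 7.76, demonstrator = cfg$demonstrator,
                       use_weights = FALSE, seed = 300 + i)$data)
  set <- fit_oada_set(sims, nets[c("affiliative", "agonistic", "proximity")],
                      with_and_without_weights = FALSE)
  expect_equal(sum(set$akaike_weight), 1, tolerance = 1e-12)
  srs <- vapply(c("affiliative", "agonistic", "proximity"),
                function(nm) support_ratio(set, nm), 0)
  expect_equal(names(which.max(srs)), "affiliative")
  # glance/tidy surfaces
  best <- attr(set, "fits")[[1]]
  expect_s3_class(glance(best), "tbl_df")
  expect_true("s" %in% tidy(best)$term || best$network_label == "asocial")
})

test_that("diffusion data round-trips through the CSV interchange format", {
  ids <- c("A", "B", "C", "D")
  scb <- rbind(c(A = 10, B = 0, C = 0, D = 0),
               c(A = 12, B = 1, C = 0, D = 0))
  d <- diffusion_data(order = c("B", "C"), ids = ids, seeded = "A",
                      solve_counts_before = scb)
  ef <- tempfile(fileext = ".csv"); cf <- tempfile(fileext = ".csv")
  write_diffusion_csv(d, ef, cf)
  back <- read_diffusion_csv(ef, cf)
  expect_equal(back$order, d$order)
  expect_equal(back$seeded, d$seeded)
  expect_equal(back$solve_counts_before, d$solve_counts_before)
  expect_setequal(back$ids, d$ids)
})
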