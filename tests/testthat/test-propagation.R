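test_that("degree normalization matches hand-computed transition matrices", {
  W <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(normalize_transition(W), matrix(c(0, 1, 1, 0), 2, 2))

  W2 <- matrix(c(1, 0, 1, 1), 2, 2)  # rows (1,1),(0,1): Dr=(2,1), Dc=(1,2)
  expect_equal(normalize_transition(W2),
               matrix(c(1 / sqrt(2), 0, 1 / 2, 1 / sqrt(2)), 2, 2))

  expect_equal(normalize_transition(matrix(0, 3, 3)), matrix(0, 3, 3))
  expect_error(normalize_transition(matrix(-1, 2, 2)),
               class = "drugprop_validation_error")

  # symmetric inputs have spectral radius at most 1
  set.seed(41)
  for (rep in 1:5) {
    S <- normalize_transition(random_symmetric_network(20))
    expect_lte(max(abs(eigen(S, only.values = TRUE)$values)), 1 + 1e-12)
  }
})

test_that("single-network propagation traps at alpha 0 and matches the linear solve", {
  S <- matrix(c(0, 1, 1, 0), 2, 2)
  res <- propagate_single(S, c(1, 0), alpha = 0)
  expect_identical(res$p, c(1, 0))
  expect_equal(res$iterations, 1)

  res2 <- propagate_single(S, c(1, 0), alpha = 0.5, tol = 1e-12)
  expect_equal(res2$p, c(2 / 3, 1 / 3), tolerance = 1e-9)

  # self-weight-only network normalizes to the identity: p0 is a fixed point
  expect_equal(propagate_single(diag(3), c(0.2, 0.3, 0.5), alpha = 0.8)$p,
               c(0.2, 0.3, 0.5))

  expect_error(propagate_single(S, c(1, 0), alpha = 0.999, max_iter = 3),
               class = "drugprop_convergence_error")
})

test_that("iteration residuals contract geometrically on normalized networks", {
  set.seed(43)
  S <- normalize_transition(random_symmetric_network(30))
  p <- p0 <- c(1, numeric(29))
  alpha <- 0.7
  residuals <- numeric(25)
  for (t in 1:25) {
    p_new <- (1 - alpha) * p0 + alpha * drop(S %*% p)
    residuals[t] <- sqrt(sum((p_new - p)^2))
    p <- p_new
  }
  expect_true(all(diff(residuals) <= 1e-15))
})

test_that("enriched initialization mixes with a = 1 - k*alpha in both modes", {
  # k = 1, alpha = 0.5: equal split, coefficients sum to one
  nb <- list(list(S = diag(2), p0 = c(0, 1)))
  expect_equal(enriched_initial(c(1, 0), nb, 0.5, "strict"), c(0.5, 0.5))

  # alpha = 0 leaves the initial vector unchanged
  expect_equal(enriched_initial(c(0.3, 0.7), nb, 0, "strict"), c(0.3, 0.7))

  # accepted strict configurations satisfy a + k*alpha = 1 with a >= 0: with
  # unit vectors everywhere the output is 1, exactly so at dyadic alphas
  for (k in 0:3) for (alpha in c(0, 0.25, 0.5)) {
    if (k * alpha > 1) next
    nbs <- replicate(k, list(S = diag(1), p0 = 1), simplify = FALSE)
    expect_identical(enriched_initial(1, nbs, alpha, "strict"), 1)
  }
  nbs3 <- replicate(3, list(S = diag(1), p0 = 1), simplify = FALSE)
  expect_equal(enriched_initial(1, nbs3, 0.3, "strict"), 1, tolerance = 1e-15)

  # k = 2, alpha = 0.7: strict rejects, literal uses a = -0.4 as written
  nb2 <- replicate(2, list(S = diag(1), p0 = 0), simplify = FALSE)
  expect_error(enriched_initial(1, nb2, 0.7, "strict"),
               class = "drugprop_config_error")
  expect_equal(enriched_initial(1, nb2, 0.7, "literal"), -0.4)
})

test_that("integrated propagation with all alphas zero returns the query indicator", {
  net <- toy_network("chain")
  cfg <- diffusion_config(alpha = c(drug = 0, gene = 0, phenotype = 0))
  state <- propagate_integrated(net, "P1", cfg)
  expect_identical(unname(state$vectors$phenotype), c(1, 0))
  expect_identical(unname(state$vectors$drug), c(0, 0))
  expect_identical(unname(state$vectors$gene), c(0, 0))
  expect_true(state$converged)
})

test_that("integrated propagation matches the dense coupled-system oracle", {
  alpha <- c(drug = 0.2, gene = 0.2, phenotype = 0.2)
  for (variant in c("chain", "twin", "ones")) {
    net <- toy_network(variant)
    cfg <- diffusion_config(alpha = alpha, coefficient_mode = "strict")
    state <- propagate_integrated(net, "P1", cfg)
    oracle <- coupled_oracle(net, "P1", alpha)
    for (kd in c("drug", "gene", "phenotype")) {
      expect_lt(max(abs(state$vectors[[kd]] - oracle[[kd]])), 1e-8)
    }
  }
})

test_that("iterative inner loops agree with the direct solver", {
  net <- toy_network("chain")
  cfg_direct <- diffusion_config(alpha = c(drug = 0.2, gene = 0.2, phenotype = 0.2),
                                 coefficient_mode = "strict")
  cfg_iter <- diffusion_config(alpha = c(drug = 0.2, gene = 0.2, phenotype = 0.2),
                               coefficient_mode = "strict", tol = 1e-12,
                               direct_solver = FALSE)
  s1 <- propagate_integrated(net, "P1", cfg_direct)
  s2 <- propagate_integrated(net, "P1", cfg_iter)
  expect_equal(s1$vectors, s2$vectors, tolerance = 1e-8)
})

test_that("the chain toy ranks the linked drug above the unlinked one", {
  net <- toy_network("chain")
  state <- propagate_integrated(net, "P1",
                                diffusion_config(alpha = c(drug = 0.3, gene = 0.3,
                                                           phenotype = 0.3),
                                                 coefficient_mode = "strict"))
  expect_gt(state$vectors$drug["D1"], state$vectors$drug["D2"])
})

test_that("twin drugs with identical connectivity get identical probabilities", {
  net <- toy_network("twin")
  state <- propagate_integrated(net, "P1")
  expect_equal(unname(state$vectors$drug["D1"]), unname(state$vectors$drug["D2"]),
               tolerance = 1e-12)
})

test_that("relabeling nodes permutes outputs identically", {
  fx <- generate_fixture(small_fixture_spec(seed = 5))
  net <- fx$network
  state <- propagate_integrated(net, fx$query)
  set.seed(6)
  perm_d <- sample(length(net$drug$node_ids))
  perm_g <- sample(length(net$gene$node_ids))
  perm_p <- sample(length(net$phenotype$node_ids))
  net_perm <- permute_integrated(net, perm_d, perm_g, perm_p)
  state_perm <- propagate_integrated(net_perm, fx$query)
  for (kd in c("drug", "gene", "phenotype")) {
    expect_equal(state_perm$vectors[[kd]][names(state$vectors[[kd]])],
                 state$vectors[[kd]], tolerance = 1e-9)
  }
})

test_that("unknown query phenotypes and strict-mode violations are rejected", {
  net <- toy_network("chain")
  expect_error(propagate_integrated(net, "P99"),
               class = "drugprop_validation_error")
  cfg <- diffusion_config(alpha = c(drug = 0.1, gene = 0.7, phenotype = 0.3),
                          coefficient_mode = "strict")
  expect_error(propagate_integrated(net, "P1", cfg), "gene",
               class = "drugprop_config_error")
})
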