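test_that("tanimoto coefficient matches set arithmetic and is symmetric", {
  a <- fingerprint("a", c(1, 2, 3))
  expect_equal(tanimoto_similarity(a, fingerprint("b", c(1, 2, 3))), 1)
  expect_equal(tanimoto_similarity(a, fingerprint("b", c(9, 10))), 0)
  expect_equal(tanimoto_similarity(a, fingerprint("b", c(2, 3, 4))), 0.5)
  expect_error(tanimoto_similarity(fingerprint("a", integer(0)),
                                   fingerprint("b", integer(0))),
               class = "drugprop_validation_error")

  # symmetry and identity on random bit sets
  set.seed(11)
  for (rep in 1:20) {
    x <- fingerprint("x", sample.int(64, sample(1:20, 1)))
    y <- fingerprint("y", sample.int(64, sample(1:20, 1)))
    expect_identical(tanimoto_similarity(x, y), tanimoto_similarity(y, x))
    expect_equal(tanimoto_similarity(x, y) == 1, setequal(x$bits, y$bits))
  }
})

test_that("drug network holds pairwise Tanimoto weights with zero diagonal", {
  two <- list(fingerprint("D1", 1:5), fingerprint("D2", 1:5))
  net <- build_drug_network(two)
  expect_equal(unname(net$weights), matrix(c(0, 1, 1, 0), 2, 2))

  disjoint <- list(fingerprint("D1", 1:3), fingerprint("D2", 4:6),
                   fingerprint("D3", 7:9))
  expect_true(all(build_drug_network(disjoint)$weights == 0))

  thirds <- list(fingerprint("D1", c(1, 2)), fingerprint("D2", c(2, 3)),
                 fingerprint("D3", c(1, 3)))
  W <- build_drug_network(thirds)$weights
  expect_equal(unname(W[upper.tri(W)]), rep(1 / 3, 3))

  expect_error(build_drug_network(list(fingerprint("D1", 1:3),
                                       fingerprint("D9", integer(0)))),
               "D9", class = "drugprop_validation_error")
})

test_that("logistic transform evaluates, bounds and orders as documented", {
  p <- logistic_params()
  expect_equal(logistic_transform(-p$d / p$c, p), 0.5)
  expect_equal(logistic_transform(0, p), 1e-4)
  expect_equal(logistic_transform(1, p), 1 / (1 + exp(-15 + log(9999))))
  expect_equal(round(logistic_transform(1, p), 4), 0.997)
  expect_error(logistic_transform(1.5, p), class = "drugprop_validation_error")
  expect_error(logistic_params(c = 2), class = "drugprop_validation_error")

  # strictly increasing, bounded in (0, 1)
  xs <- seq(0, 1, by = 0.01)
  ys <- logistic_transform(xs, p)
  expect_true(all(diff(ys) > 0))
  expect_true(all(ys > 0 & ys < 1))
})

test_that("phenotype network transforms off-diagonals monotonically", {
  ids <- c("P1", "P2", "P3")
  raw <- matrix(0, 3, 3, dimnames = list(ids, ids))
  net <- build_phenotype_network(raw)
  off <- net$weights[upper.tri(net$weights)]
  expect_true(all(off == logistic_transform(0)))
  expect_true(all(diag(net$weights) == 0))

  raw["P1", "P2"] <- raw["P2", "P1"] <- 0.6
  raw["P1", "P3"] <- raw["P3", "P1"] <- 0.3
  net <- build_phenotype_network(raw)
  expect_gt(net$weights["P1", "P2"], net$weights["P1", "P3"])

  # midpoint parameters fix the midpoint value
  mid <- logistic_params(c = -10, d = 5)  # -d/c = 0.5
  raw2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(unname(build_phenotype_network(raw2, mid)$weights),
               matrix(c(0, 0.5, 0.5, 0), 2, 2))

  raw["P1", "P2"] <- 0.9  # break symmetry
  expect_error(build_phenotype_network(raw), class = "drugprop_validation_error")
})

test_that("coexpression weight is |r| times summed absolute expression change", {
  expect_equal(coexpression_weight(0, 5, 1, 7, 2), 0)
  expect_equal(coexpression_weight(1, 3, 3, 8, 8), 0)
  expect_equal(coexpression_weight(-0.5, 2, 1, 0, 2), 1.5)
  expect_error(coexpression_weight(NA, 1, 1, 1, 1),
               class = "drugprop_validation_error")
})

test_that("gene network weights PIN edges by case correlation and differential expression", {
  # perfectly correlated case values, case means (3,3), control means (1,1)
  values <- rbind(G1 = c(2, 3, 4, 1, 1, 1),
                  G2 = c(2, 3, 4, 1, 1, 1))
  expr <- expression_profile(c("G1", "G2"), values,
                             c("case", "case", "case", "control", "control", "control"))
  net <- build_gene_network(data.frame(from = "G1", to = "G2"), expr)
  expect_equal(net$weights["G1", "G2"], 4)
  expect_equal(attr(net, "pin_edges"),
               data.frame(from = "G1", to = "G2", stringsAsFactors = FALSE))

  # gene constant across case samples: undefined correlation, weight 0 + warning
  values2 <- rbind(G1 = c(1, 1, 1, 0, 2, 0), G2 = c(2, 3, 4, 1, 1, 1))
  expr2 <- expression_profile(c("G1", "G2"), values2,
                              c("case", "case", "case", "control", "control", "control"))
  expect_warning(net2 <- build_gene_network(data.frame(from = "G1", to = "G2"), expr2),
                 "zero case-sample variance")
  expect_equal(net2$weights["G1", "G2"], 0)

  # no PIN edges: isolated expression genes
  net3 <- build_gene_network(data.frame(from = character(0), to = character(0)),
                             expr)
  expect_equal(net3$node_ids, c("G1", "G2"))
  expect_true(all(net3$weights == 0))

  # equal case/control means and any correlations give the zero matrix
  set.seed(21)
  vals <- matrix(rnorm(5 * 6), 5)
  vals[, 4:6] <- vals[, 1:3]  # control block identical to case block
  expr4 <- expression_profile(sprintf("G%d", 1:5), vals,
                              rep(c("case", "control"), each = 3))
  edges4 <- data.frame(from = c("G1", "G2", "G3"), to = c("G2", "G3", "G4"))
  expect_true(all(build_gene_network(edges4, expr4)$weights == 0))
})

test_that("hetero links are binary over the given universes", {
  h <- build_hetero(data.frame(from = "D1", to = "G1"),
                    c("D1", "D2"), c("G1", "G2"), "drug", "gene")
  expect_equal(unname(h$links), matrix(c(1, 0, 0, 0), 2, 2))

  h2 <- build_hetero(data.frame(from = c("D1", "D1"), to = c("G1", "G1")),
                     c("D1", "D2"), c("G1", "G2"), "drug", "gene")
  expect_equal(h2$links["D1", "G1"], 1)

  expect_message(
    h3 <- build_hetero(data.frame(from = c("D1", "DX"), to = c("G1", "G1")),
                       c("D1", "D2"), c("G1", "G2"), "drug", "gene"),
    "unknown ids")
  expect_equal(sum(h3$links), 1)

  expect_error(build_hetero(data.frame(from = "DX", to = "GX"),
                            c("D1"), c("G1"), "drug", "gene"),
               class = "drugprop_validation_error")

  # weighted mode preserves positive weights
  hw <- build_hetero(data.frame(from = "D1", to = "G1", weight = 0.7),
                     c("D1", "D2"), c("G1", "G2"), "drug", "gene",
                     weighted = TRUE)
  expect_equal(hw$links["D1", "G1"], 0.7)
})

test_that("sink smoothing gives orphans uniform 1/(n-1) connections", {
  ids <- sprintf("G%d", 1:4)
  W <- matrix(0, 4, 4, dimnames = list(ids, ids))
  W[1, 2] <- W[2, 1] <- 3
  net <- homo_network(ids, W, "gene")

  # G5 added as an orphan among n = 5 genes: 4 edges of weight 0.25
  expect_message(attach_orphans(net, c("G1", "G5")), "added 1")
  out <- suppressMessages(attach_orphans(net, c("G1", "G5")))
  expect_equal(unname(out$weights["G5", setdiff(out$node_ids, "G5")]),
               rep(0.25, 4))
  expect_equal(attr(out, "orphans"), "G5")

  # no orphans: unchanged
  same <- attach_orphans(net, "G1")
  expect_equal(same$weights, net$weights)

  # two orphans: both smoothed, matrix symmetric
  out2 <- attach_orphans(net, c("G3", "G4"))
  expect_equal(unname(out2$weights["G3", c("G1", "G2", "G4")]), rep(1 / 3, 3))
  expect_identical(out2$weights, t(out2$weights))
})

test_that("built homo-networks are symmetric and non-negative", {
  set.seed(31)
  fps <- lapply(1:8, function(i) fingerprint(sprintf("D%d", i), sample.int(64, 12)))
  for (net in list(build_drug_network(fps),
                   build_phenotype_network(
                     local({
                       m <- matrix(runif(25, 0, 1), 5)
                       m <- (m + t(m)) / 2
                       dimnames(m) <- list(letters[1:5], letters[1:5])
                       m
                     })))) {
    expect_true(all(net$weights >= 0))
    expect_lt(max(abs(net$weights - t(net$weights))), 1e-12)
  }
})
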