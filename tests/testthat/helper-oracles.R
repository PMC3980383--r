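# Independent oracles and small generators shared across test files.

# Closed-form steady state of single-network propagation: the fixed point of
# p = (1 - alpha) p0 + alpha S p, by dense linear solve.
closed_form_single <- function(S, p0, alpha) {
  drop((1 - alpha) * solve(diag(nrow(S)) - alpha * S, p0))
}

# Dense one-shot solve of the coupled integrated system: unknowns are the
# stacked converged vectors x = (drug, gene, phenotype) satisfying
#   (I - a_i S_i) x_i - a_i * sum_j S_ij x_j = (1 - a_i)(1 - k_i a_i) p_i^0.
# Completely independent of the package's sweep iteration.
coupled_oracle <- function(net, query, alpha) {
  Sd <- normalize_transition(net$drug$weights)
  Sg <- normalize_transition(net$gene$weights)
  Sp <- normalize_transition(net$phenotype$weights)
  Sdg <- normalize_transition(net$drug_gene$links)
  Spg <- normalize_transition(net$phenotype_gene$links)
  nd <- nrow(Sd); ng <- nrow(Sg); np <- nrow(Sp)
  k <- c(drug = 1, gene = 2, phenotype = 1)
  idx_d <- seq_len(nd); idx_g <- nd + seq_len(ng); idx_p <- nd + ng + seq_len(np)
  A <- matrix(0, nd + ng + np, nd + ng + np)
  A[idx_d, idx_d] <- diag(nd) - alpha["drug"] * Sd
  A[idx_g, idx_g] <- diag(ng) - alpha["gene"] * Sg
  A[idx_p, idx_p] <- diag(np) - alpha["phenotype"] * Sp
  A[idx_d, idx_g] <- -alpha["drug"] * Sdg
  A[idx_g, idx_d] <- -alpha["gene"] * t(Sdg)
  A[idx_g, idx_p] <- -alpha["gene"] * t(Spg)
  A[idx_p, idx_g] <- -alpha["phenotype"] * Spg
  p0 <- numeric(nd + ng + np)
  p0[idx_p[match(query, net$phenotype$node_ids)]] <- 1 / length(query)
  b <- numeric(nd + ng + np)
  b[idx_d] <- (1 - alpha["drug"]) * (1 - k["drug"] * alpha["drug"]) * p0[idx_d]
  b[idx_g] <- (1 - alpha["gene"]) * (1 - k["gene"] * alpha["gene"]) * p0[idx_g]
  b[idx_p] <- (1 - alpha["phenotype"]) * (1 - k["phenotype"] * alpha["phenotype"]) * p0[idx_p]
  x <- solve(A, b)
  list(drug = stats::setNames(x[idx_d], net$drug$node_ids),
       gene = stats::setNames(x[idx_g], net$gene$node_ids),
       phenotype = stats::setNames(x[idx_p], net$phenotype$node_ids))
}

# All-pairs concordance count: the brute-force AUC oracle.
brute_force_auc <- function(scores, positive_ids) {
  lab <- names(scores) %in% positive_ids
  pos <- scores[lab]; neg <- scores[!lab]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Random symmetric non-negative weight matrix with zero diagonal.
random_symmetric_network <- function(n, density = 0.2) {
  W <- matrix(0, n, n)
  idx <- which(upper.tri(W))
  on <- sample(idx, max(1, round(density * length(idx))))
  W[on] <- runif(length(on), 0.1, 2)
  W <- W + t(W)
  W
}

# Apply a permutation of node order to every layer of an integrated network.
permute_integrated <- function(net, perm_d, perm_g, perm_p) {
  permute_homo <- function(h, perm) {
    out <- homo_network(h$node_ids[perm], h$weights[perm, perm], h$kind)
    attr(out, "pin_edges") <- attr(h, "pin_edges")
    attr(out, "orphans") <- attr(h, "orphans")
    out
  }
  drug <- permute_homo(net$drug, perm_d)
  gene <- permute_homo(net$gene, perm_g)
  phen <- permute_homo(net$phenotype, perm_p)
  dg <- hetero_network(drug$node_ids, gene$node_ids,
                       net$drug_gene$links[perm_d, perm_g, drop = FALSE],
                       "drug", "gene")
  pg <- hetero_network(phen$node_ids, gene$node_ids,
                       net$phenotype_gene$links[perm_p, perm_g, drop = FALSE],
                       "phenotype", "gene")
  integrated_network(drug, gene, phen, dg, pg, net$config)
}

# Shrunk fixture used where full study-condition sizes are not needed.
small_fixture_spec <- function(seed, ...) {
  fixture_spec(n_drugs = 20, n_genes = 60, n_phenotypes = 8, n_case = 6,
               n_ctrl = 6, module_size = 10, n_positive_drugs = 5,
               seed = seed, ...)
}

run_pipeline_auc <- function(fx, alpha = c(drug = 0.1, gene = 0.7, phenotype = 0.3),
                             mode = "literal") {
  cfg <- diffusion_config(alpha = alpha, coefficient_mode = mode)
  state <- propagate_integrated(fx$network, fx$query, cfg)
  ref <- reference_state(fx$network, fx$query, cfg)
  rk <- rank_drugs(state, ref)
  roc_auc(stats::setNames(rk$z, rk$drug_id), fx$benchmark)$auc
}
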