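# Degree normalization and the single-network / integrated propagation.

#' Normalize a weight matrix into a transition matrix
#'
#' `S[i, j] = W[i, j] / sqrt(Dr[i] * Dc[j])` where `Dr` and `Dc` hold the row
#' and column sums of `W`. For a symmetric homo-network this is the usual
#' symmetric normalization with spectral radius at most 1, so propagation
#' contracts; for a bipartite hetero-network the two diagonals differ. Rows
#' or columns summing to zero map to zero (no division error).
#'
#' @param W Non-negative numeric matrix (square or rectangular).
#'
#' @return Matrix `S` of the same shape and dimnames.
#' @export
normalize_transition <- function(W) {
  W <- as.matrix(W)
  if (anyNA(W) || any(W < 0)) {
    dp_validation_error("weight matrix must be non-negative for normalization")
  }
  dr <- rowSums(W)
  dc <- colSums(W)
  denom <- sqrt(outer(dr, dc))
  S <- matrix(0, nrow(W), ncol(W), dimnames = dimnames(W))
  ok <- denom > 0
  S[ok] <- W[ok] / denom[ok]
  S
}

l2 <- function(x) sqrt(sum(x^2))

#' Propagate probability on a single network
#'
#' Iterates `p_t = (1 - alpha) * p0 + alpha * S %*% p_{t-1}` until the L2
#' difference between consecutive iterates falls below `tol`. With
#' `alpha = 0` the walker is trapped at the initial nodes and the iteration
#' stops immediately at `p0`.
#'
#' @param S Square transition matrix from [normalize_transition()].
#' @param p0 Non-negative initial probability vector.
#' @param alpha Diffusion parameter in `[0, 1)`.
#' @param tol Convergence threshold (L2). Default `1e-9`.
#' @param max_iter Iteration cap. Default `10000`.
#'
#' @return List with elements `p` (converged vector, named like `p0`) and
#'   `iterations`.
#' @export
propagate_single <- function(S, p0, alpha, tol = 1e-9, max_iter = 10000L) {
  S <- as.matrix(S)
  if (nrow(S) != ncol(S)) dp_validation_error("propagate_single needs a square matrix")
  if (length(p0) != nrow(S)) dp_validation_error("p0 length must match the matrix dimension")
  if (any(p0 < 0)) dp_validation_error("p0 must be non-negative")
  if (alpha < 0 || alpha >= 1) dp_config_error("alpha must lie in [0, 1)")
  restart <- (1 - alpha) * p0
  p <- p0
  for (it in seq_len(max_iter)) {
    p_new <- restart + alpha * drop(S %*% p)
    res <- l2(p_new - p)
    p <- p_new
    if (res < tol) {
      names(p) <- names(p0)
      return(list(p = p, iterations = it))
    }
  }
  dp_convergence_error(
    sprintf("single-network propagation did not converge in %d iterations (residual %.3e)",
            max_iter, res),
    residual = res, level = "single")
}

#' Enriched initial distribution from neighboring networks
#'
#' Replaces a network's initial vector by the weighted sum
#' `a * p_i0 + alpha_i * sum_j S_ij %*% p_j0` with `a = 1 - k * alpha_i`,
#' where `k` is the number of attached hetero-networks, so that the mixing
#' coefficients satisfy `a + k * alpha_i = 1`. In `strict` mode a negative
#' `a` is rejected; in `literal` mode the coefficient is used as written
#' (the reported best gene setting `alpha = 0.7`, `k = 2` gives `a = -0.4`).
#'
#' @param p_i0 Initial vector of the network itself.
#' @param neighbor_inputs List of `list(S, p0)` pairs: the normalized
#'   hetero-network transition matrix mapping the neighbor into this network,
#'   and the neighbor's initial vector.
#' @param alpha_i Diffusion parameter of this network.
#' @param mode `"literal"` or `"strict"`.
#' @param kind Network name used in error messages.
#'
#' @return The enriched initial vector.
#' @export
enriched_initial <- function(p_i0, neighbor_inputs, alpha_i,
                             mode = c("literal", "strict"), kind = "network") {
  mode <- match.arg(mode)
  k <- length(neighbor_inputs)
  a <- 1 - k * alpha_i
  if (mode == "strict" && a < 0) {
    dp_config_error(sprintf(
      "strict mode: %s has k = %d attached hetero-networks and alpha = %g, so a = %g < 0",
      kind, k, alpha_i, a))
  }
  out <- a * p_i0
  for (ni in neighbor_inputs) {
    out <- out + alpha_i * drop(ni$S %*% ni$p0)
  }
  out
}

# Shared plumbing: normalized matrices, layout-derived k, coefficient checks.
integrated_operators <- function(net, config) {
  S <- list(drug = normalize_transition(net$drug$weights),
            gene = normalize_transition(net$gene$weights),
            phenotype = normalize_transition(net$phenotype$weights))
  S_dg <- normalize_transition(net$drug_gene$links)
  S_pg <- normalize_transition(net$phenotype_gene$links)
  # neighbor operators: matrices mapping a neighbor's vector into each network
  neighbors <- list(
    drug = list(list(kind = "gene", M = S_dg)),
    phenotype = list(list(kind = "gene", M = S_pg)),
    gene = list(list(kind = "drug", M = t(S_dg)),
                list(kind = "phenotype", M = t(S_pg)))
  )
  k <- if (!is.null(config$k)) {
    config$k[c("drug", "gene", "phenotype")]
  } else {
    vapply(neighbors[c("drug", "gene", "phenotype")], length, 0L)
  }
  names(k) <- c("drug", "gene", "phenotype")
  a <- 1 - k * config$alpha
  if (config$coefficient_mode == "strict" && any(a < 0)) {
    bad <- names(a)[which(a < 0)[1]]
    dp_config_error(sprintf(
      "strict mode: network '%s' has a = 1 - k*alpha = %g < 0 (k = %d, alpha = %g)",
      bad, a[bad], k[bad], config$alpha[bad]))
  }
  list(S = S, neighbors = neighbors, k = k, a = a)
}

solve_inner <- function(S, alpha, r, config, kind) {
  n <- nrow(S)
  if (config$direct_solver && n < 2000) {
    # exact fixed point of p = r + alpha * S p; identical limit as iteration
    p <- tryCatch(drop(solve(diag(n) - alpha * S, r)),
                  error = function(e) dp_convergence_error(
                    sprintf("inner solve failed on %s network: %s", kind,
                            conditionMessage(e)), level = "inner"))
    return(list(p = p, iterations = 1L))
  }
  p <- r
  for (it in seq_len(config$max_iter)) {
    p_new <- r + alpha * drop(S %*% p)
    res <- l2(p_new - p)
    p <- p_new
    if (res < tol_of(config)) return(list(p = p, iterations = it))
  }
  dp_convergence_error(
    sprintf("inner loop on %s network did not converge (residual %.3e)", kind, res),
    residual = res, level = "inner")
}

tol_of <- function(config) config$tol

#' Propagate a query disease across the integrated network
#'
#' Runs the coupled propagation: the phenotype network starts from the query
#' indicator (uniformly split over multiple query phenotypes so the vector
#' sums to 1), every network's update combines a restart term anchored at its
#' initial distribution, propagated mass from its hetero-network neighbors,
#' and diffusion along its own edges:
#'
#' `p_i^t = (1 - alpha_i) (1 - k alpha_i) p_i^0 + alpha_i * sum_j S_ij p_j^0
#'          + alpha_i * S_i p_i^{t-1}`
#'
#' Inner loops iterate each homo-network to tolerance with the neighbor
#' vectors held fixed; the outer loop then synchronously feeds every
#' network's converged vector to its neighbors (`p_j^0` above) and repeats
#' until the concatenated state changes by less than `tol` in L2. The
#' restart term stays anchored at the original initial distribution, so the
#' coupled system has a unique fixed point (see the methods vignette).
#'
#' In `literal` coefficient mode negative mixing coefficients can produce
#' negative intermediate entries; these are clamped to 0 at read-out with a
#' logged count.
#'
#' @param net An [integrated_network()].
#' @param query_phenotypes One or more phenotype ids present in the
#'   phenotype network.
#' @param config A [diffusion_config()]; defaults to the one stored in
#'   `net`.
#'
#' @return A [probability_state()].
#' @export
propagate_integrated <- function(net, query_phenotypes, config = net$config) {
  unknown <- setdiff(query_phenotypes, net$phenotype$node_ids)
  if (length(unknown)) {
    dp_validation_error(sprintf("unknown query phenotype(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  ops <- integrated_operators(net, config)
  kinds <- c("drug", "gene", "phenotype")
  sizes <- c(drug = length(net$drug$node_ids), gene = length(net$gene$node_ids),
             phenotype = length(net$phenotype$node_ids))
  p0 <- list(drug = numeric(sizes["drug"]), gene = numeric(sizes["gene"]),
             phenotype = numeric(sizes["phenotype"]))
  q_idx <- match(query_phenotypes, net$phenotype$node_ids)
  p0$phenotype[q_idx] <- 1 / length(q_idx)

  alpha <- config$alpha
  # restart coefficient (1 - alpha_i)(1 - k alpha_i), fixed for the whole run
  restart <- lapply(kinds, function(kd) (1 - alpha[kd]) * ops$a[kd] * p0[[kd]])
  names(restart) <- kinds

  state <- p0
  iters <- c(drug = 0L, gene = 0L, phenotype = 0L)
  outer_res <- Inf
  for (sweep in seq_len(config$max_iter)) {
    new_state <- state
    for (kd in kinds) {
      r <- restart[[kd]]
      for (nb in ops$neighbors[[kd]]) {
        r <- r + alpha[kd] * drop(nb$M %*% state[[nb$kind]])
      }
      sol <- solve_inner(ops$S[[kd]], alpha[kd], r, config, kd)
      new_state[[kd]] <- sol$p
      iters[kd] <- iters[kd] + sol$iterations
    }
    outer_res <- l2(unlist(new_state) - unlist(state))
    state <- new_state
    if (!is.finite(outer_res) || outer_res > 1e12) {
      dp_convergence_error(
        sprintf("outer loop diverged after %d sweeps (residual %.3e)", sweep, outer_res),
        residual = outer_res, level = "outer")
    }
    if (outer_res < config$tol) {
      n_neg <- sum(unlist(state) < 0)
      if (n_neg > 0) {
        dp_log("clamped %d negative probability entr%s to 0 at read-out",
               n_neg, if (n_neg == 1) "y" else "ies")
        state <- lapply(state, function(v) pmax(v, 0))
      }
      state <- lapply(kinds, function(kd) {
        stats::setNames(state[[kd]], net[[kd]]$node_ids)
      })
      names(state) <- kinds
      return(probability_state(state, converged = TRUE, iterations = iters,
                               outer_sweeps = sweep))
    }
  }
  dp_convergence_error(
    sprintf("outer loop did not converge in %d sweeps (residual %.3e)",
            config$max_iter, outer_res),
    residual = outer_res, level = "outer")
}
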