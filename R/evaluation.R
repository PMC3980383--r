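# ROC/AUC benchmarking and the diffusion-parameter sweep.

#' ROC curve and AUC of a drug ranking against a benchmark
#'
#' Drugs in the benchmark are positives; all other scored drugs are
#' negatives (no curated negative set exists, mirroring the evaluation
#' protocol of ranking the full drug list against curated positives). The
#' AUC is the Mann-Whitney concordance probability with ties counted 0.5 and
#' equals the trapezoidal area under the threshold-sweep ROC curve.
#'
#' @param scores Named numeric vector of drug scores (higher = stronger
#'   predicted association).
#' @param benchmark A [benchmark_set()] (or character vector of positive
#'   drug ids).
#'
#' @return List of class `roc_result` with elements `points` (data frame of
#'   `fpr`, `tpr`), `auc`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, benchmark) {
  positives <- if (inherits(benchmark, "benchmark_set")) {
    benchmark$positive_drug_ids
  } else as.character(benchmark)
  if (is.null(names(scores))) dp_validation_error("scores must be named by drug id")
  labels <- names(scores) %in% positives
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    dp_validation_error("benchmark evaluation needs at least one positive and one negative")
  }
  # Mann-Whitney via mid-ranks: ties contribute 0.5 concordance
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  # threshold sweep in descending score order, tied scores collapsed
  ord <- order(-scores)
  s_ord <- scores[ord]
  lab_ord <- labels[ord]
  step <- c(diff(s_ord) != 0, TRUE)  # last index of each tie group
  tpr <- c(0, cumsum(lab_ord)[step] / n_pos)
  fpr <- c(0, cumsum(!lab_ord)[step] / n_neg)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr),
                 auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result auc=%.4f pos=%d neg=%d>\n", x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' Default diffusion-parameter grid
#'
#' The full factorial grid of `{0.1, 0.3, 0.5, 0.7, 0.9}` over the drug,
#' gene and phenotype diffusion parameters: 125 combinations.
#'
#' @return Data frame with columns `alpha_drug`, `alpha_gene`,
#'   `alpha_phenotype`.
#' @export
default_alpha_grid <- function() {
  vals <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  g <- expand.grid(alpha_drug = vals, alpha_gene = vals, alpha_phenotype = vals,
                   KEEP.OUT.ATTRS = FALSE)
  g[, c("alpha_drug", "alpha_gene", "alpha_phenotype")]
}

#' Sweep diffusion parameters and measure ranking AUC
#'
#' Runs the full rank-and-evaluate pipeline (main propagation, reference
#' propagation, z-score ranking, ROC/AUC) for every diffusion-parameter
#' combination in the grid. Propagation failures (e.g. divergence of the
#' coupled system at extreme parameter values in literal mode) are recorded
#' per cell as `NA` AUC with the error message, and the sweep continues.
#'
#' @param net An [integrated_network()].
#' @param query Query phenotype id(s).
#' @param benchmark A [benchmark_set()].
#' @param grid Data frame of alpha triples; defaults to
#'   [default_alpha_grid()] (125 rows).
#' @param threshold Significance threshold passed to [rank_drugs()].
#' @param mode Z-score mode passed to [rank_drugs()].
#'
#' @return Data frame with columns `alpha_drug`, `alpha_gene`,
#'   `alpha_phenotype`, `auc`, `error` in grid order.
#' @export
parameter_sweep <- function(net, query, benchmark, grid = default_alpha_grid(),
                            threshold = 2.33, mode = "set") {
  if (!nrow(grid)) dp_validation_error("parameter grid must be non-empty")
  out <- grid
  out$auc <- NA_real_
  out$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    cfg <- diffusion_config(
      alpha = c(drug = grid$alpha_drug[i], gene = grid$alpha_gene[i],
                phenotype = grid$alpha_phenotype[i]),
      coefficient_mode = net$config$coefficient_mode,
      tol = net$config$tol, max_iter = net$config$max_iter,
      direct_solver = net$config$direct_solver)
    res <- tryCatch({
      state <- propagate_integrated(net, query, cfg)
      ref <- reference_state(net, query, cfg)
      ranking <- rank_drugs(state, ref, threshold = threshold, mode = mode)
      scores <- stats::setNames(ranking$z, ranking$drug_id)
      roc_auc(scores, benchmark)$auc
    }, drugprop_error = function(e) e)
    if (inherits(res, "condition")) {
      out$error[i] <- conditionMessage(res)
    } else {
      out$auc[i] <- res
    }
  }
  out
}
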