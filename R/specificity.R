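# Topology-bias reference run and Z-score specificity ranking.

#' Reference propagation with uniform protein-interaction weights
#'
#' Visitation probabilities are biased by network topology: well-connected
#' nodes collect mass regardless of the disease-specific expression weights.
#' The reference run captures this topology-only tendency by replacing every
#' structural protein-interaction edge weight with 1 (sink-node smoothing
#' re-applied on the clone) and propagating identically.
#'
#' @param net An [integrated_network()] whose gene network carries the
#'   structural `pin_edges` attribute from [build_gene_network()]; if absent,
#'   every positive non-smoothed edge is treated as structural.
#' @param query_phenotypes Query phenotype id(s), as in
#'   [propagate_integrated()].
#' @param config A [diffusion_config()]; defaults to the one stored in `net`.
#'
#' @return A [probability_state()] with the reference probabilities.
#' @export
reference_state <- function(net, query_phenotypes, config = net$config) {
  ref_net <- net
  ref_net$gene <- uniform_gene_network(net)
  propagate_integrated(ref_net, query_phenotypes, config)
}

# Rebuild the gene network with all structural PIN edges at weight 1 and
# sink smoothing re-applied for hetero-referenced genes.
uniform_gene_network <- function(net) {
  gene <- net$gene
  ids <- gene$node_ids
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  pin <- attr(gene, "pin_edges")
  if (!is.null(pin) && nrow(pin)) {
    keep <- pin$from %in% ids & pin$to %in% ids
    W[cbind(pin$from[keep], pin$to[keep])] <- 1
    W[cbind(pin$to[keep], pin$from[keep])] <- 1
  } else {
    # no structural record: binarize the non-smoothed weights
    orphans <- attr(gene, "orphans")
    W[gene$weights > 0] <- 1
    if (!is.null(orphans) && length(orphans)) {
      W[orphans, ] <- 0
      W[, orphans] <- 0
    }
  }
  diag(W) <- 0
  referenced <- referenced_gene_ids(net)
  out <- homo_network(ids, W, "gene")
  attr(out, "pin_edges") <- pin
  attach_orphans(out, referenced)
}

referenced_gene_ids <- function(net) {
  unique(c(net$drug_gene$col_ids[colSums(net$drug_gene$links) > 0],
           net$phenotype_gene$col_ids[colSums(net$phenotype_gene$links) > 0]))
}

#' Z-score specificity of propagated probabilities
#'
#' Standardizes each node's probability against the reference run:
#' `z(v) = (P(v) - avg(P_ref)) / std(P_ref)` with the population (divide by
#' N) standard deviation over the full reference vector (`mode = "set"`, the
#' formula as written; ranking by z then coincides with ranking by raw
#' probability since mean and sd are scalars). `mode = "nodewise"` instead
#' uses `z(v) = (P(v) - P_ref(v)) / std(P_ref)`, a per-node correction of
#' the topological bias.
#'
#' @param P Numeric vector of propagated probabilities (named by node id).
#' @param P_ref Reference probabilities, same length (`>= 2`).
#' @param threshold Significance threshold on z; the default 2.33
#'   corresponds to a one-tailed test at the 0.01 level.
#' @param mode `"set"` (default) or `"nodewise"`.
#'
#' @return Data frame with columns `id`, `probability`, `z`, `significant`,
#'   plus attributes `ref_mean` and `ref_sd`.
#' @export
z_scores <- function(P, P_ref, threshold = 2.33, mode = c("set", "nodewise")) {
  mode <- match.arg(mode)
  if (length(P) != length(P_ref) || length(P) < 2) {
    dp_validation_error("P and P_ref must have equal length >= 2")
  }
  m <- mean(P_ref)
  s <- sqrt(mean((P_ref - m)^2))  # population standard deviation
  if (s == 0) {
    dp_stop("reference distribution is constant; z-scores undefined",
            "drugprop_degenerate_reference_error")
  }
  z <- if (mode == "set") (P - m) / s else (P - P_ref) / s
  ids <- if (!is.null(names(P))) names(P) else as.character(seq_along(P))
  out <- data.frame(id = ids, probability = unname(P), z = unname(z),
                    significant = unname(z > threshold),
                    stringsAsFactors = FALSE)
  attr(out, "ref_mean") <- m
  attr(out, "ref_sd") <- s
  out
}

#' Z-score report for every homo-network
#'
#' Applies [z_scores()] to the drug, gene and phenotype vectors of a
#' propagation run against its reference run. Gene and phenotype scores are
#' reported as well (gene z-scores feed downstream functional analyses).
#' Negative probabilities possibly produced by literal coefficient mode are
#' clamped to 0 before scoring with a logged count.
#'
#' @param state Main-run [probability_state()].
#' @param ref Reference-run [probability_state()] from [reference_state()].
#' @param threshold Significance threshold on z (default 2.33).
#' @param mode Passed to [z_scores()].
#'
#' @return Named list of per-kind data frames (`drug`, `gene`, `phenotype`).
#' @export
zscore_report <- function(state, ref, threshold = 2.33, mode = c("set", "nodewise")) {
  mode <- match.arg(mode)
  out <- lapply(c(drug = "drug", gene = "gene", phenotype = "phenotype"), function(kd) {
    P <- clamp_nonneg(state$vectors[[kd]], kd)
    P_ref <- clamp_nonneg(ref$vectors[[kd]], paste0("reference ", kd))
    z_scores(P, P_ref, threshold = threshold, mode = mode)
  })
  out
}

clamp_nonneg <- function(v, what) {
  n_neg <- sum(v < 0)
  if (n_neg > 0) {
    dp_log("clamped %d negative entr%s in the %s vector before z-scoring",
           n_neg, if (n_neg == 1) "y" else "ies", what)
    v <- pmax(v, 0)
  }
  v
}

#' Rank candidate drugs by Z-score specificity
#'
#' @param state Main-run [probability_state()].
#' @param ref Reference-run [probability_state()].
#' @param threshold Significance threshold on z (default 2.33).
#' @param mode Passed to [z_scores()].
#'
#' @return Data frame with columns `drug_id`, `probability`, `z`,
#'   `significant`, sorted by `z` descending with ties broken by drug id
#'   (lexicographic) for determinism.
#' @export
rank_drugs <- function(state, ref, threshold = 2.33, mode = c("set", "nodewise")) {
  mode <- match.arg(mode)
  zs <- z_scores(clamp_nonneg(state$vectors$drug, "drug"),
                 clamp_nonneg(ref$vectors$drug, "reference drug"),
                 threshold = threshold, mode = mode)
  ord <- order(-zs$z, zs$id, method = "radix")
  out <- data.frame(drug_id = zs$id[ord], probability = zs$probability[ord],
                    z = zs$z[ord], significant = zs$significant[ord],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
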