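# Construction of the three weighted homo-networks and the two binary
# hetero-networks.

#' Logistic transform parameters for phenotype similarities
#'
#' The transform `1 / (1 + exp(c * x + d))` maps raw phenotype-similarity
#' scores in `[0, 1]` so that informative scores (raw >= 0.6) land near 1 and
#' non-informative scores (raw <= 0.3) near 0. The defaults `c = -15`,
#' `d = log(9999)` give `transform(0) = 1e-4` and a midpoint at
#' `x = -d/c ~ 0.614`.
#'
#' @param c Slope; must be negative so the transform is strictly increasing.
#' @param d Offset.
#'
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(c = -15, d = log(9999)) {
  if (!is.finite(c) || !is.finite(d)) dp_validation_error("logistic parameters must be finite")
  if (c >= 0) dp_validation_error("logistic slope c must be negative (increasing transform)")
  structure(list(c = c, d = d), class = "logistic_params")
}

#' Apply the logistic transform to similarity scores
#'
#' @param x Numeric vector of raw similarities in `[0, 1]`.
#' @param params A [logistic_params()].
#'
#' @return Transformed values in `(0, 1)`, strictly increasing in `x`.
#' @export
logistic_transform <- function(x, params = logistic_params()) {
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    dp_validation_error("raw similarity scores must lie in [0, 1]")
  }
  1 / (1 + exp(params$c * x + params$d))
}

#' Tanimoto coefficient between two fingerprints
#'
#' Size of the common substructures over the union: `|a & b| / |a | b|`,
#' between 0 (no bits in common) and 1 (all bits the same).
#'
#' @param a,b [fingerprint()] objects (or plain integer vectors of bit
#'   indices).
#'
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto_similarity <- function(a, b) {
  ba <- if (inherits(a, "fingerprint")) a$bits else unique(as.integer(a))
  bb <- if (inherits(b, "fingerprint")) b$bits else unique(as.integer(b))
  if (!length(ba) && !length(bb)) {
    dp_validation_error("tanimoto coefficient undefined for two empty fingerprints")
  }
  n_common <- length(intersect(ba, bb))
  n_union <- length(ba) + length(bb) - n_common
  n_common / n_union
}

#' Build the drug homo-network from fingerprints
#'
#' Pairwise Tanimoto coefficients form the symmetric chemical-similarity
#' matrix used as edge weights; the diagonal is zero.
#'
#' @param fps List of [fingerprint()] objects (at least two, all non-empty).
#'
#' @return A [homo_network()] of kind `drug`.
#' @export
build_drug_network <- function(fps) {
  if (length(fps) < 2) dp_validation_error("at least two drugs are required")
  ids <- vapply(fps, function(fp) fp$drug_id, "")
  if (anyDuplicated(ids)) dp_validation_error("duplicate drug ids among fingerprints")
  sizes <- vapply(fps, function(fp) length(fp$bits), 0L)
  if (any(sizes == 0)) {
    dp_validation_error(sprintf("empty fingerprint for drug %s", ids[which(sizes == 0)[1]]))
  }
  # incidence matrix over the union of observed bits: intersections in one
  # crossproduct, unions from the set sizes
  all_bits <- sort(unique(unlist(lapply(fps, `[[`, "bits"))))
  M <- matrix(0L, length(fps), length(all_bits))
  for (i in seq_along(fps)) M[i, match(fps[[i]]$bits, all_bits)] <- 1L
  inter <- tcrossprod(M)
  uni <- outer(sizes, sizes, `+`) - inter
  W <- inter / uni
  diag(W) <- 0
  homo_network(ids, W, "drug")
}

#' Build the phenotype homo-network from raw similarity scores
#'
#' Applies the logistic transform elementwise to the off-diagonal of a raw
#' symmetric phenotype-similarity matrix (MimMiner-style scores in `[0, 1]`);
#' the diagonal is set to zero. Near-zero transformed values are kept as
#' small positives rather than truncated.
#'
#' @param raw Square symmetric numeric matrix with identifier dimnames,
#'   entries in `[0, 1]`.
#' @param params A [logistic_params()].
#'
#' @return A [homo_network()] of kind `phenotype`.
#' @export
build_phenotype_network <- function(raw, params = logistic_params()) {
  raw <- as.matrix(raw)
  ids <- rownames(raw)
  if (is.null(ids)) dp_validation_error("raw phenotype matrix needs identifier dimnames")
  if (nrow(raw) != ncol(raw) || max(abs(raw - t(raw))) > 1e-12) {
    dp_validation_error("raw phenotype similarity matrix must be symmetric")
  }
  W <- matrix(logistic_transform(as.vector(raw), params), nrow(raw), ncol(raw))
  W <- (W + t(W)) / 2  # remove numerically negligible asymmetry from exp()
  diag(W) <- 0
  dimnames(W) <- dimnames(raw)
  homo_network(ids, W, "phenotype")
}

#' Co-expression edge weight between two interacting genes
#'
#' The product of the absolute case-sample correlation and the sum of the
#' absolute differential-expression changes of the two genes:
#' `|r| * (|ei_case - ei_ctrl| + |ej_case - ej_ctrl|)`.
#'
#' @param r_case Pearson correlation of the two genes across case samples.
#' @param ei_case,ei_ctrl Mean expression of gene i in case/control samples.
#' @param ej_case,ej_ctrl Mean expression of gene j in case/control samples.
#'
#' @return Non-negative weight.
#' @export
coexpression_weight <- function(r_case, ei_case, ei_ctrl, ej_case, ej_ctrl) {
  if (!all(is.finite(c(r_case, ei_case, ei_ctrl, ej_case, ej_ctrl)))) {
    dp_validation_error("coexpression_weight requires finite inputs")
  }
  abs(r_case) * (abs(ei_case - ei_ctrl) + abs(ej_case - ej_ctrl))
}

#' Build the expression-weighted protein-interaction homo-network
#'
#' Every structural protein-interaction edge is weighted by
#' [coexpression_weight()], with the Pearson correlation computed over case
#' samples only and within-class means over all samples of each class. Genes
#' absent from the expression profile keep their edges at weight 0 (logged);
#' a gene with zero variance across case samples makes the correlation
#' undefined and the edge weight is set to 0 with a warning.
#'
#' The structural edge list is recorded in the `pin_edges` attribute of the
#' result so that a topology-only reference network can be rebuilt later.
#'
#' @param pin_edges Data frame (or 2-column matrix) of gene-gene interaction
#'   pairs.
#' @param expr An [expression_profile()].
#'
#' @return A [homo_network()] of kind `gene`.
#' @export
build_gene_network <- function(pin_edges, expr) {
  pin_edges <- as.data.frame(pin_edges, stringsAsFactors = FALSE)
  if (ncol(pin_edges) < 2) dp_validation_error("pin_edges needs two id columns")
  from <- as.character(pin_edges[[1]])
  to <- as.character(pin_edges[[2]])
  loops <- from == to
  if (any(loops)) {
    dp_log("dropped %d self-interaction(s)", sum(loops))
    from <- from[!loops]; to <- to[!loops]
  }
  # first-appearance order over the edge list; with no edges at all the
  # expression genes stand in as isolated nodes
  ids <- if (length(from)) unique(c(rbind(from, to))) else expr$gene_ids
  n <- length(ids)
  W <- matrix(0, n, n, dimnames = list(ids, ids))
  if (length(from)) {
    present <- ids[ids %in% expr$gene_ids]
    absent <- setdiff(ids, present)
    if (length(absent)) {
      dp_log("%d PIN gene(s) absent from the expression profile kept at zero weight",
             length(absent))
    }
    is_case <- expr$sample_labels == "case"
    case_vals <- expr$values[match(present, expr$gene_ids), is_case, drop = FALSE]
    ctrl_vals <- expr$values[match(present, expr$gene_ids), !is_case, drop = FALSE]
    case_sd <- apply(case_vals, 1, stats::sd)
    diffs <- stats::setNames(abs(rowMeans(case_vals) - rowMeans(ctrl_vals)), present)
    R <- suppressWarnings(stats::cor(t(case_vals)))
    dimnames(R) <- list(present, present)
    n_zero_var <- 0L
    for (e in seq_along(from)) {
      gi <- from[e]; gj <- to[e]
      if (!(gi %in% present) || !(gj %in% present)) next
      if (case_sd[match(gi, present)] == 0 || case_sd[match(gj, present)] == 0) {
        n_zero_var <- n_zero_var + 1L
        next  # weight stays 0
      }
      w <- abs(R[gi, gj]) * (diffs[gi] + diffs[gj])
      W[gi, gj] <- max(W[gi, gj], w)
      W[gj, gi] <- W[gi, gj]
    }
    if (n_zero_var > 0) {
      warning(sprintf("%d edge(s) touch a gene with zero case-sample variance; weight set to 0",
                      n_zero_var))
    }
  }
  net <- homo_network(ids, W, "gene")
  attr(net, "pin_edges") <- data.frame(from = from, to = to, stringsAsFactors = FALSE)
  net
}

#' Build a binary hetero-network from association pairs
#'
#' Links are strictly binary by default even if the pair list carries
#' weights, matching the adjacency definition of the drug-target and
#' gene-phenotype link matrices; `weighted = TRUE` preserves a third column
#' of weights for weighted link sources. Pairs referencing unknown
#' identifiers are dropped with a logged count.
#'
#' @param pairs Data frame with columns `from` (row side) and `to` (column
#'   side), optionally `weight`.
#' @param row_universe,col_universe Identifier vectors defining the two
#'   sides.
#' @param row_kind,col_kind Node kinds of the two sides.
#' @param weighted Preserve positive weights instead of binarizing.
#'
#' @return A [hetero_network()] over the full universes.
#' @export
build_hetero <- function(pairs, row_universe, col_universe, row_kind, col_kind,
                         weighted = FALSE) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  from <- as.character(pairs[[1]])
  to <- as.character(pairs[[2]])
  w <- if (weighted && ncol(pairs) >= 3) as.numeric(pairs[[3]]) else rep(1, length(from))
  known <- from %in% row_universe & to %in% col_universe
  if (!all(known)) {
    dp_log("dropped %d association pair(s) with unknown ids", sum(!known))
  }
  if (!any(known)) dp_validation_error("all association pairs reference unknown ids")
  from <- from[known]; to <- to[known]; w <- w[known]
  links <- matrix(0, length(row_universe), length(col_universe),
                  dimnames = list(row_universe, col_universe))
  for (e in seq_along(from)) {
    v <- if (weighted) max(links[from[e], to[e]], w[e]) else 1
    links[from[e], to[e]] <- v
  }
  if (!weighted) links[links > 0] <- 1
  hetero_network(row_universe, col_universe, links, row_kind, col_kind)
}

#' Smooth sink nodes in the gene network
#'
#' A drug target or disease-associated gene with no protein-interaction link
#' would absorb probability ("sink node"). Every gene referenced by a
#' hetero-network whose row sum is zero -- including genes absent from the
#' interaction network, which are added as nodes -- receives a uniform small
#' connection `1/(n-1)` to every other gene, where `n` is the total gene
#' count after the additions. Smoothing applies only to hetero-referenced
#' genes, not to all isolated genes.
#'
#' @param gene_net A [homo_network()] of kind `gene`.
#' @param referenced_genes Identifiers referenced by a hetero-network.
#'
#' @return The smoothed gene network; smoothed gene ids are recorded in the
#'   `orphans` attribute and the structural `pin_edges` attribute is carried
#'   over.
#' @export
attach_orphans <- function(gene_net, referenced_genes) {
  referenced_genes <- unique(as.character(referenced_genes))
  ids <- gene_net$node_ids
  new_ids <- setdiff(referenced_genes, ids)
  if (length(new_ids)) {
    dp_log("added %d hetero-referenced gene(s) absent from the interaction network",
           length(new_ids))
  }
  all_ids <- c(ids, new_ids)
  n <- length(all_ids)
  if (n < 2) dp_validation_error("sink smoothing needs at least 2 genes")
  W <- matrix(0, n, n, dimnames = list(all_ids, all_ids))
  W[ids, ids] <- gene_net$weights
  orphans <- referenced_genes[rowSums(W[referenced_genes, , drop = FALSE]) == 0]
  for (g in orphans) {
    W[g, setdiff(all_ids, g)] <- 1 / (n - 1)
    W[setdiff(all_ids, g), g] <- 1 / (n - 1)
  }
  out <- homo_network(all_ids, W, "gene")
  attr(out, "pin_edges") <- attr(gene_net, "pin_edges")
  attr(out, "orphans") <- orphans
  out
}
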