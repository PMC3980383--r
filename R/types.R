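#' Weighted network over nodes of a single kind
#'
#' A homo-network is an undirected weighted graph over nodes of one kind
#' (drugs, genes/proteins, or disease phenotypes). Edge weights are held in a
#' square symmetric non-negative matrix with a zero diagonal, aligned to
#' `node_ids` (first-appearance order everywhere in the package).
#'
#' @param node_ids Character vector of unique node identifiers.
#' @param weights Square numeric matrix of non-negative edge weights with zero
#'   diagonal; `weights[i, j]` is the weight between `node_ids[i]` and
#'   `node_ids[j]`.
#' @param kind One of `"drug"`, `"gene"`, `"phenotype"`.
#'
#' @return An object of class `homo_network`: a list with elements `node_ids`,
#'   `weights` (with `node_ids` as dimnames) and `kind`.
#' @export
homo_network <- function(node_ids, weights, kind = c("drug", "gene", "phenotype")) {
  kind <- match.arg(kind)
  node_ids <- as.character(node_ids)
  if (anyDuplicated(node_ids)) {
    dp_validation_error(sprintf("duplicate node ids in %s homo-network", kind))
  }
  weights <- as.matrix(weights)
  n <- length(node_ids)
  if (!is.numeric(weights) || nrow(weights) != n || ncol(weights) != n) {
    dp_validation_error(sprintf(
      "%s homo-network weights must be a %d x %d numeric matrix", kind, n, n))
  }
  if (anyNA(weights) || any(!is.finite(weights))) {
    dp_validation_error(sprintf("non-finite weight in %s homo-network", kind))
  }
  if (any(weights < 0)) {
    dp_validation_error(sprintf("negative weight in %s homo-network", kind))
  }
  if (max(abs(weights - t(weights))) > 1e-12) {
    dp_validation_error(sprintf("%s homo-network weights are not symmetric", kind))
  }
  if (any(diag(weights) != 0)) {
    dp_validation_error(sprintf("%s homo-network has non-zero diagonal", kind))
  }
  dimnames(weights) <- list(node_ids, node_ids)
  structure(list(node_ids = node_ids, weights = weights, kind = kind),
            class = "homo_network")
}

#' @export
print.homo_network <- function(x, ...) {
  cat(sprintf("<homo_network kind=%s nodes=%d edges=%d>\n",
              x$kind, length(x$node_ids), sum(x$weights[upper.tri(x$weights)] > 0)))
  invisible(x)
}

#' Bipartite link set between two kinds of nodes
#'
#' A hetero-network connects nodes of two different homo-networks (drug-target
#' or gene-phenotype links) through a non-negative `|row_ids| x |col_ids|`
#' link matrix.
#'
#' @param row_ids,col_ids Character vectors of unique identifiers for the two
#'   sides.
#' @param links Non-negative numeric matrix, rows aligned to `row_ids` and
#'   columns to `col_ids`.
#' @param row_kind,col_kind Node kinds of the two sides; must differ.
#'
#' @return An object of class `hetero_network`.
#' @export
hetero_network <- function(row_ids, col_ids, links, row_kind, col_kind) {
  row_ids <- as.character(row_ids)
  col_ids <- as.character(col_ids)
  if (identical(row_kind, col_kind)) {
    dp_validation_error("hetero-network must connect two different node kinds")
  }
  if (anyDuplicated(row_ids) || anyDuplicated(col_ids)) {
    dp_validation_error("duplicate ids in hetero-network")
  }
  links <- as.matrix(links)
  if (nrow(links) != length(row_ids) || ncol(links) != length(col_ids)) {
    dp_validation_error("hetero-network link matrix does not match id lists")
  }
  if (anyNA(links) || any(links < 0)) {
    dp_validation_error("hetero-network links must be non-negative")
  }
  dimnames(links) <- list(row_ids, col_ids)
  structure(list(row_ids = row_ids, col_ids = col_ids, links = links,
                 row_kind = row_kind, col_kind = col_kind),
            class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat(sprintf("<hetero_network %s x %s: %d x %d, links=%d>\n",
              x$row_kind, x$col_kind, length(x$row_ids), length(x$col_ids),
              sum(x$links > 0)))
  invisible(x)
}

#' Diffusion configuration for the integrated propagation
#'
#' Holds the per-network diffusion parameters and the numerical controls of
#' the propagation. The diffusion parameter `alpha` is the probability mass a
#' walker sends onward per step; `1 - alpha` restarts at the initial
#' distribution. Each network attached to `k` hetero-networks mixes its own
#' restart vector with propagated neighbor mass using `a = 1 - k * alpha`.
#'
#' @param alpha Named numeric vector with entries `drug`, `gene`, `phenotype`,
#'   each in `[0, 1)`. Defaults `c(drug = 0.1, gene = 0.7, phenotype = 0.3)`,
#'   the setting reported to maximize AUC on the reference benchmarks.
#' @param coefficient_mode `"literal"` uses `a = 1 - k * alpha` exactly as
#'   written even when it is negative (the default gene setting `alpha = 0.7`
#'   with `k = 2` gives `a = -0.4`); `"strict"` rejects any configuration with
#'   a negative mixing coefficient.
#' @param tol L2 convergence threshold for both the inner per-network
#'   iteration and the outer cross-network loop. Default `1e-9`.
#' @param max_iter Iteration cap for inner and outer loops. Default `10000`.
#' @param k Optional named integer vector overriding the number of attached
#'   hetero-networks per kind; by default derived from the network layout
#'   (phenotype 1, drug 1, gene 2 in the standard three-network layout).
#' @param direct_solver Use an exact linear solve for inner iterations on
#'   networks below 2000 nodes (identical fixed point, fewer operations);
#'   iteration remains the reference semantics. Default `TRUE`.
#'
#' @return An object of class `diffusion_config`.
#' @export
diffusion_config <- function(alpha = c(drug = 0.1, gene = 0.7, phenotype = 0.3),
                             coefficient_mode = c("literal", "strict"),
                             tol = 1e-9, max_iter = 10000L, k = NULL,
                             direct_solver = TRUE) {
  coefficient_mode <- match.arg(coefficient_mode)
  kinds <- c("drug", "gene", "phenotype")
  if (is.null(names(alpha)) || !all(kinds %in% names(alpha))) {
    dp_config_error("alpha must be a named vector with drug, gene and phenotype entries")
  }
  alpha <- alpha[kinds]
  if (any(alpha < 0) || any(alpha >= 1)) {
    dp_config_error("every alpha must lie in [0, 1)")
  }
  if (!is.null(k)) {
    if (is.null(names(k)) || !all(names(k) %in% kinds) || any(k < 0)) {
      dp_config_error("k override must be named by kind with non-negative counts")
    }
    k <- as.integer(k)
    names(k) <- kinds[match(names(k), kinds, nomatch = 0L)]
  }
  if (tol <= 0) dp_config_error("tol must be positive")
  if (max_iter < 1) dp_config_error("max_iter must be a positive integer")
  structure(list(alpha = alpha, coefficient_mode = coefficient_mode,
                 tol = tol, max_iter = as.integer(max_iter), k = k,
                 direct_solver = isTRUE(direct_solver)),
            class = "diffusion_config")
}

#' Integrated heterogeneous network
#'
#' Bundles the three homo-networks, the two hetero-networks and a diffusion
#' configuration. On assembly the hetero-network id sets must be subsets of
#' the corresponding homo-network node sets; genes referenced by a
#' hetero-network but absent from the protein-interaction network should have
#' been added (and sink-smoothed) beforehand via [attach_orphans()].
#'
#' @param drug,gene,phenotype [homo_network()] objects of matching kind.
#' @param drug_gene Hetero-network with drug rows and gene columns.
#' @param phenotype_gene Hetero-network with phenotype rows and gene columns.
#' @param config A [diffusion_config()].
#'
#' @return An object of class `integrated_network`.
#' @export
integrated_network <- function(drug, gene, phenotype, drug_gene, phenotype_gene,
                               config = diffusion_config()) {
  for (nm in c("drug", "gene", "phenotype")) {
    net <- get(nm)
    if (!inherits(net, "homo_network") || net$kind != nm) {
      dp_validation_error(sprintf("'%s' must be a homo_network of kind %s", nm, nm))
    }
  }
  if (!inherits(drug_gene, "hetero_network") ||
      drug_gene$row_kind != "drug" || drug_gene$col_kind != "gene") {
    dp_validation_error("drug_gene must be a drug x gene hetero_network")
  }
  if (!inherits(phenotype_gene, "hetero_network") ||
      phenotype_gene$row_kind != "phenotype" || phenotype_gene$col_kind != "gene") {
    dp_validation_error("phenotype_gene must be a phenotype x gene hetero_network")
  }
  check_subset <- function(ids, universe, what) {
    missing <- setdiff(ids, universe)
    if (length(missing)) {
      dp_validation_error(sprintf("%s ids absent from homo-network: %s",
                                  what, paste(utils::head(missing, 5), collapse = ", ")))
    }
  }
  check_subset(drug_gene$row_ids, drug$node_ids, "drug_gene row")
  check_subset(drug_gene$col_ids, gene$node_ids, "drug_gene column")
  check_subset(phenotype_gene$row_ids, phenotype$node_ids, "phenotype_gene row")
  check_subset(phenotype_gene$col_ids, gene$node_ids, "phenotype_gene column")
  if (!inherits(config, "diffusion_config")) {
    dp_validation_error("config must be a diffusion_config")
  }
  structure(list(drug = drug, gene = gene, phenotype = phenotype,
                 drug_gene = drug_gene, phenotype_gene = phenotype_gene,
                 config = config),
            class = "integrated_network")
}

#' @export
print.integrated_network <- function(x, ...) {
  cat(sprintf("<integrated_network drugs=%d genes=%d phenotypes=%d>\n",
              length(x$drug$node_ids), length(x$gene$node_ids),
              length(x$phenotype$node_ids)))
  invisible(x)
}

#' Converged probability state of a propagation run
#'
#' @param vectors Named list with numeric vectors `drug`, `gene`, `phenotype`,
#'   aligned to the corresponding network's node ids.
#' @param converged Logical, whether all loops reached the tolerance.
#' @param iterations Named integer vector of cumulative inner iterations per
#'   network kind.
#' @param outer_sweeps Number of outer cross-network sweeps performed.
#'
#' @return An object of class `probability_state`.
#' @export
probability_state <- function(vectors, converged, iterations,
                              outer_sweeps = NA_integer_) {
  kinds <- c("drug", "gene", "phenotype")
  if (!all(kinds %in% names(vectors))) {
    dp_validation_error("probability_state needs drug, gene and phenotype vectors")
  }
  structure(list(vectors = vectors[kinds], converged = isTRUE(converged),
                 iterations = iterations, outer_sweeps = outer_sweeps),
            class = "probability_state")
}

#' @export
print.probability_state <- function(x, ...) {
  cat(sprintf("<probability_state converged=%s outer_sweeps=%s>\n",
              x$converged, x$outer_sweeps))
  invisible(x)
}

#' Case/control gene-expression profile
#'
#' @param gene_ids Character vector of unique gene identifiers.
#' @param values Numeric genes x samples matrix.
#' @param sample_labels Character vector, one of `"case"`/`"control"` per
#'   sample column. At least two samples per class are required (Pearson
#'   correlation needs two points); below three a warning is raised.
#'
#' @return An object of class `expression_profile`.
#' @export
expression_profile <- function(gene_ids, values, sample_labels) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) dp_validation_error("duplicate gene ids in expression profile")
  values <- as.matrix(values)
  if (nrow(values) != length(gene_ids)) {
    dp_validation_error("expression matrix rows must match gene_ids")
  }
  if (ncol(values) != length(sample_labels)) {
    dp_validation_error("one sample label per expression column is required")
  }
  if (!all(sample_labels %in% c("case", "control"))) {
    dp_validation_error("sample labels must be 'case' or 'control'")
  }
  n_case <- sum(sample_labels == "case")
  n_ctrl <- sum(sample_labels == "control")
  if (n_case < 2 || n_ctrl < 2) {
    dp_validation_error("at least 2 case and 2 control samples are required")
  }
  if (n_case < 3 || n_ctrl < 3) {
    warning("fewer than 3 samples in a class; correlation estimates will be unstable")
  }
  rownames(values) <- gene_ids
  structure(list(gene_ids = gene_ids, values = values,
                 sample_labels = sample_labels),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("<expression_profile genes=%d case=%d control=%d>\n",
              length(x$gene_ids), sum(x$sample_labels == "case"),
              sum(x$sample_labels == "control")))
  invisible(x)
}

#' Benchmark set of known drug-disease associations
#'
#' @param disease_id Identifier of the query disease phenotype.
#' @param positive_drug_ids Character vector of drugs with a curated
#'   association to the disease.
#'
#' @return An object of class `benchmark_set`.
#' @export
benchmark_set <- function(disease_id, positive_drug_ids) {
  positive_drug_ids <- unique(as.character(positive_drug_ids))
  if (!length(positive_drug_ids)) {
    dp_validation_error("benchmark must contain at least one positive drug")
  }
  structure(list(disease_id = as.character(disease_id),
                 positive_drug_ids = positive_drug_ids),
            class = "benchmark_set")
}

#' Hashed chemical fingerprint
#'
#' Holds the indices of set bits of a hashed substructure fingerprint
#' (path-based, 1024 bits when derived externally); only the set-bit indices
#' matter for the Tanimoto coefficient.
#'
#' @param drug_id Drug identifier.
#' @param bits Vector of non-negative integer bit indices.
#'
#' @return An object of class `fingerprint`.
#' @export
fingerprint <- function(drug_id, bits) {
  bits <- as.integer(bits)
  if (anyNA(bits) || any(bits < 0)) {
    dp_validation_error(sprintf("fingerprint for %s has invalid bit indices", drug_id))
  }
  bits <- sort(unique(bits))
  structure(list(drug_id = as.character(drug_id), bits = bits),
            class = "fingerprint")
}
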