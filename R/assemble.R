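# Assembly of the integrated network from its raw ingredients.

#' Assemble an integrated heterogeneous network
#'
#' Builds the three homo-networks and two hetero-networks from raw inputs:
#' Tanimoto similarities over fingerprints (drug), logistic-transformed raw
#' similarities (phenotype), co-expression-weighted protein interactions
#' (gene), and binary link matrices from the association pair lists. Genes
#' referenced by either hetero-network but missing from the interaction
#' network are added and sink-smoothed via [attach_orphans()]; pairs
#' referencing unknown drugs or phenotypes are dropped with a logged count.
#'
#' @param fingerprints List of [fingerprint()] objects.
#' @param phenotype_sim Raw square phenotype-similarity matrix with id
#'   dimnames, entries in `[0, 1]`.
#' @param pin_edges Data frame of protein-interaction gene pairs.
#' @param expr An [expression_profile()].
#' @param drug_targets Data frame of (drug, gene) pairs.
#' @param gene_phenotypes Data frame of (phenotype, gene) pairs.
#' @param config A [diffusion_config()].
#' @param logistic A [logistic_params()].
#' @param weighted_hetero Preserve third-column weights in the hetero
#'   networks instead of binarizing (for weighted link sources).
#'
#' @return An [integrated_network()].
#' @export
build_integrated <- function(fingerprints, phenotype_sim, pin_edges, expr,
                             drug_targets, gene_phenotypes,
                             config = diffusion_config(),
                             logistic = logistic_params(),
                             weighted_hetero = FALSE) {
  drug_net <- build_drug_network(fingerprints)
  phen_net <- build_phenotype_network(phenotype_sim, logistic)
  gene_net <- build_gene_network(pin_edges, expr)
  referenced <- unique(c(as.character(drug_targets[[2]]),
                         as.character(gene_phenotypes[[2]])))
  gene_net <- attach_orphans(gene_net, referenced)
  dg <- build_hetero(drug_targets, drug_net$node_ids, gene_net$node_ids,
                     "drug", "gene", weighted = weighted_hetero)
  pg <- build_hetero(gene_phenotypes, phen_net$node_ids, gene_net$node_ids,
                     "phenotype", "gene", weighted = weighted_hetero)
  integrated_network(drug_net, gene_net, phen_net, dg, pg, config)
}

#' Assemble an integrated network from flat files
#'
#' File-level counterpart of [build_integrated()]; see the reader functions
#' for the expected formats.
#'
#' @param fingerprints_path Fingerprint TSV ([read_fingerprints()]).
#' @param phenotype_sim_path Square similarity TSV
#'   ([read_similarity_matrix()]).
#' @param pin_path Protein-interaction edge list ([read_edge_list()]).
#' @param expr_path,labels_path Expression matrix and label map
#'   ([read_expression_matrix()]).
#' @param drug_targets_path,gene_phenotypes_path Association pair TSVs
#'   ([read_association_pairs()]).
#' @param ... Passed on to [build_integrated()].
#'
#' @return An [integrated_network()].
#' @export
build_integrated_from_files <- function(fingerprints_path, phenotype_sim_path,
                                        pin_path, expr_path, labels_path,
                                        drug_targets_path, gene_phenotypes_path,
                                        ...) {
  build_integrated(
    fingerprints = read_fingerprints(fingerprints_path),
    phenotype_sim = read_similarity_matrix(phenotype_sim_path),
    pin_edges = read_edge_list(pin_path)[, c("from", "to")],
    expr = read_expression_matrix(expr_path, labels_path),
    drug_targets = read_association_pairs(drug_targets_path),
    gene_phenotypes = read_association_pairs(gene_phenotypes_path),
    ...)
}
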