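# Self-contained synthetic fixtures with planted drug-disease associations.

#' Specification of a synthetic integrated-network fixture
#'
#' Defines the study conditions emulated by [generate_fixture()]: a planted
#' disease module of genes carrying correlated differential expression,
#' targeted by the benchmark-positive drugs and linked to the query
#' phenotype.
#'
#' @param n_drugs,n_genes,n_phenotypes Node counts per layer.
#' @param n_case,n_ctrl Case and control sample counts of the expression
#'   matrix.
#' @param module_size Number of genes in the planted disease module.
#' @param n_positive_drugs Number of benchmark-positive drugs.
#' @param signal_strength Differential-expression effect added to module
#'   genes in case samples, in within-class noise SD units.
#' @param within_module_corr Pairwise Pearson correlation induced among
#'   module genes in case samples via one shared latent factor, in `[0, 1)`.
#' @param fingerprint_bits Size of the hashed fingerprint bit space.
#' @param seed Integer seed; one seeded generator threads through all draws
#'   so the fixture is reproducible from this single integer.
#' @param null_targets If `TRUE`, positive drugs target background genes
#'   instead of module genes (null control).
#'
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_drugs = 60, n_genes = 200, n_phenotypes = 20,
                         n_case = 10, n_ctrl = 10, module_size = 20,
                         n_positive_drugs = 10, signal_strength = 2,
                         within_module_corr = 0.6, fingerprint_bits = 256,
                         seed = 1, null_targets = FALSE) {
  spec <- list(n_drugs = n_drugs, n_genes = n_genes, n_phenotypes = n_phenotypes,
               n_case = n_case, n_ctrl = n_ctrl, module_size = module_size,
               n_positive_drugs = n_positive_drugs,
               signal_strength = signal_strength,
               within_module_corr = within_module_corr,
               fingerprint_bits = fingerprint_bits, seed = as.integer(seed),
               null_targets = isTRUE(null_targets))
  counts <- c(n_drugs, n_genes, n_phenotypes, n_case, n_ctrl, module_size,
              n_positive_drugs, fingerprint_bits)
  if (any(counts < 2)) dp_validation_error("all fixture counts must be >= 2")
  if (module_size > n_genes) dp_validation_error("module_size cannot exceed n_genes")
  if (n_positive_drugs > n_drugs) dp_validation_error("more positive drugs than drugs")
  if (signal_strength < 0) dp_validation_error("signal_strength must be >= 0")
  if (within_module_corr < 0 || within_module_corr >= 1) {
    dp_validation_error("within_module_corr must lie in [0, 1)")
  }
  targets_per_drug <- 3L
  if (module_size < targets_per_drug) {
    dp_validation_error("module_size too small for the requested target links")
  }
  if (n_genes - module_size < targets_per_drug) {
    dp_validation_error("too few background genes for the requested target links")
  }
  structure(spec, class = "fixture_spec")
}

#' Fixture presets
#'
#' `default` is the standard planted-signal condition; `weak` halves the
#' expression signal; `null` removes the signal and points the positive
#' drugs at background genes.
#'
#' @param preset One of `"default"`, `"weak"`, `"null"`.
#' @param ... Overrides passed to [fixture_spec()].
#'
#' @return A [fixture_spec()].
#' @export
fixture_preset <- function(preset = c("default", "weak", "null"), ...) {
  preset <- match.arg(preset)
  args <- switch(preset,
                 default = list(),
                 weak = list(signal_strength = 1),
                 null = list(signal_strength = 0, null_targets = TRUE))
  do.call(fixture_spec, utils::modifyList(args, list(...)))
}

with_fixture_rng <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Generate a synthetic integrated-network fixture
#'
#' Produces all raw inputs of the pipeline with a planted disease module:
#' (a) random bit fingerprints, with the positive drugs sharing a common bit
#' block so chemically similar drugs share module targets; (b) a case/control
#' expression matrix where case samples add `signal_strength` to module genes
#' plus one shared latent factor inducing `within_module_corr`; (c) a sparse
#' background interaction network with a denser subgraph on module genes;
#' (d) a block-structured phenotype similarity matrix in which the query
#' phenotype and its related phenotypes score in the informative band
#' (raw >= 0.6) and all other pairs in the non-informative band (raw <= 0.3);
#' (e) gene-phenotype links from the query to module genes; (f) drug-target
#' links pointing positives at module genes (background genes under
#' `null_targets`); (g) the benchmark set of planted positives.
#'
#' Output is deterministic for a fixed seed; when `dir` is given the raw
#' inputs are also written as TSV files (byte-identical across runs).
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional output directory for the input TSVs and a manifest.
#'
#' @return List with elements `fingerprints`, `phenotype_sim`, `pin_edges`,
#'   `expr`, `drug_targets`, `gene_phenotypes`, `benchmark`, `query`,
#'   `module_genes`, `positive_drugs`, `network` (the assembled
#'   [integrated_network()]) and `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec(), dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  fx <- with_fixture_rng(spec$seed, generate_fixture_impl(spec))
  if (!is.null(dir)) write_fixture(fx, dir)
  fx
}

generate_fixture_impl <- function(spec) {
  drugs <- sprintf("D%03d", seq_len(spec$n_drugs))
  genes <- sprintf("G%03d", seq_len(spec$n_genes))
  phens <- sprintf("P%03d", seq_len(spec$n_phenotypes))
  module <- genes[seq_len(spec$module_size)]
  background <- setdiff(genes, module)
  positives <- drugs[seq_len(spec$n_positive_drugs)]
  query <- phens[1]
  n_related <- min(3L, spec$n_phenotypes - 1L)
  related <- phens[1L + seq_len(n_related)]

  # (a) fingerprints: ~32 random bits each; positives share a 16-bit block
  bits_per_drug <- min(32L, spec$fingerprint_bits %/% 2L)
  shared_block <- seq_len(min(16L, spec$fingerprint_bits %/% 4L))
  fps <- lapply(drugs, function(d) {
    bits <- sample.int(spec$fingerprint_bits, bits_per_drug) - 1L
    if (d %in% positives) bits <- c(shared_block - 1L, bits)
    fingerprint(d, bits)
  })

  # (b) expression: control i.i.d. noise; case adds signal + latent factor
  n_s <- spec$n_case + spec$n_ctrl
  values <- matrix(stats::rnorm(spec$n_genes * n_s), spec$n_genes, n_s)
  rho <- spec$within_module_corr
  latent <- stats::rnorm(spec$n_case)
  mod_idx <- match(module, genes)
  case_cols <- seq_len(spec$n_case)
  values[mod_idx, case_cols] <- spec$signal_strength +
    sqrt(rho) * matrix(latent, length(mod_idx), spec$n_case, byrow = TRUE) +
    sqrt(1 - rho) * matrix(stats::rnorm(length(mod_idx) * spec$n_case),
                           length(mod_idx), spec$n_case)
  labels <- c(rep("case", spec$n_case), rep("control", spec$n_ctrl))
  expr <- expression_profile(genes, values, labels)

  # (c) PIN: sparse background (mean degree ~6) + dense module subgraph
  p_bg <- min(1, 6 / max(spec$n_genes - 1, 1))
  pairs <- which(upper.tri(matrix(0, spec$n_genes, spec$n_genes)), arr.ind = TRUE)
  in_module <- pairs[, 1] %in% mod_idx & pairs[, 2] %in% mod_idx
  p_edge <- ifelse(in_module, 0.6, p_bg)
  keep <- stats::runif(nrow(pairs)) < p_edge
  pin_edges <- data.frame(from = genes[pairs[keep, 1]],
                          to = genes[pairs[keep, 2]],
                          stringsAsFactors = FALSE)

  # (d) phenotype similarities: informative within the query block
  raw <- matrix(stats::runif(spec$n_phenotypes^2, 0.05, 0.3),
                spec$n_phenotypes, spec$n_phenotypes)
  raw[upper.tri(raw)] <- t(raw)[upper.tri(raw)]
  block <- match(c(query, related), phens)
  for (i in block) for (j in block) {
    if (i < j) raw[i, j] <- raw[j, i] <- stats::runif(1, 0.6, 0.9)
  }
  diag(raw) <- 0
  dimnames(raw) <- list(phens, phens)

  # (e) gene-phenotype links: query and related phenotypes hit the module
  gp <- rbind(
    data.frame(from = query,
               to = sample(module, max(2L, spec$module_size %/% 2L)),
               stringsAsFactors = FALSE),
    do.call(rbind, lapply(related, function(p) {
      data.frame(from = p, to = sample(module, 3L), stringsAsFactors = FALSE)
    })),
    do.call(rbind, lapply(setdiff(phens, c(query, related)), function(p) {
      data.frame(from = p, to = sample(background, min(3L, length(background))),
                 stringsAsFactors = FALSE)
    }))
  )

  # (f) drug targets: positives hit the module unless null_targets
  pos_pool <- if (spec$null_targets) background else module
  dt <- do.call(rbind, lapply(drugs, function(d) {
    pool <- if (d %in% positives) pos_pool else background
    data.frame(from = d, to = sample(pool, 3L), stringsAsFactors = FALSE)
  }))

  benchmark <- benchmark_set(query, positives)
  network <- build_integrated(fps, raw, pin_edges, expr, dt, gp)
  list(fingerprints = fps, phenotype_sim = raw, pin_edges = pin_edges,
       expr = expr, drug_targets = dt, gene_phenotypes = gp,
       benchmark = benchmark, query = query, module_genes = module,
       positive_drugs = positives, network = network, spec = spec)
}

write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_fingerprints(p("fingerprints.tsv"), fx$fingerprints)
  write_similarity_matrix(p("phenotype_sim.tsv"), fx$phenotype_sim)
  write_edge_list(p("pin.tsv"),
                  data.frame(from = fx$pin_edges$from, to = fx$pin_edges$to,
                             weight = 1, stringsAsFactors = FALSE))
  write_expression_matrix(fx$expr, p("expression.tsv"), p("labels.tsv"))
  write_association_pairs(p("drug_targets.tsv"), fx$drug_targets)
  write_association_pairs(p("gene_phenotypes.tsv"), fx$gene_phenotypes)
  write_association_pairs(p("benchmark.tsv"),
                          data.frame(from = fx$benchmark$disease_id,
                                     to = fx$benchmark$positive_drug_ids,
                                     stringsAsFactors = FALSE))
  manifest <- c(sprintf("query\t%s", fx$query),
                sprintf("seed\t%d", fx$spec$seed),
                sprintf("%s\t%s", names(unclass(fx$spec)),
                        vapply(unclass(fx$spec), format, "")))
  writeLines(manifest, p("manifest.tsv"))
  invisible(dir)
}

#' Hand-sized integrated network with printed weights
#'
#' Fixed-constant toy networks used by oracle tests, two nodes per layer.
#'
#' * `chain`: the P1--G1--D1 chain. Weights: phenotype `W[P1,P2] = 0.4`,
#'   gene `W[G1,G2] = 1.5`, drug `W[D1,D2] = 0.2`; links `P1-G1` and
#'   `D1-G1` only.
#' * `twin`: both drugs target G1 and carry identical connectivity, so their
#'   converged probabilities must coincide.
#' * `ones`: all gene edge weights already 1, so the topology reference run
#'   coincides with the main run.
#'
#' @param variant One of `"chain"`, `"twin"`, `"ones"`.
#' @param config A [diffusion_config()] stored in the network.
#'
#' @return An [integrated_network()].
#' @export
toy_network <- function(variant = c("chain", "twin", "ones"),
                        config = diffusion_config()) {
  variant <- match.arg(variant)
  wp <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("P1", "P2"), c("P1", "P2")))
  wd <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("D1", "D2"), c("D1", "D2")))
  wg_val <- if (variant == "ones") 1 else 1.5
  wg <- matrix(c(0, wg_val, wg_val, 0), 2, 2,
               dimnames = list(c("G1", "G2"), c("G1", "G2")))
  gene <- homo_network(c("G1", "G2"), wg, "gene")
  attr(gene, "pin_edges") <- data.frame(from = "G1", to = "G2",
                                        stringsAsFactors = FALSE)
  attr(gene, "orphans") <- character(0)
  drug <- homo_network(c("D1", "D2"), wd, "drug")
  phen <- homo_network(c("P1", "P2"), wp, "phenotype")
  dg_links <- matrix(0, 2, 2, dimnames = list(c("D1", "D2"), c("G1", "G2")))
  dg_links["D1", "G1"] <- 1
  if (variant == "twin") dg_links["D2", "G1"] <- 1
  pg_links <- matrix(0, 2, 2, dimnames = list(c("P1", "P2"), c("G1", "G2")))
  pg_links["P1", "G1"] <- 1
  dg <- hetero_network(c("D1", "D2"), c("G1", "G2"), dg_links, "drug", "gene")
  pg <- hetero_network(c("P1", "P2"), c("G1", "G2"), pg_links, "phenotype", "gene")
  integrated_network(drug, gene, phen, dg, pg, config)
}
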