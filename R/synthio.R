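# Synthetic inputs with the statistical structure the analysis assumes:
# blockwise AR(1) LD, sparse cis weight panels, GWAS Z-vectors with planted
# causal genes, chemical sets with planted enrichment, two-group log2
# expression with planted fold changes, and graphs with planted dense
# modules. Every generator is a pure function of (config, master seed):
# per-generator sub-seeds are derived by hashing the generator name with the
# master seed, so adding a generator never perturbs the others.

#' Simulation configuration
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: 20 LD blocks of 50 SNPs with AR(1) correlation 0.6, 200 genes with
#' 5 cis SNPs each across 5 tissues, 10 causal genes of standardized effect
#' 6, 100 chemical sets of 10-50 genes with 5 active chemicals drawing 80%
#' of their members from causal genes, 10 samples per expression group with
#' log2 noise SD 0.5 and 20 planted fold changes of magnitude 2, and a PPI
#' graph with two planted cliques (sizes 6 and 4) over background edge
#' probability 0.02.
#'
#' @param seed master integer seed; recorded in every generated artifact.
#' @param n_blocks,block_size number and size of LD blocks.
#' @param rho within-block AR(1) correlation, in (0, 1).
#' @param n_genes number of genes in the universe.
#' @param snps_per_gene cis SNPs per gene (must not exceed `block_size`).
#' @param causal_genes named numeric vector mapping gene id to the effect
#'   alpha on the standardized gene-statistic scale (the expectation of the
#'   gene's TWAS Z).
#' @param n_tissues number of weight-panel tissues.
#' @param tissue_jitter SD of the per-tissue perturbation added to each
#'   gene's base weights before re-normalization; 0 makes tissues identical.
#' @param n_chemicals number of chemical sets.
#' @param active_chemicals named numeric vector mapping chemical id to the
#'   fraction of its set drawn from causal genes.
#' @param set_size_range inclusive (min, max) chemical-set sizes.
#' @param n_samples_per_group expression samples per group.
#' @param planted_lfc named numeric vector of planted log2 fold changes
#'   (case minus control).
#' @param expr_noise_sd Gaussian noise SD on the log2 scale.
#' @param ppi_planted_modules list of `c(size, within_prob)` pairs.
#' @param ppi_background_prob background edge probability.
#' @param ppi_n_nodes number of PPI nodes (first `ppi_n_nodes` genes).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_blocks = 20L, block_size = 50L, rho = 0.6,
                       n_genes = 200L, snps_per_gene = 5L,
                       causal_genes = setNames(rep(6, 10),
                                               sprintf("gene%03d", 1:10)),
                       n_tissues = 5L, tissue_jitter = 0.2,
                       n_chemicals = 100L,
                       active_chemicals = setNames(rep(0.8, 5),
                                                   sprintf("chem%03d", 1:5)),
                       set_size_range = c(10L, 50L),
                       n_samples_per_group = 10L,
                       planted_lfc = setNames(rep(c(2, -2), 10),
                                              sprintf("gene%03d", 1:20)),
                       expr_noise_sd = 0.5,
                       ppi_planted_modules = list(c(6, 1), c(4, 1)),
                       ppi_background_prob = 0.02,
                       ppi_n_nodes = min(100L, n_genes)) {
  cfg <- list(seed = as.integer(seed), n_blocks = as.integer(n_blocks),
              block_size = as.integer(block_size), rho = rho,
              n_genes = as.integer(n_genes),
              snps_per_gene = as.integer(snps_per_gene),
              causal_genes = causal_genes, n_tissues = as.integer(n_tissues),
              tissue_jitter = tissue_jitter,
              n_chemicals = as.integer(n_chemicals),
              active_chemicals = active_chemicals,
              set_size_range = as.integer(set_size_range),
              n_samples_per_group = as.integer(n_samples_per_group),
              planted_lfc = planted_lfc, expr_noise_sd = expr_noise_sd,
              ppi_planted_modules = ppi_planted_modules,
              ppi_background_prob = ppi_background_prob,
              ppi_n_nodes = as.integer(ppi_n_nodes))
  if (!(cfg$rho >= 0 && cfg$rho < 1)) .stopf("sim_config: rho must be in [0, 1)")
  if (cfg$snps_per_gene > cfg$block_size)
    .stopf("sim_config: snps_per_gene (%d) exceeds block_size (%d)",
           cfg$snps_per_gene, cfg$block_size)
  probs <- c(cfg$active_chemicals, cfg$ppi_background_prob,
             vapply(cfg$ppi_planted_modules, `[`, numeric(1), 2))
  if (any(probs < 0 | probs > 1))
    .stopf("sim_config: probabilities must lie in [0, 1]")
  sizes <- c(cfg$n_blocks, cfg$block_size, cfg$n_genes, cfg$snps_per_gene,
             cfg$n_tissues, cfg$n_chemicals, cfg$n_samples_per_group,
             cfg$ppi_n_nodes)
  if (any(sizes < 1)) .stopf("sim_config: sizes must be positive")
  if (cfg$ppi_n_nodes > cfg$n_genes)
    .stopf("sim_config: ppi_n_nodes exceeds n_genes")
  class(cfg) <- "sim_config"
  cfg
}

.gene_ids <- function(cfg) sprintf("gene%03d", seq_len(cfg$n_genes))
.snp_ids <- function(cfg) sprintf("rs%06d",
                                  seq_len(cfg$n_blocks * cfg$block_size))
.tissue_ids <- function(cfg) sprintf("tissue%d", seq_len(cfg$n_tissues))
.chem_ids <- function(cfg) sprintf("chem%03d", seq_len(cfg$n_chemicals))

# block b occupies a 2-Mb stretch; SNP i within a block sits 1 kb apart so
# a whole block fits inside the +/- 1 Mb cis window of its genes' TSS
.snp_positions <- function(cfg) {
  block <- rep(seq_len(cfg$n_blocks), each = cfg$block_size)
  within <- rep(seq_len(cfg$block_size), times = cfg$n_blocks)
  (block - 1L) * 2000000L + (within - 1L) * 1000L + 1L
}

.gene_block <- function(cfg) ((seq_len(cfg$n_genes) - 1L) %% cfg$n_blocks) + 1L

#' Simulate a blockwise AR(1) LD matrix
#'
#' Block-diagonal over `n_blocks` blocks of `block_size` SNPs; within a
#' block, `corr(i, j) = rho^|i - j|`. AR(1) correlation matrices are
#' positive definite for `|rho| < 1`, so the result satisfies every LD
#' invariant by construction.
#'
#' @param config a `sim_config`.
#' @return An `ld_matrix`.
#' @export
sim_ld <- function(config) {
  m <- config$block_size
  idx <- seq_len(m)
  block <- config$rho^abs(outer(idx, idx, "-"))
  n <- config$n_blocks * m
  corr <- matrix(0, n, n)
  for (b in seq_len(config$n_blocks)) {
    at <- (b - 1L) * m + idx
    corr[at, at] <- block
  }
  ld_matrix(.snp_ids(config), corr)
}

#' Simulate an eQTL weight panel
#'
#' Each gene is assigned to an LD block (round-robin) and receives
#' `snps_per_gene` SNPs sampled from that block in every tissue. Base
#' weights are standard normal, tissue weights add Gaussian jitter of SD
#' `tissue_jitter`, and each vector is scaled so that the predicted
#' expression has unit variance: `w'Lw = 1`. TSS positions are the block
#' start, so every weighted SNP lies inside the cis window.
#'
#' @param config a `sim_config`.
#' @param ld the `ld_matrix` from [sim_ld()] under the same config.
#' @return A `weight_panel`. The attribute `base_weights` records, per gene,
#'   the normalized tissue-independent weight vector used as the causal
#'   architecture by [sim_gwas_z()].
#' @export
sim_weights <- function(config, ld) {
  set.seed(derive_seed("sim_weights", config$seed))
  genes <- .gene_ids(config)
  gene_block <- .gene_block(config)
  snp_pos <- .snp_positions(config)
  m <- config$block_size
  k <- config$snps_per_gene
  entries <- vector("list", config$n_genes * config$n_tissues)
  base_weights <- vector("list", config$n_genes)
  names(base_weights) <- genes
  tiss <- .tissue_ids(config)
  row <- 0L
  for (g in seq_along(genes)) {
    b <- gene_block[g]
    offset <- (b - 1L) * m
    snps <- sort(sample.int(m, k)) + offset
    Lg <- ld$corr[snps, snps, drop = FALSE]
    w0 <- rnorm(k)
    w0 <- w0 / sqrt(as.numeric(crossprod(w0, Lg %*% w0)))
    base_weights[[g]] <- setNames(w0, ld$snp_ids[snps])
    for (t in seq_along(tiss)) {
      wt <- w0 + config$tissue_jitter * rnorm(k)
      wt <- wt / sqrt(as.numeric(crossprod(wt, Lg %*% wt)))
      row <- row + 1L
      entries[[row]] <- data.frame(
        gene_id = genes[g], tissue = tiss[t], snp_id = ld$snp_ids[snps],
        weight = wt, allele_ref = "A", allele_alt = "G",
        stringsAsFactors = FALSE)
    }
  }
  tss <- data.frame(gene_id = genes, chromosome = "1",
                    position = snp_pos[(gene_block - 1L) * m + 1L],
                    stringsAsFactors = FALSE)
  panel <- weight_panel(do.call(rbind, entries), tss)
  attr(panel, "base_weights") <- base_weights
  attr(panel, "seed") <- config$seed
  panel
}

#' Simulate GWAS Z-scores under a planted-causal-gene model
#'
#' Z is drawn from a multivariate normal with covariance L and mean
#' `mu = sum_g alpha_g * (L w_g) / sqrt(w_g' L w_g)` over causal genes g,
#' where `w_g` is the gene's base weight vector from [sim_weights()]. With
#' unit-normalized weights this makes the causal gene's own TWAS Z have
#' expectation exactly `alpha_g`; with no causal genes the mean is zero and
#' per-SNP Z-scores are marginally standard normal.
#'
#' @param config a `sim_config`.
#' @param ld the matching `ld_matrix`.
#' @param panel the matching `weight_panel` (carrying `base_weights`).
#' @return A `gwas_summary`.
#' @export
sim_gwas_z <- function(config, ld, panel) {
  set.seed(derive_seed("sim_gwas_z", config$seed))
  n <- length(ld$snp_ids)
  mu <- numeric(n)
  bw <- attr(panel, "base_weights")
  if (is.null(bw)) .stopf("sim_gwas_z: panel lacks base_weights")
  for (g in names(config$causal_genes)) {
    wg <- bw[[g]]
    if (is.null(wg)) .stopf("sim_gwas_z: causal gene %s not in panel", g)
    idx <- match(names(wg), ld$snp_ids)
    quad <- as.numeric(crossprod(wg, ld$corr[idx, idx] %*% wg))
    mu <- mu + config$causal_genes[[g]] *
      as.numeric(ld$corr[, idx] %*% wg) / sqrt(quad)
  }
  # block-diagonal covariance: sample block by block via Cholesky
  m <- config$block_size
  z <- numeric(n)
  chol_block <- NULL
  for (b in seq_len(config$n_blocks)) {
    at <- (b - 1L) * m + seq_len(m)
    if (is.null(chol_block)) chol_block <- chol(ld$corr[at, at])
    z[at] <- as.numeric(crossprod(chol_block, rnorm(m)))
  }
  z <- z + mu
  pos <- .snp_positions(config)
  gwas_summary(data.frame(snp_id = ld$snp_ids, chr = "1", pos = pos,
                          ref = "A", alt = "G", z = z,
                          stringsAsFactors = FALSE),
               trait_label = sprintf("sim_seed%d", config$seed))
}

#' Simulate chemical-gene interaction sets with planted enrichment
#'
#' Active chemicals draw the configured fraction of their members from the
#' causal genes (remainder uniformly from non-causal genes); inactive
#' chemicals draw uniformly from all genes. Set sizes are uniform over
#' `set_size_range`.
#'
#' @param config a `sim_config`.
#' @return A `chemical_gene_sets`.
#' @export
sim_chemical_sets <- function(config) {
  set.seed(derive_seed("sim_chemical_sets", config$seed))
  genes <- .gene_ids(config)
  causal <- intersect(names(config$causal_genes), genes)
  noncausal <- setdiff(genes, causal)
  sets <- list()
  for (id in .chem_ids(config)) {
    size <- sample(config$set_size_range[1]:config$set_size_range[2], 1)
    frac <- if (id %in% names(config$active_chemicals))
      config$active_chemicals[[id]] else 0
    n_causal <- min(round(frac * size), length(causal))
    members <- c(sample(causal, n_causal),
                 sample(noncausal, size - n_causal))
    sets[[id]] <- list(name = paste0("chemical_", id), genes = sort(members))
  }
  out <- chemical_gene_sets(sets)
  attr(out, "seed") <- config$seed
  out
}

#' Simulate a two-group log2 expression matrix
#'
#' Values are gene baseline (N(7, 1), fixed per gene) plus the planted log2
#' fold change for case samples plus Gaussian noise of SD `expr_noise_sd`.
#'
#' @param config a `sim_config`.
#' @return An `expression_matrix`.
#' @export
sim_expression <- function(config) {
  set.seed(derive_seed("sim_expression", config$seed))
  genes <- .gene_ids(config)
  ng <- config$n_genes
  ns <- config$n_samples_per_group
  baseline <- rnorm(ng, mean = 7, sd = 1)
  lfc <- setNames(numeric(ng), genes)
  planted <- intersect(names(config$planted_lfc), genes)
  lfc[planted] <- config$planted_lfc[planted]
  samples <- c(sprintf("case%02d", seq_len(ns)),
               sprintf("ctrl%02d", seq_len(ns)))
  groups <- setNames(rep(c("case", "control"), each = ns), samples)
  is_case <- rep(c(1, 0), each = ns)
  vals <- baseline + outer(lfc, is_case) +
    matrix(rnorm(ng * 2 * ns, sd = config$expr_noise_sd), ng, 2 * ns)
  dimnames(vals) <- list(genes, samples)
  out <- expression_matrix(vals, groups)
  attr(out, "seed") <- config$seed
  out
}

#' Simulate a STRING-like PPI edge list with planted dense modules
#'
#' Planted modules are Erdos-Renyi graphs with their `within_prob` over
#' disjoint node subsets; all remaining pairs get background edges with
#' `ppi_background_prob`. Edge confidence scores are uniform on \[0.4, 1\].
#'
#' @param config a `sim_config`.
#' @return An `edge_list`; attribute `module_members` lists the planted
#'   module memberships.
#' @export
sim_ppi <- function(config) {
  set.seed(derive_seed("sim_ppi", config$seed))
  nodes <- .gene_ids(config)[seq_len(config$ppi_n_nodes)]
  n <- length(nodes)
  sizes <- vapply(config$ppi_planted_modules, `[`, numeric(1), 1)
  if (sum(sizes) > n) .stopf("sim_ppi: planted modules exceed node count")
  prob <- matrix(config$ppi_background_prob, n, n)
  at <- 0L
  members <- list()
  for (i in seq_along(config$ppi_planted_modules)) {
    size <- as.integer(config$ppi_planted_modules[[i]][1])
    wp <- config$ppi_planted_modules[[i]][2]
    idx <- at + seq_len(size)
    prob[idx, idx] <- wp
    members[[sprintf("module%d", i)]] <- nodes[idx]
    at <- at + size
  }
  pair <- which(upper.tri(prob), arr.ind = TRUE)
  keep <- runif(nrow(pair)) < prob[pair]
  pair <- pair[keep, , drop = FALSE]
  edges <- data.frame(node_a = nodes[pair[, 1]], node_b = nodes[pair[, 2]],
                      combined_score = runif(nrow(pair), 0.4, 1),
                      stringsAsFactors = FALSE)
  out <- edge_list(edges)
  attr(out, "module_members") <- members
  attr(out, "seed") <- config$seed
  out
}

#' Ground-truth ledger for a simulation
#'
#' @param config a `sim_config`.
#' @param ppi optionally, the `edge_list` from [sim_ppi()] (to copy planted
#'   module memberships); regenerated from the config when omitted.
#' @return A `sim_truth` list: `causal_genes`, `active_chemicals`,
#'   `planted_deg_genes`, `planted_module_memberships`, `seed`.
#' @export
sim_truth <- function(config, ppi = NULL) {
  if (is.null(ppi)) ppi <- sim_ppi(config)
  structure(list(
    causal_genes = names(config$causal_genes),
    active_chemicals = names(config$active_chemicals),
    planted_deg_genes = names(config$planted_lfc)[
      abs(config$planted_lfc) > 0],
    planted_module_memberships = attr(ppi, "module_members"),
    seed = config$seed), class = "sim_truth")
}

#' Generate the full synthetic fixture bundle on disk
#'
#' Writes every generated artifact as TSV plus a JSON ground-truth ledger
#' and a config echo, under `dir`.
#'
#' @param config a `sim_config`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the generated in-memory objects.
#' @export
simulate_bundle <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ld <- sim_ld(config)
  panel <- sim_weights(config, ld)
  gwas <- sim_gwas_z(config, ld, panel)
  chems <- sim_chemical_sets(config)
  expr <- sim_expression(config)
  ppi <- sim_ppi(config)
  truth <- sim_truth(config, ppi)
  write_ld(ld, file.path(dir, "ld.tsv"))
  write_weight_panel(panel, file.path(dir, "weights.tsv"),
                     file.path(dir, "gene_tss.tsv"))
  write_gwas(gwas, file.path(dir, "gwas.tsv"))
  write_chemical_sets(chems, file.path(dir, "chemical_sets.tsv"))
  write_expression(expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "groups.tsv"))
  write_edge_list(ppi, file.path(dir, "ppi_edges.tsv"))
  jsonlite::write_json(unclass(truth), file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  jsonlite::write_json(unclass(config), file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(ld = ld, panel = panel, gwas = gwas, chems = chems,
                 expr = expr, ppi = ppi, truth = truth))
}
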