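# Synthetic-data generators: construction, planted structure, determinism.

small_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, n_blocks = 4L, block_size = 10L, rho = 0.5,
             n_genes = 8L, snps_per_gene = 3L,
             causal_genes = setNames(5, "gene001"),
             n_tissues = 2L, n_chemicals = 6L,
             active_chemicals = setNames(1.0, "chem001"),
             set_size_range = c(2L, 4L), n_samples_per_group = 4L,
             planted_lfc = setNames(2, "gene001"),
             ppi_planted_modules = list(c(4, 1)), ppi_n_nodes = 8L, ...)
}

test_that("sim_ld builds a valid blockwise AR(1) matrix", {
  cfg <- small_cfg()
  ld <- sim_ld(cfg)
  expect_s3_class(ld, "ld_matrix")
  expect_equal(ld$corr[1, 2], 0.5)
  expect_equal(ld$corr[1, 3], 0.25)
  expect_equal(ld$corr[1, 11], 0)  # across blocks
  ev <- eigen(ld$corr, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)

  ident <- sim_ld(sim_config(seed = 1, n_blocks = 2, block_size = 5,
                             rho = 0, n_genes = 2, snps_per_gene = 2))
  expect_equal(ident$corr, diag(10), ignore_attr = TRUE)
})

test_that("sim_weights normalizes predicted-expression variance to 1", {
  cfg <- small_cfg()
  ld <- sim_ld(cfg)
  panel <- sim_weights(cfg, ld)
  check_cis_window(panel, sim_gwas_z(cfg, ld, panel))
  e <- panel$entries
  for (key in unique(paste(e$gene_id, e$tissue))) {
    rows <- e[paste(e$gene_id, e$tissue) == key, ]
    idx <- match(rows$snp_id, ld$snp_ids)
    quad <- as.numeric(crossprod(rows$weight,
                                 ld$corr[idx, idx] %*% rows$weight))
    expect_lt(abs(quad - 1), 1e-10)
  }
  # snps_per_gene = 1 forces a unit-magnitude weight
  cfg1 <- sim_config(seed = 2, n_blocks = 2, block_size = 5, rho = 0.4,
                     n_genes = 3, snps_per_gene = 1,
                     causal_genes = setNames(1, "gene001"),
                     ppi_n_nodes = 3, ppi_planted_modules = list(c(2, 1)))
  p1 <- sim_weights(cfg1, sim_ld(cfg1))
  expect_equal(abs(p1$entries$weight), rep(1, nrow(p1$entries)))
  expect_error(sim_config(snps_per_gene = 60, block_size = 50), "exceeds")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_cfg(seed = 9)
  ld <- sim_ld(cfg)
  p1 <- sim_weights(cfg, ld); p2 <- sim_weights(cfg, ld)
  expect_identical(p1$entries, p2$entries)
  expect_identical(sim_gwas_z(cfg, ld, p1)$z, sim_gwas_z(cfg, ld, p1)$z)
  expect_identical(unclass(sim_chemical_sets(cfg))[],
                   unclass(sim_chemical_sets(cfg))[])
  expect_identical(sim_expression(cfg)$values, sim_expression(cfg)$values)
  expect_identical(as.data.frame(sim_ppi(cfg)), as.data.frame(sim_ppi(cfg)))
  # different seeds change the draws
  cfg2 <- small_cfg(seed = 10)
  expect_false(identical(sim_gwas_z(cfg2, ld, sim_weights(cfg2, ld))$z,
                         sim_gwas_z(cfg, ld, p1)$z))
})

test_that("planted causal gene gives its own TWAS Z expectation alpha", {
  cfg <- small_cfg(seed = 5)
  ld <- sim_ld(cfg)
  panel <- sim_weights(cfg, ld)
  w <- attr(panel, "base_weights")[["gene001"]]
  idx <- match(names(w), ld$snp_ids)
  zs <- vapply(1:2000, function(i) {
    cfg_i <- cfg; cfg_i$seed <- 100000L + i
    g <- sim_gwas_z(cfg_i, ld, panel)
    twas_zscore(w, g$z[idx], ld$corr[idx, idx])
  }, numeric(1))
  se <- sd(zs) / sqrt(length(zs))
  expect_lt(abs(mean(zs) - 5), 3 * se)
  # and the statistic has roughly unit variance
  expect_lt(abs(sd(zs) - 1), 0.1)
})

test_that("null GWAS Z-scores are marginally standard normal", {
  cfg <- small_cfg(seed = 6)
  cfg$causal_genes <- setNames(numeric(0), character(0))
  ld <- sim_ld(cfg)
  panel <- sim_weights(cfg, ld)
  zs <- unlist(lapply(1:150, function(i) {
    cfg_i <- cfg; cfg_i$seed <- 200000L + i
    sim_gwas_z(cfg_i, ld, panel)$z
  }))
  ks <- suppressWarnings(ks.test(zs, "pnorm"))
  expect_gt(ks$p.value, 0.01)
})

test_that("chemical sets honor the planted active fraction", {
  cfg <- small_cfg(seed = 3)
  sets <- sim_chemical_sets(cfg)
  # active fraction 1.0 with set sizes <= number of causal genes... here
  # only one causal gene, so every active member set of size > 1 tops up
  # from non-causal genes after exhausting the causal pool
  expect_true("gene001" %in% sets$chem001$genes)
  cfg2 <- small_cfg(seed = 3)
  cfg2$causal_genes <- setNames(rep(5, 4), sprintf("gene%03d", 1:4))
  cfg2$set_size_range <- c(2L, 3L)
  sets2 <- sim_chemical_sets(cfg2)
  expect_true(all(sets2$chem001$genes %in% names(cfg2$causal_genes)))
  # inactive chemicals have no preference; just check validity
  expect_s3_class(sets2, "chemical_gene_sets")
})

test_that("expression carries the planted fold change; PPI plants cliques", {
  cfg <- small_cfg(seed = 4)
  expr <- sim_expression(cfg)
  case_mean <- rowMeans(expr$values[, expr$groups == "case"])
  ctrl_mean <- rowMeans(expr$values[, expr$groups == "control"])
  expect_gt(case_mean["gene001"] - ctrl_mean["gene001"], 1)
  null_diffs <- (case_mean - ctrl_mean)[-1]
  expect_lt(max(abs(null_diffs)), 1.5)

  ppi <- sim_ppi(cfg)
  members <- attr(ppi, "module_members")$module1
  g <- build_graph(ppi, cutoff = 0)
  sub <- igraph::induced_subgraph(g, members)
  expect_equal(igraph::ecount(sub), choose(length(members), 2))
  # background_prob = 0 leaves only planted edges
  cfg0 <- small_cfg(seed = 4, ppi_background_prob = 0)
  ppi0 <- sim_ppi(cfg0)
  nodes0 <- unique(c(ppi0$node_a, ppi0$node_b))
  expect_true(all(nodes0 %in% attr(ppi0, "module_members")$module1))
})

test_that("sim_truth is consistent with the generated universes", {
  cfg <- small_cfg(seed = 8)
  truth <- sim_truth(cfg)
  genes <- sprintf("gene%03d", seq_len(cfg$n_genes))
  expect_true(all(truth$causal_genes %in% genes))
  expect_true(all(truth$planted_deg_genes %in% genes))
  expect_true(all(unlist(truth$planted_module_memberships) %in% genes))
  sets <- sim_chemical_sets(cfg)
  expect_true(all(truth$active_chemicals %in% names(sets)))
})

test_that("simulate_bundle writes artifacts that pass their validators", {
  dir <- withr::local_tempdir()
  bundle <- simulate_bundle(small_cfg(seed = 2), dir)
  expect_s3_class(read_gwas(file.path(dir, "gwas.tsv")), "gwas_summary")
  expect_s3_class(read_ld(file.path(dir, "ld.tsv")), "ld_matrix")
  expect_s3_class(read_weight_panel(file.path(dir, "weights.tsv"),
                                    file.path(dir, "gene_tss.tsv")),
                  "weight_panel")
  expect_s3_class(read_chemical_sets(file.path(dir, "chemical_sets.tsv"),
                                     min_size = 1, max_size = 100),
                  "chemical_gene_sets")
  expect_s3_class(read_expression(file.path(dir, "expression.tsv"),
                                  file.path(dir, "groups.tsv")),
                  "expression_matrix")
  expect_s3_class(read_edge_list(file.path(dir, "ppi_edges.tsv")),
                  "edge_list")
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$seed, 2)
})
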