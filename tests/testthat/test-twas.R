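# TWAS association statistic, BH adjustment, predicted-expression
# correlation and feature clustering.

test_that("twas_zscore matches hand evaluations and the brute-force oracle", {
  # single-SNP reduction: w = e_i, L = I returns z_i
  z <- c(0.7, -1.2, 2.4)
  expect_identical(twas_zscore(c(0, 1, 0), z, diag(3)), -1.2)
  # hand evaluation: (0.5 + 0.5) / sqrt(0.5) = sqrt(2)
  expect_equal(twas_zscore(c(0.5, 0.5, 0), c(1, 1, 0), diag(3)), sqrt(2),
               tolerance = 1e-12)
  set.seed(11)
  for (rep in 1:50) {
    n <- sample(2:12, 1)
    w <- rnorm(n); zv <- rnorm(n); L <- random_corr(n)
    expect_equal(twas_zscore(w, zv, L), oracle_twas_z(w, zv, L),
                 tolerance = 1e-10)
  }
  expect_error(twas_zscore(c(0, 0), c(1, 1), diag(2)), "degenerate")
  expect_error(twas_zscore(1:3, 1:2, diag(3)), "mismatch")
})

test_that("twas_zscore is invariant to joint permutation and sign flips", {
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    w <- rnorm(n); z <- rnorm(n); L <- random_corr(n)
    z0 <- twas_zscore(w, z, L)
    perm <- sample(n)
    expect_equal(twas_zscore(w[perm], z[perm], L[perm, perm]), z0,
                 tolerance = 1e-12)
    s <- sample(c(-1, 1), n, replace = TRUE)
    expect_equal(twas_zscore(w * s, z * s, diag(s) %*% L %*% diag(s)), z0,
                 tolerance = 1e-12)
  }
})

test_that("bh_adjust is a standard step-up BH", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(13)
  for (rep in 1:40) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm], tolerance = 1e-12)
  }
})

test_that("expression_correlation matches definitions and sampling", {
  n <- 6
  set.seed(14)
  L <- ld_matrix(sprintf("rs%d", 1:n), random_corr(n))
  w <- setNames(rnorm(n), L$snp_ids)
  expect_equal(expression_correlation(w, w, L), 1, tolerance = 1e-12)
  wi <- setNames(c(1, 2), c("rs1", "rs2"))
  wj <- setNames(c(3, -1), c("rs4", "rs5"))
  Li <- ld_matrix(sprintf("rs%d", 1:6), diag(6))
  expect_equal(expression_correlation(wi, wj, Li), 0)
  # Monte-Carlo oracle: correlation of simulated predicted expressions
  wi <- setNames(rnorm(3), c("rs1", "rs2", "rs3"))
  wj <- setNames(rnorm(3), c("rs3", "rs4", "rs5"))
  r <- expression_correlation(wi, wj, L)
  Rchol <- chol(L$corr)
  x <- matrix(rnorm(50000 * n), 50000, n) %*% Rchol
  colnames(x) <- L$snp_ids
  ei <- x[, names(wi)] %*% wi
  ej <- x[, names(wj)] %*% wj
  expect_lt(abs(cor(ei, ej) - r), 0.02)
  expect_error(expression_correlation(setNames(0, "rs1"), wj, L),
               "degenerate")
})

test_that("cluster_features merges, labels and picks representatives", {
  res <- data.frame(gene_id = c("a", "b", "c", "d"),
                    p = c(0.01, 0.002, 0.04, 0.5))
  rmat <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  rmat["a", "b"] <- rmat["b", "a"] <- 0.95
  rmat["b", "c"] <- rmat["c", "b"] <- 0.95
  rmat["a", "c"] <- rmat["c", "a"] <- 0.5
  fn <- function(x, y) rmat[x, y]
  cl <- cluster_features(res, fn)
  # d excluded by p; chain a-b-c merged transitively into one cluster
  expect_equal(nrow(cl), 1)
  expect_equal(cl$relation, "merged")
  expect_equal(cl$members, "a;b;c")
  expect_equal(cl$representative, "b")

  # two uncorrelated genes stay independent singletons
  cl2 <- cluster_features(res[1:2, ], function(x, y) 0)
  expect_equal(cl2$relation, c("independent", "independent"))
  # a pair correlated between the thresholds is labelled joint
  cl3 <- cluster_features(res[1:2, ], function(x, y) 0.3)
  expect_equal(cl3$relation, c("joint", "joint"))
  # threshold: r = 0.95 merges
  cl4 <- cluster_features(res[1:2, ], function(x, y) 0.95)
  expect_equal(cl4$relation, "merged")
  # union-find closure agrees with an independent transitive-closure oracle
  set.seed(15)
  for (rep in 1:10) {
    n <- 6
    genes <- letters[1:n]
    rr <- matrix(runif(n * n), n, n, dimnames = list(genes, genes))
    rr[lower.tri(rr)] <- t(rr)[lower.tri(rr)]
    diag(rr) <- 1
    resr <- data.frame(gene_id = genes, p = runif(n, 0, 0.05))
    cl <- cluster_features(resr, function(x, y) rr[x, y])
    # oracle: connected components of the >0.9 graph by matrix powering
    adj <- (rr > 0.9) * 1; diag(adj) <- 1
    reach <- adj
    for (k in 1:n) reach <- ((reach %*% adj) > 0) * 1
    comp_oracle <- apply(reach, 1, function(row) paste(genes[row > 0],
                                                       collapse = ";"))
    expect_setequal(cl$members, unique(unname(comp_oracle)))
  }
})

test_that("run_twas produces calibrated p-values and per-tissue FDR", {
  cfg <- sim_config(seed = 21, n_blocks = 10, block_size = 20, rho = 0.6,
                    n_genes = 60, snps_per_gene = 4,
                    causal_genes = setNames(numeric(0), character(0)),
                    n_tissues = 1, ppi_n_nodes = 10,
                    ppi_planted_modules = list(c(4, 1)))
  ld <- sim_ld(cfg)
  panel <- sim_weights(cfg, ld)
  gwas <- sim_gwas_z(cfg, ld, panel)
  res <- run_twas(panel, gwas, ld)
  expect_equal(nrow(res), 60)
  expect_equal(res$p, 2 * pnorm(-abs(res$z)), tolerance = 1e-12)
  expect_equal(res$q_tissue, bh_adjust(res$p), tolerance = 1e-12)
  expect_true(all(res$n_snps_used >= 1))

  # single gene, single SNP, weight 1, z = 2 -> z = 2, p ~ 0.0455
  g1 <- gwas_summary(data.frame(snp_id = "rs1", chr = "1", pos = 100L,
                                ref = "A", alt = "G", z = 2,
                                stringsAsFactors = FALSE))
  p1 <- weight_panel(
    data.frame(gene_id = "geneX", tissue = "t1", snp_id = "rs1", weight = 1,
               allele_ref = "A", allele_alt = "G", stringsAsFactors = FALSE),
    data.frame(gene_id = "geneX", chromosome = "1", position = 100L,
               stringsAsFactors = FALSE))
  r1 <- run_twas(p1, g1, ld_matrix("rs1", matrix(1, 1, 1)))
  expect_equal(r1$z, 2)
  expect_equal(r1$p, 0.0455, tolerance = 1e-3)

  expect_error(run_twas(p1, g1, ld_matrix("rs2", matrix(1, 1, 1))),
               "no gene")
})

test_that("TWAS power is monotone in the planted effect size", {
  alphas <- c(0, 2, 4, 6)
  power <- vapply(alphas, function(a) {
    hits <- 0; total <- 0
    for (seed in 1:8) {
      cfg <- sim_config(seed = 300 + seed, n_blocks = 8, block_size = 10,
                        rho = 0.5, n_genes = 8, snps_per_gene = 3,
                        causal_genes = setNames(a, "gene001"),
                        n_tissues = 1, ppi_n_nodes = 8,
                        ppi_planted_modules = list(c(4, 1)))
      ld <- sim_ld(cfg)
      panel <- sim_weights(cfg, ld)
      res <- run_twas(panel, sim_gwas_z(cfg, ld, panel), ld)
      hits <- hits + (res$p[res$gene_id == "gene001"] < 0.05)
      total <- total + 1
    }
    hits / total
  }, numeric(1))
  expect_true(all(diff(power) >= -0.15))  # one MC standard error at n = 8
  expect_gt(power[4], 0.9)
})
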