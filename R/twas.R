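# Summary-statistics TWAS: per-gene association Z from (w, Z, L), BH
# multiple-testing correction, predicted-expression correlation and feature
# clustering.

#' TWAS association Z-statistic
#'
#' The association between genetically predicted expression and the trait,
#' computed from eQTL weights `w`, GWAS Z-scores `z` and the LD matrix `L`
#' on a shared SNP frame as `(w . z) / sqrt(w' L w)`. When `z ~ MVN(0, L)`
#' the statistic is standard normal; the square-root denominator is what
#' standardizes the weighted sum to unit variance.
#'
#' @param w numeric weight vector.
#' @param z numeric GWAS Z vector, same length.
#' @param L symmetric positive semidefinite LD matrix.
#' @return The scalar TWAS Z.
#' @export
twas_zscore <- function(w, z, L) {
  L <- as.matrix(L)
  n <- length(w)
  if (length(z) != n || nrow(L) != n || ncol(L) != n)
    .stopf("twas_zscore: length mismatch (w: %d, z: %d, L: %dx%d)",
           n, length(z), nrow(L), ncol(L))
  quad <- as.numeric(crossprod(w, L %*% w))
  if (quad <= 1e-12) .stopf("twas_zscore: degenerate predictor (w'Lw = %g)",
                            quad)
  as.numeric(crossprod(w, z)) / sqrt(quad)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH adjustment, capped at 1 and monotone in the p-value
#' ranks. Inputs outside (0, 1] are rejected.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1))
    .stopf("bh_adjust: p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Run TWAS across a weight panel
#'
#' For every gene x tissue in the panel (optionally restricted to one
#' tissue), harmonizes the weights with the GWAS records and the LD locus
#' containing the gene's SNPs, computes the TWAS Z, a two-sided normal
#' p-value, BH-adjusted q within tissue (`q_tissue`) and pooled across
#' tissues (`q_pooled`). Genes with no usable SNPs are reported in the
#' `skipped` attribute rather than the result table. A metadata column
#' `segment_id` assigns each gene to its contiguous 100-kb genomic segment
#' (TSS position divided by 100,000).
#'
#' @param panel a `weight_panel`.
#' @param gwas a `gwas_summary`.
#' @param ld_by_locus a single `ld_matrix` or a list of them, jointly
#'   covering the panel's SNPs.
#' @param tissue optional tissue id to restrict to.
#' @return data.frame with columns `gene_id`, `tissue`, `z`, `p`,
#'   `q_tissue`, `q_pooled`, `n_snps_used`, `n_snps_dropped`, `segment_id`.
#' @export
run_twas <- function(panel, gwas, ld_by_locus, tissue = NULL) {
  if (inherits(ld_by_locus, "ld_matrix")) ld_by_locus <- list(ld_by_locus)
  if (nrow(panel$entries) == 0) .stopf("run_twas: empty weight panel")
  check_cis_window(panel, gwas)
  snp_locus <- integer(0)
  for (i in seq_along(ld_by_locus))
    snp_locus[ld_by_locus[[i]]$snp_ids] <- i
  entries <- panel$entries
  if (!is.null(tissue)) {
    entries <- entries[entries$tissue %in% tissue, , drop = FALSE]
    if (nrow(entries) == 0) .stopf("run_twas: no entries for tissue %s",
                                   paste(tissue, collapse = ", "))
  }
  key <- interaction(entries$gene_id, entries$tissue, drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(entries)), key)
  tss <- setNames(panel$gene_tss$position, panel$gene_tss$gene_id)
  rows <- vector("list", length(groups))
  skipped <- character(0)
  for (i in seq_along(groups)) {
    e <- entries[groups[[i]], , drop = FALSE]
    gid <- e$gene_id[1]; tis <- e$tissue[1]
    loci <- unique(snp_locus[e$snp_id])
    loci <- loci[!is.na(loci)]
    if (length(loci) != 1) {
      skipped <- c(skipped, paste(gid, tis, sep = "/"))
      next
    }
    h <- tryCatch(harmonize(e, gwas, ld_by_locus[[loci]]),
                  error = function(err) NULL)
    if (is.null(h)) {
      skipped <- c(skipped, paste(gid, tis, sep = "/"))
      next
    }
    zstat <- twas_zscore(h$w, h$z, h$L)
    rows[[i]] <- data.frame(
      gene_id = gid, tissue = tis, z = zstat,
      p = 2 * pnorm(-abs(zstat)),
      n_snps_used = length(h$w), n_snps_dropped = h$n_dropped,
      segment_id = unname(tss[gid]) %/% 100000L,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(res)) .stopf("run_twas: no gene had usable SNPs")
  res <- res[order(res$tissue, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res$p <- pmax(res$p, .Machine$double.xmin)  # keep p in (0, 1] for BH
  res$q_tissue <- ave(res$p, res$tissue, FUN = bh_adjust)
  res$q_pooled <- bh_adjust(res$p)
  res <- res[, c("gene_id", "tissue", "z", "p", "q_tissue", "q_pooled",
                 "n_snps_used", "n_snps_dropped", "segment_id")]
  attr(res, "skipped") <- skipped
  res
}

#' Correlation between two genes' predicted expressions
#'
#' For weight vectors aligned to the SNP frame of `L` (missing SNPs padded
#' with zero weight), returns
#' `(w_i' L w_j) / sqrt((w_i' L w_i)(w_j' L w_j))`.
#'
#' @param w_i,w_j named numeric weight vectors (names are SNP ids in `L`'s
#'   frame) or plain vectors already aligned to `L`.
#' @param L an `ld_matrix` or a plain matrix.
#' @return The correlation, in \[-1, 1\].
#' @export
expression_correlation <- function(w_i, w_j, L) {
  if (inherits(L, "ld_matrix")) {
    ids <- L$snp_ids
    L <- L$corr
    if (!is.null(names(w_i))) {
      wi <- setNames(numeric(length(ids)), ids); wi[names(w_i)] <- w_i
      w_i <- wi
    }
    if (!is.null(names(w_j))) {
      wj <- setNames(numeric(length(ids)), ids); wj[names(w_j)] <- w_j
      w_j <- wj
    }
  }
  vi <- as.numeric(crossprod(w_i, L %*% w_i))
  vj <- as.numeric(crossprod(w_j, L %*% w_j))
  if (vi <= 1e-12 || vj <= 1e-12)
    .stopf("expression_correlation: degenerate predictor variance")
  r <- as.numeric(crossprod(w_i, L %*% w_j)) / sqrt(vi * vj)
  if (abs(r) > 1 + 1e-9)
    .stopf("expression_correlation: correlation outside [-1, 1]")
  max(-1, min(1, r))
}

#' Cluster TWAS features by predicted-expression correlation
#'
#' Genes with p-value at or below `p_include` enter the clustering. Pairs
#' with `|r| > r_merge` are treated as redundant (identical) and merged by
#' transitive closure (relation `"merged"`). Remaining singletons whose
#' correlation with every other included gene satisfies `|r| < r_indep` are
#' `"independent"`; singletons correlated above that floor with some other
#' feature but never above the merge threshold are labelled `"joint"`. The
#' representative of each cluster is its smallest-p member, ties broken
#' lexicographically by gene id.
#'
#' @param results data.frame with `gene_id` and `p` (one row per gene).
#' @param corr_fn function(gene_a, gene_b) returning the predicted-expression
#'   correlation.
#' @param r_merge,r_indep,p_include thresholds.
#' @return data.frame with `cluster_id`, `representative`, `relation`,
#'   `members` (semicolon-joined).
#' @export
cluster_features <- function(results, corr_fn, r_merge = 0.9,
                             r_indep = 0.008, p_include = 0.05) {
  inc <- results[results$p <= p_include, , drop = FALSE]
  inc <- inc[order(inc$gene_id), , drop = FALSE]
  genes <- inc$gene_id
  n <- length(genes)
  if (n == 0)
    return(data.frame(cluster_id = integer(0), representative = character(0),
                      relation = character(0), members = character(0),
                      stringsAsFactors = FALSE))
  absr <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      r <- abs(corr_fn(genes[i], genes[j]))
      absr[i, j] <- r; absr[j, i] <- r
    }
  }
  # union-find transitive closure of |r| > r_merge
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (absr[i, j] > r_merge) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- list()
  cid <- 0L
  for (root in sort(unique(comp))) {
    members <- which(comp == root)
    cid <- cid + 1L
    pvals <- inc$p[members]
    best <- members[order(pvals, genes[members])][1]
    if (length(members) > 1) {
      relation <- "merged"
    } else if (n == 1 || max(absr[members, -members]) < r_indep) {
      relation <- "independent"
    } else {
      relation <- "joint"
    }
    out[[cid]] <- data.frame(
      cluster_id = cid, representative = genes[best], relation = relation,
      members = paste(sort(genes[members]), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
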