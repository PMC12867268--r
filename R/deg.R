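# Two-group differential expression on a log2 matrix with fold-change and
# adjusted-p thresholds.

#' Differential expression between case and control groups
#'
#' Per gene: `log2fc` is the case-minus-control difference of group means on
#' the log2 scale; the p-value comes from a two-sided Welch (unequal
#' variance) two-sample t-test; `adj_p` is BH-adjusted across all genes. A
#' gene is flagged (`is_deg`) when `adj_p < adj_p_max` and
#' `|log2fc| > lfc_min`, both strict. When both groups have zero variance
#' and equal means the p-value is 1 by convention. Input is assumed already
#' log2-transformed; no normalization is performed.
#'
#' @param expr an `expression_matrix`.
#' @param adj_p_max,lfc_min DEG thresholds (strict inequalities).
#' @return data.frame with `gene_id`, `log2fc`, `p`, `adj_p`, `is_deg`,
#'   `direction` (`"up"`, `"down"` or `"none"`).
#' @export
diff_expr <- function(expr, adj_p_max = 0.05, lfc_min = 0.5) {
  groups <- expr$groups
  case <- expr$values[, groups == "case", drop = FALSE]
  ctrl <- expr$values[, groups == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  if (n1 < 2 || n2 < 2) .stopf("diff_expr: fewer than 2 samples per group")
  m1 <- rowMeans(case); m2 <- rowMeans(ctrl)
  v1 <- apply(case, 1, var); v2 <- apply(ctrl, 1, var)
  lfc <- m1 - m2
  se2 <- v1 / n1 + v2 / n2
  p <- rep(1, length(lfc))
  ok <- se2 > 0
  tt <- lfc[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((v1[ok] / n1)^2 / (n1 - 1) + (v2[ok] / n2)^2 / (n2 - 1))
  p[ok] <- 2 * stats::pt(-abs(tt), df)
  zero_var_diff <- !ok & lfc != 0  # deterministic separation
  p[zero_var_diff] <- .Machine$double.xmin
  p <- pmax(p, .Machine$double.xmin)
  adj_p <- bh_adjust(p)
  is_deg <- adj_p < adj_p_max & abs(lfc) > lfc_min
  direction <- ifelse(!is_deg, "none", ifelse(lfc > 0, "up", "down"))
  data.frame(gene_id = rownames(expr$values), log2fc = unname(lfc),
             p = unname(p), adj_p = unname(adj_p), is_deg = unname(is_deg),
             direction = direction, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Partition flagged DEGs into up- and down-regulated lists
#'
#' @param results output of [diff_expr()].
#' @param adj_p_max,lfc_min thresholds (strict), re-applied so loosened
#'   values can widen the selection.
#' @return list with `up` and `down` gene id vectors, each sorted by
#'   adjusted p ascending, ties by gene id.
#' @export
filter_degs <- function(results, adj_p_max = 0.05, lfc_min = 0.5) {
  flag <- results$adj_p < adj_p_max & abs(results$log2fc) > lfc_min
  pick <- function(sign_ok) {
    r <- results[flag & sign_ok, , drop = FALSE]
    r$gene_id[order(r$adj_p, r$gene_id)]
  }
  list(up = pick(results$log2fc > 0), down = pick(results$log2fc < 0))
}
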