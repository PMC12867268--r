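# Chemical-related gene-set enrichment: weighted Kolmogorov-Smirnov
# running-sum enrichment score on a TWAS-derived gene ranking, gene-label
# permutation p-values and normalized enrichment scores, BH FDR, and the
# triple significance rule (p < 0.05, FDR < 0.05, |NES| > 1).

#' Build per-gene scores from TWAS results
#'
#' Default rule `"best_p"`: for each gene, take the signed TWAS Z from the
#' tissue with the smallest p-value (ties broken lexicographically by
#' tissue). Alternative rule `"max_abs"`: the Z of largest magnitude (same
#' tie-break).
#'
#' @param twas_results data.frame from [run_twas()] (columns `gene_id`,
#'   `tissue`, `z`, `p`).
#' @param rule `"best_p"` or `"max_abs"`.
#' @return A `gene_score_table`: list with `scores` (named numeric) and
#'   `source_rule`.
#' @export
build_gene_scores <- function(twas_results, rule = c("best_p", "max_abs")) {
  rule <- match.arg(rule)
  if (nrow(twas_results) == 0) .stopf("build_gene_scores: empty input")
  ord <- switch(rule,
    best_p = order(twas_results$gene_id, twas_results$p,
                   twas_results$tissue),
    max_abs = order(twas_results$gene_id, -abs(twas_results$z),
                    twas_results$tissue))
  first <- twas_results[ord, ][!duplicated(twas_results$gene_id[ord]), ]
  structure(list(scores = setNames(first$z, first$gene_id),
                 source_rule = rule),
            class = "gene_score_table")
}

# ranked universe shared by observed and permuted ES evaluations
.rank_scores <- function(scores) {
  ord <- order(-scores, names(scores))
  list(ids = names(scores)[ord], stat = unname(scores[ord]))
}

# ES on a pre-ranked universe; hit_pos = positions of set members in the
# ranking. Hit steps are |stat|^p normalized over hits; miss steps 1/(N-Nh).
.es_ranked <- function(stat, hit_pos, p = 1) {
  N <- length(stat)
  nh <- length(hit_pos)
  steps <- rep(-1 / (N - nh), N)
  hw <- abs(stat[hit_pos])^p
  total <- sum(hw)
  if (total <= 0) .stopf("enrichment_score: all hit weights are zero")
  steps[hit_pos] <- hw / total
  run <- cumsum(steps)
  # positive deviation wins exact ties
  if (max(run) >= -min(run)) max(run) else min(run)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Genes are ranked by score descending (ties broken lexicographically by
#' gene id). Walking down the ranking, the running sum is incremented by
#' `|score|^p` (normalized by the sum over set members) at each set member
#' and decremented by `1/(N - N_hit)` at each non-member; the enrichment
#' score is the running-sum value of maximal absolute deviation (the
#' positive deviation wins an exact tie in magnitude). With
#' `p = 0` this is the classic unweighted two-sample KS statistic on ranks.
#'
#' @param scores a `gene_score_table` or a named numeric vector.
#' @param gene_set character vector of gene ids.
#' @param p weight exponent (>= 0), default 1.
#' @return list with `es`, `peak_index` (position in the ranking), and
#'   `leading_edge` (set members at or before the peak for positive ES,
#'   at or after it for negative ES).
#' @export
enrichment_score <- function(scores, gene_set, p = 1) {
  if (inherits(scores, "gene_score_table")) scores <- scores$scores
  rk <- .rank_scores(scores)
  N <- length(rk$ids)
  hit <- rk$ids %in% gene_set
  nh <- sum(hit)
  if (nh == 0) .stopf("enrichment_score: empty intersection with universe")
  if (nh == N) .stopf("enrichment_score: set equals the universe")
  hit_pos <- which(hit)
  steps <- rep(-1 / (N - nh), N)
  hw <- abs(rk$stat[hit_pos])^p
  total <- sum(hw)
  if (total <= 0) .stopf("enrichment_score: all hit weights are zero")
  steps[hit_pos] <- hw / total
  run <- cumsum(steps)
  # positive deviation wins exact ties
  if (max(run) >= -min(run)) {
    peak <- which.max(run)
  } else {
    peak <- which.min(run)
  }
  es <- run[peak]
  leading <- if (es >= 0) rk$ids[hit_pos[hit_pos <= peak]]
             else rk$ids[hit_pos[hit_pos >= peak]]
  list(es = es, peak_index = peak, leading_edge = leading)
}

#' CGSEA configuration
#'
#' @param weight_exponent KS weight exponent (>= 0).
#' @param n_perm number of gene-label permutations (>= 100 for reported
#'   p-values).
#' @param seed integer seed for the permutation stream.
#' @param min_set,max_set inclusive retained set-size bounds after
#'   restriction to the score universe.
#' @param p_max,fdr_max,nes_min_abs the triple significance thresholds.
#' @return A `cgsea_config` list.
#' @export
cgsea_config <- function(weight_exponent = 1, n_perm = 1000L, seed = 1L,
                         min_set = 5L, max_set = 500L, p_max = 0.05,
                         fdr_max = 0.05, nes_min_abs = 1.0) {
  if (n_perm < 100) .stopf("cgsea_config: n_perm must be >= 100")
  if (weight_exponent < 0) .stopf("cgsea_config: weight_exponent must be >= 0")
  structure(list(weight_exponent = weight_exponent,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 min_set = as.integer(min_set), max_set = as.integer(max_set),
                 p_max = p_max, fdr_max = fdr_max,
                 nes_min_abs = nes_min_abs), class = "cgsea_config")
}

# null |ES| sample for one set size on a pre-ranked universe
.null_es <- function(rk, size, config) {
  N <- length(rk$stat)
  vapply(seq_len(config$n_perm), function(i) {
    .es_ranked(rk$stat, sort(sample.int(N, size)), config$weight_exponent)
  }, numeric(1))
}

.perm_summary <- function(es_obs, null_es, n_perm) {
  p_perm <- (1 + sum(abs(null_es) >= abs(es_obs))) / (n_perm + 1)
  if (es_obs == 0) return(list(p_perm = p_perm, nes = 0))
  same_sign <- null_es[sign(null_es) == sign(es_obs)]
  if (length(same_sign) == 0)
    return(list(p_perm = p_perm, nes = NA_real_))
  list(p_perm = p_perm, nes = es_obs / mean(abs(same_sign)))
}

#' Permutation null, p-value and NES for one gene set
#'
#' Gene-label permutation: the set membership is reassigned uniformly at
#' random `n_perm` times with the same set size. The permutation p-value is
#' `(1 + #{|ES_perm| >= |ES_obs|}) / (n_perm + 1)` (never exactly zero); the
#' NES divides the observed ES by the mean absolute null ES of the same
#' sign. When no null permutation shares the observed sign the NES is
#' reported as `NA` and flagged.
#'
#' @param scores a `gene_score_table` or named numeric vector.
#' @param gene_set character vector of gene ids.
#' @param config a `cgsea_config`.
#' @return list with `p_perm`, `nes`, `es`, and `null_es` (the permutation
#'   sample).
#' @export
permutation_null <- function(scores, gene_set, config = cgsea_config()) {
  if (inherits(scores, "gene_score_table")) scores <- scores$scores
  obs <- enrichment_score(scores, gene_set, config$weight_exponent)
  rk <- .rank_scores(scores)
  size <- sum(rk$ids %in% gene_set)
  set.seed(config$seed)
  null_es <- .null_es(rk, size, config)
  s <- .perm_summary(obs$es, null_es, config$n_perm)
  list(p_perm = s$p_perm, nes = s$nes, es = obs$es, null_es = null_es)
}

#' Run CGSEA over a collection of chemical-gene sets
#'
#' Each set is restricted to the score universe; sets outside
#' `[min_set, max_set]` are dropped. Because the gene-label permutation null
#' depends only on the set size, null ES samples are generated once per
#' distinct retained size and shared across chemicals of that size. The
#' permutation p-values are BH-adjusted across chemicals, and a chemical is
#' flagged significant when `p_perm < p_max`, `q < fdr_max` and
#' `|NES| > nes_min_abs` simultaneously. Output is sorted by `|NES|`
#' descending.
#'
#' @param scores a `gene_score_table` or named numeric vector (the gene
#'   universe is the names of the scores).
#' @param chem_sets a `chemical_gene_sets`.
#' @param config a `cgsea_config`.
#' @return data.frame with `chemical_id`, `chemical_name`, `set_size_used`,
#'   `es`, `nes`, `p_perm`, `q`, `significant`, `leading_edge`
#'   (semicolon-joined). The attribute `universe_size` records the number of
#'   scored genes.
#' @export
run_cgsea <- function(scores, chem_sets, config = cgsea_config()) {
  if (inherits(scores, "gene_score_table")) scores <- scores$scores
  rk <- .rank_scores(scores)
  ids <- sort(names(chem_sets))
  sizes <- vapply(ids, function(id)
    sum(rk$ids %in% chem_sets[[id]]$genes), integer(1))
  keep <- sizes >= config$min_set & sizes <= config$max_set
  ids <- ids[keep]; sizes <- sizes[keep]
  if (length(ids) == 0) .stopf("run_cgsea: no set within size bounds")
  set.seed(config$seed)
  null_by_size <- list()
  for (s in sort(unique(sizes)))
    null_by_size[[as.character(s)]] <- .null_es(rk, s, config)
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    obs <- enrichment_score(setNames(rk$stat, rk$ids),
                            chem_sets[[id]]$genes, config$weight_exponent)
    s <- .perm_summary(obs$es, null_by_size[[as.character(sizes[i])]],
                       config$n_perm)
    data.frame(chemical_id = id, chemical_name = chem_sets[[id]]$name,
               set_size_used = sizes[i], es = obs$es, nes = s$nes,
               p_perm = s$p_perm,
               leading_edge = paste(obs$leading_edge, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p_perm)
  res$significant <- !is.na(res$nes) &
    res$p_perm < config$p_max & res$q < config$fdr_max &
    abs(res$nes) > config$nes_min_abs
  res <- res[order(-abs(res$nes), res$chemical_id),
             c("chemical_id", "chemical_name", "set_size_used", "es", "nes",
               "p_perm", "q", "significant", "leading_edge")]
  rownames(res) <- NULL
  attr(res, "universe_size") <- length(rk$ids)
  res
}
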