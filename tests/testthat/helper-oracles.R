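# Independent brute-force oracles and small fixture builders used across the
# suite. Oracles are deliberately naive (loops, subset scans, direct
# enumeration) and share no code with the implementation paths they check.

# step-up BH, written directly from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# naive double-loop evaluation of (w.z)/sqrt(w'Lw)
oracle_twas_z <- function(w, z, L) {
  num <- 0
  for (i in seq_along(w)) num <- num + w[i] * z[i]
  quad <- 0
  for (i in seq_along(w)) for (j in seq_along(w))
    quad <- quad + w[i] * L[i, j] * w[j]
  num / sqrt(quad)
}

# exhaustive prefix scan for the weighted KS enrichment score; returns the
# extreme positive and negative running-sum deviations so a caller can apply
# (or relax) the positive-wins tie rule
oracle_es_extremes <- function(scores, gene_set, p = 1) {
  ord <- order(-scores, names(scores))
  ids <- names(scores)[ord]
  stat <- unname(scores[ord])
  hit <- ids %in% gene_set
  N <- length(ids)
  nh <- sum(hit)
  total <- sum(abs(stat[hit])^p)
  hi <- 0; lo <- 0
  for (i in seq_len(N)) {
    hit_sum <- sum(abs(stat[seq_len(i)][hit[seq_len(i)]])^p) / total
    miss_sum <- sum(!hit[seq_len(i)]) / (N - nh)
    dev <- hit_sum - miss_sum
    if (dev > hi) hi <- dev
    if (dev < lo) lo <- dev
  }
  c(hi = hi, lo = lo)
}

oracle_es <- function(scores, gene_set, p = 1) {
  ext <- oracle_es_extremes(scores, gene_set, p)
  if (ext[["hi"]] >= -ext[["lo"]]) ext[["hi"]] else ext[["lo"]]
}

# brute-force maximal-clique MCC by subset scan (n <= 10)
oracle_mcc <- function(adj) {
  n <- nrow(adj)
  nodes <- seq_len(n)
  is_clique <- function(s) {
    if (length(s) < 2) return(FALSE)
    all(adj[s, s][upper.tri(diag(length(s)))] == 1)
  }
  out <- numeric(n)
  for (bits in seq_len(2^n - 1)) {
    s <- nodes[bitwAnd(bits, 2^(nodes - 1)) > 0]
    if (!is_clique(s)) next
    maximal <- all(vapply(setdiff(nodes, s), function(v)
      !is_clique(c(s, v)), logical(1)))
    if (maximal) out[s] <- out[s] + factorial(length(s) - 1)
  }
  out
}

# exact hypergeometric upper tail by direct pmf summation
oracle_hyper_tail <- function(k, N, K, n) {
  j <- k:min(n, K)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# random valid correlation matrix (for oracle tests, not AR(1))
random_corr <- function(n) {
  A <- matrix(rnorm(n * (n + 2)), n)
  S <- A %*% t(A)
  d <- 1 / sqrt(diag(S))
  diag(d) %*% S %*% diag(d)
}

tiny_gwas <- function(n = 5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gwas_summary(data.frame(
    snp_id = sprintf("rs%d", seq_len(n)), chr = "1",
    pos = seq_len(n) * 100L, ref = "A", alt = "G",
    z = rnorm(n), stringsAsFactors = FALSE))
}

# complete-graph edge list on the given node names
clique_edges <- function(nodes, score = 0.9) {
  pairs <- t(combn(nodes, 2))
  data.frame(node_a = pairs[, 1], node_b = pairs[, 2],
             combined_score = score, stringsAsFactors = FALSE)
}
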