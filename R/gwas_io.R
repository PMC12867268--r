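# Readers, writers and validators for every on-disk format the pipeline
# touches, plus harmonization of weights, summary statistics and LD to a
# shared SNP frame. All tables are tab-separated UTF-8 with a single header
# line; missing values are the literal "NA". Validation is eager: files are
# fully validated at read time.

# ---- GWAS summary statistics -------------------------------------------

#' Construct a validated GWAS summary-statistics table
#'
#' @param records data.frame with columns `snp_id`, `chr`, `pos`, `ref`,
#'   `alt`, `z` (GWAS Z-score for the alternate allele).
#' @param trait_label character scalar naming the trait.
#' @return A `gwas_summary` object (a data.frame).
#' @export
gwas_summary <- function(records, trait_label = "trait") {
  .require_cols(records, c("snp_id", "chr", "pos", "ref", "alt", "z"),
                "gwas_summary")
  records$snp_id <- as.character(records$snp_id)
  records$chr <- as.character(records$chr)
  records$ref <- as.character(records$ref)
  records$alt <- as.character(records$alt)
  dup <- records$snp_id[duplicated(records$snp_id)]
  if (length(dup) > 0)
    .stopf("gwas_summary: duplicated snp_id: %s",
           paste(unique(dup), collapse = ", "))
  if (any(!is.finite(records$z)))
    .stopf("gwas_summary: non-finite z for snp_id %s",
           paste(records$snp_id[!is.finite(records$z)], collapse = ", "))
  if (any(records$pos < 1))
    .stopf("gwas_summary: position < 1 for snp_id %s",
           paste(records$snp_id[records$pos < 1], collapse = ", "))
  same <- records$ref == records$alt
  if (any(same))
    .stopf("gwas_summary: ref == alt for snp_id %s",
           paste(records$snp_id[same], collapse = ", "))
  out <- records[, c("snp_id", "chr", "pos", "ref", "alt", "z")]
  rownames(out) <- NULL
  attr(out, "trait_label") <- trait_label
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Read GWAS summary statistics from TSV
#'
#' Expects header columns `snp_id`, `chr`, `pos`, `ref`, `alt`, `z`.
#' Row order is preserved.
#'
#' @param path file path.
#' @param trait_label trait name to attach.
#' @return A `gwas_summary`.
#' @export
read_gwas <- function(path, trait_label = "trait") {
  df <- .read_tsv(path)
  .require_cols(df, c("snp_id", "chr", "pos", "ref", "alt", "z"), "read_gwas")
  if (!is.numeric(df$z)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$z))))
    .stopf("read_gwas: non-numeric z at data line %s",
           paste(bad, collapse = ", "))
  }
  gwas_summary(df, trait_label = trait_label)
}

#' Write GWAS summary statistics to TSV
#' @param gwas a `gwas_summary`.
#' @param path output path.
#' @export
write_gwas <- function(gwas, path) {
  .write_tsv(as.data.frame(gwas), path)
}

# ---- LD matrices --------------------------------------------------------

#' Construct a validated LD (SNP correlation) matrix
#'
#' @param snp_ids ordered SNP identifiers.
#' @param corr symmetric correlation matrix matching `snp_ids`.
#' @return An `ld_matrix` object: list with `snp_ids` and `corr`.
#' @export
ld_matrix <- function(snp_ids, corr) {
  snp_ids <- as.character(snp_ids)
  corr <- as.matrix(corr)
  if (nrow(corr) != length(snp_ids) || ncol(corr) != length(snp_ids))
    .stopf("ld_matrix: dimensions (%d x %d) do not match %d snp_ids",
           nrow(corr), ncol(corr), length(snp_ids))
  if (anyDuplicated(snp_ids))
    .stopf("ld_matrix: duplicated snp_id: %s",
           paste(unique(snp_ids[duplicated(snp_ids)]), collapse = ", "))
  if (any(abs(diag(corr) - 1) > 1e-8))
    .stopf("ld_matrix: diagonal not 1 at snp %s",
           paste(snp_ids[abs(diag(corr) - 1) > 1e-8], collapse = ", "))
  if (any(corr < -1 - 1e-12 | corr > 1 + 1e-12))
    .stopf("ld_matrix: entries outside [-1, 1]")
  if (max(abs(corr - t(corr))) > 1e-10)
    .stopf("ld_matrix: not symmetric within 1e-10")
  ev <- min(eigen(corr, symmetric = TRUE, only.values = TRUE)$values)
  if (ev < -1e-8)
    .stopf("ld_matrix: not positive semidefinite (min eigenvalue %g)", ev)
  dimnames(corr) <- list(snp_ids, snp_ids)
  structure(list(snp_ids = snp_ids, corr = corr), class = "ld_matrix")
}

#' Read an LD matrix written by [write_ld()]
#'
#' The format is a TSV whose first column `snp_id` carries the row ids and
#' whose remaining column names repeat them in the same order.
#'
#' @param path file path.
#' @return An `ld_matrix`.
#' @export
read_ld <- function(path) {
  df <- .read_tsv(path)
  .require_cols(df, "snp_id", "read_ld")
  ids <- as.character(df$snp_id)
  mat <- as.matrix(df[, setdiff(names(df), "snp_id"), drop = FALSE])
  if (!identical(colnames(mat), ids))
    .stopf("read_ld: column ids do not match row ids in %s", path)
  storage.mode(mat) <- "double"
  ld_matrix(ids, mat)
}

#' Read an LD matrix stored as a dense whitespace-delimited square matrix
#' with a sidecar SNP-id list (one id per line)
#'
#' @param mat_path path to the dense matrix.
#' @param ids_path path to the id list.
#' @return An `ld_matrix`.
#' @export
read_ld_dense <- function(mat_path, ids_path) {
  ids <- readLines(ids_path)
  ids <- ids[nzchar(ids)]
  mat <- as.matrix(read.table(mat_path, header = FALSE))
  ld_matrix(ids, unname(mat))
}

#' Write an LD matrix to TSV
#' @param ld an `ld_matrix`.
#' @param path output path.
#' @export
write_ld <- function(ld, path) {
  df <- data.frame(snp_id = ld$snp_ids, check.names = FALSE)
  df <- cbind(df, as.data.frame(ld$corr, check.names = FALSE))
  .write_tsv(df, path)
}

# ---- Weight panels ------------------------------------------------------

#' Construct a validated eQTL weight panel
#'
#' @param entries data.frame with columns `gene_id`, `tissue`, `snp_id`,
#'   `weight`, `allele_ref`, `allele_alt`. The alleles give the orientation
#'   of the weight so it can be harmonized with GWAS records.
#' @param gene_tss data.frame with columns `gene_id`, `chromosome`,
#'   `position` (transcription start site, 1-based).
#' @param cis_window half-width in basepairs of the cis window around the
#'   TSS (closed interval); weighted SNP positions, when checkable, must lie
#'   within it.
#' @return A `weight_panel` object.
#' @export
weight_panel <- function(entries, gene_tss, cis_window = 1e6) {
  .require_cols(entries, c("gene_id", "tissue", "snp_id", "weight",
                           "allele_ref", "allele_alt"), "weight_panel")
  .require_cols(gene_tss, c("gene_id", "chromosome", "position"),
                "weight_panel gene_tss")
  for (col in c("gene_id", "tissue", "snp_id", "allele_ref", "allele_alt"))
    entries[[col]] <- as.character(entries[[col]])
  gene_tss$gene_id <- as.character(gene_tss$gene_id)
  gene_tss$chromosome <- as.character(gene_tss$chromosome)
  if (any(!is.finite(entries$weight)))
    .stopf("weight_panel: non-finite weight for snp_id %s",
           paste(entries$snp_id[!is.finite(entries$weight)], collapse = ", "))
  key <- paste(entries$gene_id, entries$tissue, sep = "\r")
  has_nz <- tapply(entries$weight != 0, key, any)
  if (!all(has_nz))
    .stopf("weight_panel: gene x tissue with no nonzero weight: %s",
           paste(gsub("\r", "/", names(has_nz)[!has_nz]), collapse = ", "))
  missing_tss <- setdiff(unique(entries$gene_id), gene_tss$gene_id)
  if (length(missing_tss) > 0)
    .stopf("weight_panel: no TSS for gene %s",
           paste(missing_tss, collapse = ", "))
  rownames(entries) <- NULL
  structure(list(entries = entries, gene_tss = gene_tss,
                 cis_window = cis_window),
            class = "weight_panel")
}

#' Check that every weighted SNP lies within its gene's cis window
#'
#' The panel format does not carry SNP positions; positions are taken from a
#' GWAS summary table sharing the SNP ids. SNPs absent from the GWAS table
#' are not checkable and are skipped.
#'
#' @param panel a `weight_panel`.
#' @param gwas a `gwas_summary` supplying SNP positions.
#' @return Invisibly `TRUE`; errors on violation.
#' @export
check_cis_window <- function(panel, gwas) {
  pos <- setNames(gwas$pos, gwas$snp_id)
  tss <- setNames(panel$gene_tss$position, panel$gene_tss$gene_id)
  e <- panel$entries
  p <- pos[e$snp_id]
  known <- !is.na(p)
  d <- abs(p[known] - tss[e$gene_id[known]])
  bad <- d > panel$cis_window
  if (any(bad))
    .stopf("weight_panel: SNP outside cis window for gene %s",
           paste(unique(e$gene_id[known][bad]), collapse = ", "))
  invisible(TRUE)
}

#' Read a weight panel from its two TSV files
#'
#' @param entries_path TSV with columns `gene_id`, `tissue`, `snp_id`,
#'   `weight`, `allele_ref`, `allele_alt`.
#' @param tss_path TSV with columns `gene_id`, `chromosome`, `position`.
#' @param cis_window half-width of the cis window in basepairs.
#' @return A `weight_panel`.
#' @export
read_weight_panel <- function(entries_path, tss_path, cis_window = 1e6) {
  weight_panel(.read_tsv(entries_path), .read_tsv(tss_path),
               cis_window = cis_window)
}

#' Write a weight panel to its two TSV files
#' @param panel a `weight_panel`.
#' @param entries_path,tss_path output paths.
#' @export
write_weight_panel <- function(panel, entries_path, tss_path) {
  .write_tsv(panel$entries, entries_path)
  .write_tsv(panel$gene_tss, tss_path)
  invisible(c(entries_path, tss_path))
}

# ---- Chemical-gene interaction sets ------------------------------------

#' Construct validated chemical-gene interaction sets
#'
#' @param sets named list; each element a list with `name` (chemical name)
#'   and `genes` (character vector of gene symbols, unique within a set).
#'   List names are the chemical ids.
#' @return A `chemical_gene_sets` object.
#' @export
chemical_gene_sets <- function(sets) {
  if (length(sets) == 0) .stopf("chemical_gene_sets: no sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    .stopf("chemical_gene_sets: sets must be named by chemical id")
  for (id in names(sets)) {
    s <- sets[[id]]
    if (length(s$genes) == 0)
      .stopf("chemical_gene_sets: empty set for chemical %s", id)
    if (anyDuplicated(s$genes))
      .stopf("chemical_gene_sets: duplicated gene in set %s", id)
  }
  structure(sets, class = "chemical_gene_sets")
}

#' Read CTD-style chemical-gene pairs from TSV
#'
#' One pair per row, columns `chemical_id`, `chemical_name`, `gene_symbol`;
#' pairs are aggregated per chemical. After optional restriction to a gene
#' universe, sets with size outside `[min_size, max_size]` are excluded;
#' the number excluded is recorded in the `n_excluded` attribute.
#'
#' @param path file path.
#' @param min_size,max_size inclusive retained set-size bounds.
#' @param universe optional character vector of analysis genes; sets are
#'   intersected with it before size filtering.
#' @return A `chemical_gene_sets`.
#' @export
read_chemical_sets <- function(path, min_size = 5, max_size = 500,
                               universe = NULL) {
  df <- .read_tsv(path)
  if (nrow(df) == 0) .stopf("read_chemical_sets: empty file %s", path)
  .require_cols(df, c("chemical_id", "chemical_name", "gene_symbol"),
                "read_chemical_sets")
  split_genes <- split(as.character(df$gene_symbol),
                       as.character(df$chemical_id))
  name_of <- tapply(as.character(df$chemical_name),
                    as.character(df$chemical_id), function(x) x[[1]])
  sets <- list()
  n_excluded <- 0L
  for (id in sort(names(split_genes))) {
    genes <- unique(split_genes[[id]])
    restricted <- if (is.null(universe)) genes else intersect(genes, universe)
    if (length(restricted) < min_size || length(restricted) > max_size) {
      n_excluded <- n_excluded + 1L
      next
    }
    sets[[id]] <- list(name = unname(name_of[[id]]), genes = restricted)
  }
  if (length(sets) == 0)
    .stopf("read_chemical_sets: no set within [%d, %d] after restriction",
           min_size, max_size)
  out <- chemical_gene_sets(sets)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Write chemical-gene sets as CTD-style pairs
#' @param sets a `chemical_gene_sets`.
#' @param path output path.
#' @export
write_chemical_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(names(sets), function(id) {
    data.frame(chemical_id = id, chemical_name = sets[[id]]$name,
               gene_symbol = sets[[id]]$genes, stringsAsFactors = FALSE)
  }))
  .write_tsv(df, path)
}

#' Read gene sets in GMT format (set id, description, tab-separated members)
#' @param path file path.
#' @return A named list of lists with `name` and `genes`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) .stopf("read_gmt: empty file %s", path)
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) .stopf("read_gmt: malformed line: %s", ln)
    sets[[parts[1]]] <- list(name = parts[2], genes = unique(parts[-(1:2)]))
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of lists with `name` and `genes`.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    paste(c(id, sets[[id]]$name, sets[[id]]$genes), collapse = "\t")
  }, character(1))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  writeLines(lines, path)
  invisible(path)
}

# ---- Expression matrices -----------------------------------------------

#' Construct a validated two-group log2 expression matrix
#'
#' @param values numeric matrix, genes in rows, samples in columns, log2
#'   scale; dimnames give gene and sample ids.
#' @param groups named character vector mapping sample id to `"case"` or
#'   `"control"`; at least 2 samples per group.
#' @return An `expression_matrix` object.
#' @export
expression_matrix <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stopf("expression_matrix: values must have gene and sample dimnames")
  if (anyDuplicated(rownames(values)))
    .stopf("expression_matrix: duplicated gene_id")
  if (!setequal(names(groups), colnames(values)))
    .stopf("expression_matrix: group labels do not cover the samples")
  groups <- groups[colnames(values)]
  if (!all(groups %in% c("case", "control")))
    .stopf("expression_matrix: group labels must be 'case' or 'control'")
  tab <- table(factor(groups, levels = c("case", "control")))
  if (any(tab < 2))
    .stopf("expression_matrix: fewer than 2 samples in group %s",
           paste(names(tab)[tab < 2], collapse = ", "))
  structure(list(values = values, groups = groups),
            class = "expression_matrix")
}

#' Read an expression matrix and its sample-group table
#'
#' @param expr_path TSV with column `gene_id` then one column per sample.
#' @param groups_path TSV with columns `sample_id`, `group`.
#' @return An `expression_matrix`.
#' @export
read_expression <- function(expr_path, groups_path) {
  df <- .read_tsv(expr_path)
  .require_cols(df, "gene_id", "read_expression")
  mat <- as.matrix(df[, setdiff(names(df), "gene_id"), drop = FALSE])
  rownames(mat) <- as.character(df$gene_id)
  storage.mode(mat) <- "double"
  g <- .read_tsv(groups_path)
  .require_cols(g, c("sample_id", "group"), "read_expression groups")
  expression_matrix(mat, setNames(as.character(g$group),
                                  as.character(g$sample_id)))
}

#' Write an expression matrix and its sample-group table
#' @param expr an `expression_matrix`.
#' @param expr_path,groups_path output paths.
#' @export
write_expression <- function(expr, expr_path, groups_path) {
  df <- data.frame(gene_id = rownames(expr$values), check.names = FALSE)
  df <- cbind(df, as.data.frame(expr$values, check.names = FALSE))
  .write_tsv(df, expr_path)
  .write_tsv(data.frame(sample_id = names(expr$groups),
                        group = unname(expr$groups)), groups_path)
  invisible(c(expr_path, groups_path))
}

# ---- Edge lists ---------------------------------------------------------

#' Construct a validated weighted edge list
#'
#' @param edges data.frame with columns `node_a`, `node_b`,
#'   `combined_score` in \[0, 1\]. Self-loops are rejected.
#' @return An `edge_list` object (a data.frame).
#' @export
edge_list <- function(edges) {
  .require_cols(edges, c("node_a", "node_b", "combined_score"), "edge_list")
  edges$node_a <- as.character(edges$node_a)
  edges$node_b <- as.character(edges$node_b)
  loops <- edges$node_a == edges$node_b
  if (any(loops))
    .stopf("edge_list: self-loop at node %s",
           paste(unique(edges$node_a[loops]), collapse = ", "))
  if (any(edges$combined_score < 0 | edges$combined_score > 1))
    .stopf("edge_list: combined_score outside [0, 1]")
  out <- edges[, c("node_a", "node_b", "combined_score")]
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Read a STRING-style weighted edge list from TSV
#' @param path file path (columns `node_a`, `node_b`, `combined_score`).
#' @return An `edge_list`.
#' @export
read_edge_list <- function(path) edge_list(.read_tsv(path))

#' Write an edge list to TSV
#' @param edges an `edge_list`.
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) .write_tsv(as.data.frame(edges), path)

# ---- Harmonization ------------------------------------------------------

#' Harmonize one gene's weights with GWAS Z-scores and an LD matrix
#'
#' Restricts all three inputs to the SNPs present in each, in LD order. A
#' weight whose (ref, alt) orientation is swapped relative to the GWAS
#' record has its sign flipped; SNPs whose allele sets match neither
#' orientation are dropped and counted. Strand-ambiguous SNPs are matched by
#' exact allele labels only; no strand flipping is attempted.
#'
#' @param entries weight-panel rows for a single gene and tissue (columns
#'   `snp_id`, `weight`, `allele_ref`, `allele_alt`).
#' @param gwas a `gwas_summary`.
#' @param ld an `ld_matrix`.
#' @return List with `w`, `z` (numeric vectors), `L` (matrix), `snp_ids`,
#'   and `n_dropped` (allele-incompatible SNPs).
#' @export
harmonize <- function(entries, gwas, ld) {
  .require_cols(entries, c("snp_id", "weight", "allele_ref", "allele_alt"),
                "harmonize")
  shared <- ld$snp_ids[ld$snp_ids %in% entries$snp_id &
                       ld$snp_ids %in% gwas$snp_id]
  ei <- match(shared, entries$snp_id)
  gi <- match(shared, gwas$snp_id)
  w <- entries$weight[ei]
  same <- entries$allele_ref[ei] == gwas$ref[gi] &
          entries$allele_alt[ei] == gwas$alt[gi]
  swapped <- entries$allele_ref[ei] == gwas$alt[gi] &
             entries$allele_alt[ei] == gwas$ref[gi]
  keep <- same | swapped
  n_dropped <- sum(!keep)
  shared <- shared[keep]
  if (length(shared) == 0) .stopf("harmonize: no usable SNPs for gene")
  w <- ifelse(swapped[keep], -w[keep], w[keep])
  z <- gwas$z[gi[keep]]
  li <- match(shared, ld$snp_ids)
  list(w = as.numeric(w), z = as.numeric(z),
       L = ld$corr[li, li, drop = FALSE],
       snp_ids = shared, n_dropped = n_dropped)
}
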