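# Orchestration: simulate -> per-tissue TWAS -> overlaps -> differential
# expression intersection -> CGSEA -> network and over-representation
# post-processing, from a single configuration, with a ground-truth recovery
# report and a deterministic run manifest.

#' Pipeline configuration
#'
#' @param sim a `sim_config` describing the synthetic inputs.
#' @param twas_fdr FDR threshold for headline TWAS significance.
#' @param twas_p per-tissue nominal p threshold defining the overlap
#'   universe (the wider gene pool intersected with DEGs).
#' @param deg_adj_p,deg_lfc DEG thresholds.
#' @param cgsea a `cgsea_config`.
#' @param string_cutoff confidence-score cutoff for the PPI graph.
#' @param epc_iters EPC Monte-Carlo iterations.
#' @param out_dir output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), twas_fdr = 0.05,
                            twas_p = 0.05, deg_adj_p = 0.05, deg_lfc = 0.5,
                            cgsea = cgsea_config(seed = derive_seed("cgsea",
                                                                    sim$seed)),
                            string_cutoff = 0.4, epc_iters = 1000L,
                            out_dir = tempfile("chemtwas_run_")) {
  thr <- c(twas_fdr, twas_p, deg_adj_p, cgsea$p_max, cgsea$fdr_max)
  if (any(thr <= 0 | thr > 1))
    .stopf("pipeline_config: thresholds must lie in (0, 1]")
  structure(list(sim = sim, twas_fdr = twas_fdr, twas_p = twas_p,
                 deg_adj_p = deg_adj_p, deg_lfc = deg_lfc, cgsea = cgsea,
                 string_cutoff = string_cutoff,
                 epc_iters = as.integer(epc_iters), out_dir = out_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `sim`, `cgsea` and the scalar thresholds mirror the
#' arguments of [pipeline_config()], [sim_config()] and [cgsea_config()];
#' omitted keys take the defaults. `sim$causal_genes`, `sim$active_chemicals`
#' and `sim$planted_lfc` are YAML mappings from id to value.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  simargs <- raw$sim %||% list()
  for (key in c("causal_genes", "active_chemicals", "planted_lfc"))
    if (!is.null(simargs[[key]]))
      simargs[[key]] <- unlist(simargs[[key]])
  if (!is.null(simargs$ppi_planted_modules))
    simargs$ppi_planted_modules <- lapply(simargs$ppi_planted_modules,
                                          unlist)
  sim <- do.call(sim_config, simargs)
  cgargs <- raw$cgsea %||% list()
  if (is.null(cgargs$seed)) cgargs$seed <- derive_seed("cgsea", sim$seed)
  args <- raw[setdiff(names(raw), c("sim", "cgsea"))]
  args$sim <- sim
  args$cgsea <- do.call(cgsea_config, cgargs)
  do.call(pipeline_config, args)
}

#' Intersection of per-tissue significant gene sets
#'
#' @param per_tissue_sets list (length >= 2) of gene id vectors.
#' @return Character vector: the exact set intersection, sorted.
#' @export
cross_tissue_overlap <- function(per_tissue_sets) {
  if (length(per_tissue_sets) < 2)
    .stopf("cross_tissue_overlap: need at least 2 tissue sets")
  sort(Reduce(intersect, per_tissue_sets))
}

#' Overlap ratio as a printed percentage
#'
#' `100 * numerator / denominator`, rounded half-even to 2 decimals.
#'
#' @param numerator,denominator non-negative integers, `numerator <=
#'   denominator`, `denominator > 0`.
#' @return The percentage, rounded to 2 decimals.
#' @export
overlap_ratio <- function(numerator, denominator) {
  if (denominator <= 0) .stopf("overlap_ratio: denominator must be > 0")
  if (numerator < 0 || numerator > denominator)
    .stopf("overlap_ratio: numerator must lie in [0, denominator]")
  round(100 * numerator / denominator, 2)
}

.jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Run the full pipeline on synthetic inputs
#'
#' Executes every stage in order — simulation, per-tissue TWAS, cross-tissue
#' and TWAS-DEG overlaps, differential expression, CGSEA on the TWAS gene
#' ranking, PPI hub/module analysis, over-representation of the significant
#' TWAS genes against the chemical sets — writing one TSV per stage plus a
#' run manifest and a ground-truth recovery report under
#' `config$out_dir`. All randomness is derived from `config$sim$seed`, so
#' rerunning with an identical config reproduces byte-identical outputs.
#'
#' @param config a `pipeline_config`.
#' @return Invisibly, a list with every stage result (`twas`, `deg`,
#'   `cgsea`, `hubs`, `modules`, `ora`, `overlap`, `recovery`, `truth`,
#'   `manifest`).
#' @export
run_all <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  message("stage 1/6: simulate")
  bundle <- simulate_bundle(config$sim, file.path(out, "sim"))
  truth <- bundle$truth

  message("stage 2/6: twas")
  twas <- run_twas(bundle$panel, bundle$gwas, bundle$ld)
  .write_tsv(twas, file.path(out, "twas.tsv"))
  tissues <- sort(unique(twas$tissue))
  sig_fdr <- lapply(tissues, function(t)
    twas$gene_id[twas$tissue == t & twas$q_tissue < config$twas_fdr])
  names(sig_fdr) <- tissues
  sig_p <- lapply(tissues, function(t)
    twas$gene_id[twas$tissue == t & twas$p < config$twas_p])
  names(sig_p) <- tissues
  cross <- cross_tissue_overlap(sig_fdr)

  message("stage 3/6: differential expression")
  deg <- diff_expr(bundle$expr, adj_p_max = config$deg_adj_p,
                   lfc_min = config$deg_lfc)
  .write_tsv(deg, file.path(out, "deg.tsv"))
  deg_genes <- deg$gene_id[deg$is_deg]

  ratio_rows <- lapply(tissues, function(t) {
    genes_t <- unique(sig_p[[t]])
    ov <- intersect(genes_t, deg_genes)
    rbind(
      data.frame(line = paste0(t, "_overlap_of_twas"),
                 numerator = length(ov), denominator = length(genes_t),
                 percent = if (length(genes_t) > 0)
                   overlap_ratio(length(ov), length(genes_t)) else NA_real_),
      data.frame(line = paste0(t, "_overlap_of_deg"),
                 numerator = length(ov), denominator = length(deg_genes),
                 percent = if (length(deg_genes) > 0)
                   overlap_ratio(length(ov), length(deg_genes)) else NA_real_))
  })
  overlap <- list(sig_fdr = sig_fdr, sig_p = sig_p, cross_tissue = cross,
                  ratios = do.call(rbind, ratio_rows))
  .write_tsv(overlap$ratios, file.path(out, "overlap_ratios.tsv"))
  writeLines(cross, file.path(out, "cross_tissue_genes.txt"))

  message("stage 4/6: cgsea")
  scores <- build_gene_scores(twas)
  universe <- names(scores$scores)
  chems <- bundle$chems
  cg <- run_cgsea(scores, chems, config$cgsea)
  .write_tsv(cg, file.path(out, "cgsea.tsv"))

  message("stage 5/6: network")
  graph <- build_graph(bundle$ppi, cutoff = config$string_cutoff)
  hubs <- hub_scores(graph, epc_iters = config$epc_iters,
                     epc_seed = derive_seed("epc", config$sim$seed))
  modules <- mcode(graph)
  .write_tsv(hubs, file.path(out, "hub_scores.tsv"))
  .write_tsv(modules, file.path(out, "mcode_modules.tsv"))

  message("stage 6/6: over-representation")
  query <- sort(unique(twas$gene_id[twas$q_pooled < config$twas_fdr]))
  ora_res <- if (length(query) > 0)
    ora(query, chems, universe) else NULL
  if (!is.null(ora_res)) .write_tsv(ora_res, file.path(out, "ora.tsv"))

  # ground-truth recovery
  detected_genes <- sort(unique(twas$gene_id[twas$q_pooled <
                                               config$twas_fdr]))
  flagged_chems <- cg$chemical_id[cg$significant]
  prec_rec <- function(found, planted) {
    c(precision = if (length(found) > 0)
        length(intersect(found, planted)) / length(found) else NA_real_,
      recall = if (length(planted) > 0)
        length(intersect(found, planted)) / length(planted) else NA_real_)
  }
  gene_pr <- prec_rec(detected_genes, truth$causal_genes)
  chem_pr <- prec_rec(flagged_chems, truth$active_chemicals)
  deg_pr <- prec_rec(deg_genes, truth$planted_deg_genes)
  module_jaccard <- vapply(truth$planted_module_memberships,
                           function(planted) {
    if (nrow(modules) == 0) return(0)
    found <- strsplit(top_modules(modules)$members, ";", fixed = TRUE)
    max(vapply(found, .jaccard, numeric(1), b = planted))
  }, numeric(1))
  recovery <- data.frame(
    metric = c("causal_gene_precision", "causal_gene_recall",
               "active_chemical_precision", "active_chemical_recall",
               "planted_deg_precision", "planted_deg_recall",
               paste0("module_jaccard_",
                      names(truth$planted_module_memberships))),
    value = c(gene_pr, chem_pr, deg_pr, module_jaccard),
    stringsAsFactors = FALSE)
  .write_tsv(recovery, file.path(out, "recovery.tsv"))

  manifest <- list(
    seed = config$sim$seed,
    package_version = as.character(utils::packageVersion("chemtwas")),
    thresholds = list(twas_fdr = config$twas_fdr, twas_p = config$twas_p,
                      deg_adj_p = config$deg_adj_p, deg_lfc = config$deg_lfc,
                      cgsea_p = config$cgsea$p_max,
                      cgsea_fdr = config$cgsea$fdr_max,
                      cgsea_nes = config$cgsea$nes_min_abs,
                      string_cutoff = config$string_cutoff),
    rows = list(twas = nrow(twas), deg = nrow(deg), cgsea = nrow(cg),
                hubs = nrow(hubs), modules = nrow(modules),
                ora = if (is.null(ora_res)) 0L else nrow(ora_res)),
    twas_skipped = attr(twas, "skipped"),
    cgsea_universe = attr(cg, "universe_size"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(twas = twas, deg = deg, cgsea = cg, hubs = hubs,
                 modules = modules, ora = ora_res, overlap = overlap,
                 recovery = recovery, truth = truth, manifest = manifest))
}
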