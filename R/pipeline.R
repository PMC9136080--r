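# End-to-end pipeline: ADME screen -> component-target assembly -> merged
# disease-target network -> importance/FRS -> UET + validation coverage ->
# greedy KFCG selection -> PES -> reports + reproducibility manifest.

#' Pipeline configuration
#'
#' @param edges,genes,components,ct,gmt Input file paths (PPI edge TSV,
#'   evidence gene TSV, component TSV, component-target pair TSV, pathway
#'   GMT).
#' @param frs_rule `"median"` (default) or `"mean"`.
#' @param ccr_threshold KFCG coverage threshold (default 0.90).
#' @param alpha Enrichment cutoff (default 0.01).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when inputs are generated).
#' @param outdir Output directory.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(edges, genes, components, ct, gmt,
                            frs_rule = "median", ccr_threshold = 0.90,
                            alpha = 0.01, seed = 1L, outdir = tempfile()) {
  paths <- c(edges = edges, genes = genes, components = components,
             ct = ct, gmt = gmt)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("input file(s) not found: ", paste(missing, collapse = ", "))
  }
  stopifnot(frs_rule %in% c("median", "mean"),
            ccr_threshold > 0, ccr_threshold <= 1, alpha > 0, alpha < 1)
  structure(list(paths = paths, frs_rule = frs_rule,
                 ccr_threshold = ccr_threshold, alpha = alpha,
                 seed = as.integer(seed), outdir = outdir),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full network-pharmacology workflow
#'
#' Executes every stage in order and writes `frs.tsv`, `kfcg.json`,
#' `pes.tsv`, `coverage.json` and `manifest.json` (input checksums,
#' parameters, package version) under the configured output directory.
#' Every stage is a pure function of the inputs and parameters, so reruns
#' with identical inputs are byte-identical.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a list with all stage results: `ppi`, `merged`,
#'   `ranked`, `frs`, `uet`, `validation`, `ccr`, `pes`, `manifest`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$outdir)) dir.create(config$outdir, recursive = TRUE)

  comps <- .stage("adme", {
    tab <- read_component_table(config$paths[["components"]])
    scr <- adme_filter(tab)
    lit <- tab[tab$source == "literature", , drop = FALSE]
    merge_literature(scr$pass, lit)
  })
  ctmap <- .stage("ct_assembly", {
    m <- read_ct_map(config$paths[["ct"]])
    m[names(m) %in% comps$component_id]
  })
  if (!length(ctmap)) stop("pipeline stage 'ct_assembly' failed: no active ",
                           "component has targets", call. = FALSE)
  gene_tab <- .stage("gene_table", read_gene_table(config$paths[["genes"]]))
  ppi <- .stage("network", {
    g <- load_edge_list(config$paths[["edges"]])
    attach_weights(g, gene_tab)
  })
  merged <- .stage("merge", merge_disease_target_network(
    ppi, gene_tab$gene_id, unique(unlist(ctmap, use.names = FALSE))))
  ranked <- .stage("importance", score_all(merged))
  frs <- .stage("frs", select_frs(ranked, rule = config$frs_rule))
  pathways <- .stage("gmt", read_gmt(config$paths[["gmt"]]))
  uet_genes <- .stage("uet", uet(unlist(ctmap, use.names = FALSE),
                                 gene_tab$gene_id))
  validation <- .stage("validation", {
    if (length(uet_genes)) {
      frs_validation(frs$selected, uet_genes,
                     list(pathways = pathways), alpha = config$alpha)
    } else NULL
  })
  ccr <- .stage("ccr", ccr_select(ctmap, frs$selected,
                                  threshold = config$ccr_threshold))
  pes <- .stage("pes", {
    kf <- ctmap[ccr$selected]
    ctp <- build_ctp(kf, pathways)
    normalize_pes(compute_all_pes(ctp))
  })

  write_frs_table(ranked, frs, file.path(config$outdir, "frs.tsv"))
  write_ccr(ccr, kfcg_path = file.path(config$outdir, "kfcg.json"))
  write_pes(pes, file.path(config$outdir, "pes.tsv"))
  cov_out <- list(
    uet_size = length(uet_genes),
    frs_size = frs$n_selected,
    kfcg_size = length(ccr$selected),
    kfcg_coverage_percent = round(100 * ccr$coverage, 2),
    validation = if (is.null(validation)) NULL else
      lapply(validation, function(r)
        list(shared = r$shared_count, reference = r$reference_count,
             coverage_percent = r$coverage_percent)))
  jsonlite::write_json(cov_out, file.path(config$outdir, "coverage.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("netpharm")),
    parameters = list(frs_rule = config$frs_rule,
                      ccr_threshold = config$ccr_threshold,
                      alpha = config$alpha, seed = config$seed),
    inputs = as.list(tools::md5sum(unname(config$paths))))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(components = comps, ctmap = ctmap, ppi = ppi,
                 merged = merged, ranked = ranked, frs = frs,
                 uet = uet_genes, validation = validation, ccr = ccr,
                 pes = pes, manifest = manifest))
}
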