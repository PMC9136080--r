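# Seeded synthetic-data generators.
#
# The generators emulate the statistical shape of the real inputs: a
# connected scale-free-like PPI/disease-target network (preferential
# attachment, heavy-tailed degrees), a pathogenetic gene list with
# geometric literature-evidence counts (few genes exceed 15 supports), a
# bipartite component-target map with heavy-tailed target-set sizes, and
# pathway gene sets overlapping both targets and disease genes. All
# functions are deterministic under the config seed.

#' Synthetic-data configuration
#'
#' @param seed Integer RNG seed; identical seed gives identical outputs.
#' @param n_genes Genes in the network (the disease-target universe).
#' @param n_disease_genes Pathogenetic genes with evidence counts.
#' @param evidence_prob Geometric success probability for evidence counts
#'   (counts = 1 + Geom(p); p = 0.2 leaves a few percent of genes above 15
#'   supports, echoing the heavy literature tail).
#' @param pa_m Preferential-attachment edges added per node (controls
#'   density; 14 at 1,836 nodes gives ~25k edges).
#' @param n_components Candidate components.
#' @param target_meanlog,target_sdlog Log-normal parameters of per-component
#'   target-set sizes (heavy-tailed: a few components have very many
#'   targets).
#' @param n_pathways Gene sets in the synthetic pathway collection.
#' @param pathway_size Integer range (min, max) of pathway sizes.
#' @param overlap Fraction of each pathway drawn from the disease-target
#'   overlap pool (keeps UET enrichment and coverage non-degenerate).
#' @param coverage_target Fraction of all genes the union of active
#'   components' targets is guaranteed to reach (makes >= 90% coverage of
#'   any upper-half effective-protein set achievable by construction).
#' @param n_background Extra genome-background genes added to the pathway
#'   collection and its universe (real pathway collections span far more
#'   genes than any one disease network; without a wider background,
#'   enrichment of a query holding half the universe is degenerate).
#' @param literature_fraction Fraction of components curated from
#'   literature (no ADME properties; rescued by [merge_literature()]).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_genes = 200L, n_disease_genes = 120L,
                       evidence_prob = 0.2, pa_m = 3L, n_components = 40L,
                       target_meanlog = log(8), target_sdlog = 1,
                       n_pathways = 25L, pathway_size = c(5L, 25L),
                       overlap = 0.6, coverage_target = 0.97,
                       literature_fraction = 0.2, n_background = NULL) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_disease_genes = as.integer(n_disease_genes),
              evidence_prob = evidence_prob, pa_m = as.integer(pa_m),
              n_components = as.integer(n_components),
              target_meanlog = target_meanlog, target_sdlog = target_sdlog,
              n_pathways = as.integer(n_pathways),
              pathway_size = as.integer(pathway_size), overlap = overlap,
              coverage_target = coverage_target,
              literature_fraction = literature_fraction,
              n_background = as.integer(
                if (is.null(n_background)) 2L * n_genes else n_background))
  stopifnot(cfg$n_genes >= 2L, cfg$n_disease_genes >= 1L,
            cfg$n_disease_genes <= cfg$n_genes, cfg$pa_m >= 1L,
            cfg$n_components >= 1L, cfg$n_pathways >= 1L,
            length(cfg$pathway_size) == 2L,
            cfg$pathway_size[1L] >= 1L,
            cfg$pathway_size[2L] <= cfg$n_genes,
            cfg$overlap >= 0, cfg$overlap <= 1,
            cfg$coverage_target > 0, cfg$coverage_target <= 1,
            cfg$evidence_prob > 0, cfg$evidence_prob <= 1,
            cfg$n_background >= 0L)
  class(cfg) <- "sim_config"
  cfg
}

#' Preset configurations
#'
#' `"toy"` is a hand-checkable 20-gene instance; `"paper_scale"` matches
#' the scale of a published stroke study: a 1,836-node disease-target
#' network (1,012 pathogenetic genes), 334 candidate components and 150
#' pathway sets.
#'
#' @param preset `"toy"` or `"paper_scale"`.
#' @param seed RNG seed.
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("toy", "paper_scale"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "toy") {
    sim_config(seed = seed, n_genes = 20L, n_disease_genes = 12L,
               pa_m = 2L, n_components = 6L, target_meanlog = log(5),
               target_sdlog = 0.6, n_pathways = 5L,
               pathway_size = c(3L, 8L), coverage_target = 0.95)
  } else {
    sim_config(seed = seed, n_genes = 1836L, n_disease_genes = 1012L,
               pa_m = 14L, n_components = 334L, target_meanlog = log(15),
               target_sdlog = 1.1, n_pathways = 150L,
               pathway_size = c(10L, 80L), overlap = 0.6,
               coverage_target = 0.97)
  }
}

.gene_names <- function(n) sprintf("G%05d", seq_len(n))
.component_names <- function(n) sprintf("CMP%04d", seq_len(n))

#' Generate a connected scale-free-like gene network
#'
#' Preferential attachment (Barabasi-Albert) with `pa_m` edges per added
#' node: connected, simple and heavy-tailed by construction.
#'
#' @param cfg A `sim_config`.
#' @param path Optional TSV path; when given, the edge list is written.
#' @return An undirected simple igraph with gene names `G00001`, ...
#' @export
generate_ppi <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$pa_m >= cfg$n_genes) stop("pa_m must be below n_genes")
  set.seed(cfg$seed)
  g <- igraph::sample_pa(cfg$n_genes, m = cfg$pa_m, directed = FALSE)
  g <- igraph::simplify(g)
  g <- igraph::set_vertex_attr(g, "name", value = .gene_names(cfg$n_genes))
  if (!is.null(path)) write_edge_list(g, path)
  g
}

#' Generate a pathogenetic gene table with evidence counts
#'
#' Evidence counts are 1 + Geometric(`evidence_prob`): every gene has at
#' least one supporting report and the tail is heavy, so only a small
#' fraction exceeds 15 supports.
#'
#' @param cfg A `sim_config`.
#' @param path Optional TSV path.
#' @return data.frame `gene_id`, `evidence_count`.
#' @export
generate_disease_genes <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  genes <- sort(sample(.gene_names(cfg$n_genes), cfg$n_disease_genes))
  counts <- 1L + stats::rgeom(cfg$n_disease_genes, cfg$evidence_prob)
  df <- data.frame(gene_id = genes, evidence_count = counts,
                   stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  df
}

#' Generate a candidate component table with ADME properties
#'
#' Database-sourced components get plausible OB/Caco-2/DL/MW draws;
#' literature-sourced components carry only a molecular weight (their ADME
#' fields are missing, so they fail the screen and enter via the
#' literature-merge route).
#'
#' @param cfg A `sim_config`.
#' @param path Optional TSV path.
#' @return Component data.frame (see [read_component_table()]).
#' @export
generate_components <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  n <- cfg$n_components
  ids <- .component_names(n)
  lit <- stats::runif(n) < cfg$literature_fraction
  herbs <- paste0("H", sample(1:12, n, replace = TRUE))
  df <- data.frame(
    component_id = ids,
    name = paste0("compound-", seq_len(n)),
    herbs = herbs,
    ob = ifelse(lit, NA, round(stats::rnorm(n, 40, 15), 2)),
    caco2 = ifelse(lit, NA, round(stats::rnorm(n, 0.5, 0.6), 2)),
    dl = ifelse(lit, NA, round(stats::rbeta(n, 2, 6), 2)),
    mw = round(stats::rnorm(n, 300, 80), 2),
    source = ifelse(lit, "literature", "database"),
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  }
  df
}

#' Generate the component-target map and pathway gene sets
#'
#' Target-set sizes are log-normal (heavy-tailed). Two construction
#' guarantees make the downstream pipeline feasible: every gene outside the
#' disease list is targeted by at least one component (so the merged
#' disease-target network spans all `n_genes` genes), and the union of all
#' component targets reaches at least `coverage_target` of the gene
#' universe (so greedy selection can reach 90% coverage of any upper-half
#' effective-protein set). Pathway members mix the disease-target overlap
#' pool with the whole universe in proportion `overlap`.
#'
#' @param cfg A `sim_config`.
#' @param components Optional character vector of component ids to map
#'   (defaults to all of [generate_components()]'s ids).
#' @param disease_genes Optional character vector (defaults to
#'   [generate_disease_genes()]'s genes under the same seed).
#' @param ppi Optional igraph over the gene universe. When supplied, target
#'   sampling is degree-proportional, emulating the well-documented hub
#'   bias of real drug targets; this also keeps the enrichment-based
#'   validation metrics non-degenerate.
#' @param ct_path,gmt_path Optional output paths (pair TSV and GMT).
#' @return List with `ctmap` (named list) and `pathways`
#'   (`gene_set_collection` over the gene universe).
#' @export
generate_ct_and_pathways <- function(cfg, components = NULL,
                                     disease_genes = NULL, ppi = NULL,
                                     ct_path = NULL, gmt_path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  genes <- .gene_names(cfg$n_genes)
  if (is.null(components)) components <- .component_names(cfg$n_components)
  if (is.null(disease_genes)) {
    disease_genes <- generate_disease_genes(cfg)$gene_id
  }
  set.seed(cfg$seed + 3L)
  sizes <- pmax(1L, pmin(cfg$n_genes, round(stats::rlnorm(
    length(components), cfg$target_meanlog, cfg$target_sdlog))))
  w <- if (is.null(ppi)) NULL else
    igraph::degree(ppi)[genes] + 1
  ctmap <- stats::setNames(
    lapply(sizes, function(s) sample(genes, s, prob = w)), components)
  # guarantee 1: every non-disease gene is someone's target
  uncovered <- setdiff(setdiff(genes, disease_genes),
                       unlist(ctmap, use.names = FALSE))
  for (gn in uncovered) {
    k <- sample(length(ctmap), 1L)
    ctmap[[k]] <- c(ctmap[[k]], gn)
  }
  # guarantee 2: union of targets reaches coverage_target of the universe
  need <- ceiling(cfg$coverage_target * cfg$n_genes)
  uncovered <- setdiff(genes, unlist(ctmap, use.names = FALSE))
  extra <- max(0L, need - (cfg$n_genes - length(uncovered)))
  if (extra > 0L) {
    for (gn in sample(uncovered, extra)) {
      k <- sample(length(ctmap), 1L)
      ctmap[[k]] <- c(ctmap[[k]], gn)
    }
  }
  ctmap <- lapply(ctmap, function(t) sort(unique(t)))
  covered <- length(unique(unlist(ctmap, use.names = FALSE)))
  stopifnot(covered >= need)  # post-generation feasibility assertion
  # pathways: mix the UET-like pool with a genome-scale background universe
  pool <- intersect(unlist(ctmap, use.names = FALSE), disease_genes)
  if (!length(pool)) pool <- genes
  background <- c(genes, if (cfg$n_background > 0L)
    sprintf("B%05d", seq_len(cfg$n_background)))
  sets <- lapply(seq_len(cfg$n_pathways), function(i) {
    s <- sample(seq(cfg$pathway_size[1L], cfg$pathway_size[2L]), 1L)
    n_in <- min(length(pool), round(cfg$overlap * s))
    unique(c(sample(pool, n_in), sample(background, s - n_in)))
  })
  names(sets) <- sprintf("PWY%04d", seq_len(cfg$n_pathways))
  pathways <- gene_set_collection(sets, universe = background)
  if (!is.null(ct_path)) {
    pairs <- do.call(rbind, lapply(names(ctmap), function(k)
      if (length(ctmap[[k]])) cbind(k, ctmap[[k]]) else NULL))
    utils::write.table(
      data.frame(component_id = pairs[, 1L], target_gene = pairs[, 2L]),
      ct_path, sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  if (!is.null(gmt_path)) write_gmt(pathways, gmt_path)
  list(ctmap = ctmap, pathways = pathways)
}

#' Generate a complete synthetic input bundle
#'
#' Runs every generator under one config and, when `outdir` is given,
#' writes the standard files: `ppi_edges.tsv`, `disease_genes.tsv`,
#' `components.tsv`, `ct_pairs.tsv`, `pathways.gmt`.
#'
#' @param cfg A `sim_config` (e.g. from [sim_preset()]).
#' @param outdir Optional output directory (created if absent).
#' @return List with `cfg`, `ppi`, `disease_genes`, `components`, `ctmap`,
#'   `pathways`.
#' @export
generate_all <- function(cfg, outdir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- function(f) if (is.null(outdir)) NULL else file.path(outdir, f)
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  ppi <- generate_ppi(cfg, path = p("ppi_edges.tsv"))
  dg <- generate_disease_genes(cfg, path = p("disease_genes.tsv"))
  comps <- generate_components(cfg, path = p("components.tsv"))
  # the coverage guarantee must hold for the components that survive the
  # ADME screen (plus literature rescues), i.e. those the pipeline maps
  active <- merge_literature(adme_filter(comps)$pass,
                             comps[comps$source == "literature", ,
                                   drop = FALSE])
  ctp <- generate_ct_and_pathways(cfg, components = active$component_id,
                                  disease_genes = dg$gene_id, ppi = ppi,
                                  ct_path = p("ct_pairs.tsv"),
                                  gmt_path = p("pathways.gmt"))
  list(cfg = cfg, ppi = ppi, disease_genes = dg, components = comps,
       ctmap = ctp$ctmap, pathways = ctp$pathways)
}
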