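# Hypergeometric over-representation analysis (ORA), un-optimized effective
# targets (UET), and the coverage metrics used to validate the FRS and KFCG.

#' Build a gene-set collection
#'
#' @param sets Named list: term id -> character vector of member genes.
#' @param universe Background gene universe; defaults to the union of all
#'   set members.
#' @param names Optional named character vector of human-readable term
#'   names (term id -> name).
#' @return A list of class `gene_set_collection` with `sets`, `universe`,
#'   `term_names`.
#' @export
gene_set_collection <- function(sets, universe = NULL, names = NULL) {
  stopifnot(is.list(sets), !is.null(base::names(sets)))
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (any(lengths(sets) == 0L)) stop("empty gene set in collection")
  if (is.null(universe)) {
    universe <- unique(unlist(sets, use.names = FALSE))
  } else {
    universe <- unique(as.character(universe))
    out <- setdiff(unlist(sets, use.names = FALSE), universe)
    if (length(out)) {
      stop("gene set members outside the universe: ",
           paste(utils::head(out, 5), collapse = ", "))
    }
  }
  structure(list(sets = sets, universe = universe,
                 term_names = names), class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' Standard gene-matrix-transposed format: one set per line,
#' `term_id<TAB>term_name<TAB>gene1<TAB>gene2...`.
#'
#' @param path GMT file.
#' @param universe Optional explicit background; defaults to all genes seen.
#' @return A `gene_set_collection`.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) stop("malformed GMT line(s): ", paste(bad, collapse = ", "))
  ids <- vapply(parts, `[[`, "", 1L)
  nms <- vapply(parts, `[[`, "", 2L)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  base::names(sets) <- ids
  gene_set_collection(sets, universe = universe,
                      names = stats::setNames(nms, ids))
}

#' Write a gene-set collection as GMT
#'
#' @param collection A `gene_set_collection`.
#' @param path Output file.
#' @export
write_gmt <- function(collection, path) {
  ids <- base::names(collection$sets)
  nms <- if (is.null(collection$term_names)) ids else
    collection$term_names[ids]
  lines <- vapply(seq_along(ids), function(i) {
    paste(c(ids[i], nms[i], collection$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Un-optimized effective targets: intersection of targets and disease genes
#'
#' @param targets,pathogenetic Character vectors of gene ids.
#' @return Their intersection (the UET reference set).
#' @export
uet <- function(targets, pathogenetic) {
  intersect(unique(as.character(targets)), unique(as.character(pathogenetic)))
}

#' Hypergeometric over-representation analysis
#'
#' For each term with at least one overlapping gene, computes the upper-tail
#' hypergeometric probability P[X >= overlap] of drawing `|query|` genes
#' from the universe and hitting at least `overlap` of the term's members.
#' Query genes outside the universe are dropped (and reported via the
#' `dropped_genes` attribute). No multiple-testing correction is applied by
#' default; set `correct = "BH"` for Benjamini-Hochberg adjusted
#' significance.
#'
#' @param query Character vector of genes.
#' @param collection A `gene_set_collection`.
#' @param alpha Significance cutoff on the (possibly adjusted) p-value;
#'   default 0.01.
#' @param correct `"none"` (default, raw p < alpha) or `"BH"`.
#' @return data.frame `term_id`, `term_name`, `overlap`, `set_size`,
#'   `query_size`, `universe_size`, `p_value`, (`p_adjust`,) `significant`,
#'   sorted by p-value.
#' @export
enrich <- function(query, collection, alpha = 0.01,
                   correct = c("none", "BH")) {
  correct <- match.arg(correct)
  stopifnot(inherits(collection, "gene_set_collection"))
  universe <- collection$universe
  if (!length(universe)) stop("empty universe")
  query <- unique(as.character(query))
  dropped <- setdiff(query, universe)
  query <- intersect(query, universe)
  N <- length(universe)
  q <- length(query)
  rows <- lapply(base::names(collection$sets), function(id) {
    set <- collection$sets[[id]]
    k <- length(intersect(set, query))
    if (k == 0L) return(NULL)
    m <- length(set)
    p <- stats::phyper(k - 1L, m, N - m, q, lower.tail = FALSE)
    data.frame(term_id = id,
               term_name = if (is.null(collection$term_names)) id else
                 unname(collection$term_names[id]),
               overlap = k, set_size = m, query_size = q,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(term_id = character(0), term_name = character(0),
                      overlap = integer(0), set_size = integer(0),
                      query_size = integer(0), universe_size = integer(0),
                      p_value = numeric(0), significant = logical(0))
    attr(res, "dropped_genes") <- dropped
    return(res)
  }
  if (correct == "BH") {
    res$p_adjust <- stats::p.adjust(res$p_value, method = "BH")
    res$significant <- res$p_adjust < alpha
  } else {
    res$significant <- res$p_value < alpha
  }
  res <- res[order(res$p_value, res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "dropped_genes") <- dropped
  res
}

#' Coverage of a reference term set by a query term set
#'
#' @param query_terms,reference_terms Character vectors of term (or gene)
#'   ids.
#' @return List of class `coverage_report`: `shared` (ids), `shared_count`,
#'   `reference_count`, `coverage_percent` (2 decimals).
#' @export
coverage <- function(query_terms, reference_terms) {
  reference_terms <- unique(as.character(reference_terms))
  if (length(reference_terms) == 0L) stop("reference term set is empty")
  query_terms <- unique(as.character(query_terms))
  shared <- intersect(query_terms, reference_terms)
  structure(list(shared = shared, shared_count = length(shared),
                 reference_count = length(reference_terms),
                 coverage_percent =
                   round(100 * length(shared) / length(reference_terms), 2)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("coverage: %d/%d reference terms shared (%.2f%%)\n",
              x$shared_count, x$reference_count, x$coverage_percent))
  invisible(x)
}

#' Validate an effective-protein set against the UET reference
#'
#' Computes the three validation indicators: (1) gene-level coverage of the
#' UET set by the FRS genes; (2) coverage of the UET's significantly
#' enriched pathway terms by the FRS's; (3) the same for a second (GO-style)
#' collection. Term matching is by term id.
#'
#' @param frs_genes,uet_genes Character vectors of gene ids.
#' @param collections Named list of `gene_set_collection`s, e.g.
#'   `list(pathways = ..., go = ...)`; each yields one term-level indicator.
#' @param alpha Enrichment significance cutoff (default 0.01).
#' @return Named list of `coverage_report`s: `genes` plus one per
#'   collection.
#' @export
frs_validation <- function(frs_genes, uet_genes, collections, alpha = 0.01) {
  stopifnot(length(frs_genes) > 0L, length(uet_genes) > 0L)
  out <- list(genes = coverage(frs_genes, uet_genes))
  for (nm in base::names(collections)) {
    ref <- enrich(uet_genes, collections[[nm]], alpha = alpha)
    qry <- enrich(frs_genes, collections[[nm]], alpha = alpha)
    ref_terms <- ref$term_id[ref$significant]
    qry_terms <- qry$term_id[qry$significant]
    out[[nm]] <- if (length(ref_terms)) coverage(qry_terms, ref_terms) else
      structure(list(shared = character(0), shared_count = 0L,
                     reference_count = 0L, coverage_percent = NA_real_),
                class = "coverage_report")
  }
  out
}
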