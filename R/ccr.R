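# Components contribution ratio (CCR): greedy maximum-coverage selection of
# the key functional components group (KFCG).
#
# At each step the component whose target set adds the most uncovered
# effective proteins is selected; selection stops once the cumulative
# coverage W = |covered| / |effective| reaches the threshold (default 90%)
# or no remaining component adds coverage. Only effective proteins count:
# targets outside the effective set contribute nothing.

#' Read a component-to-target map from a pair TSV
#'
#' @param path TSV with one `component_id<TAB>target_gene` pair per row;
#'   header optional (detected by the literal column names).
#' @return Named list: component id -> character vector of target genes.
#' @export
read_ct_map <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("component_id", "target_gene"))
  if (tolower(df$component_id[1]) %in% c("component_id", "component")) {
    df <- df[-1L, , drop = FALSE]
  }
  ct_map(df$component_id, df$target_gene)
}

#' Build a component-to-target map from paired vectors
#'
#' @param component_id,target_gene Character vectors of equal length.
#' @return Named list of unique target-gene sets per component.
#' @export
ct_map <- function(component_id, target_gene) {
  component_id <- as.character(component_id)
  if (any(!nzchar(component_id))) stop("empty component_id")
  lapply(split(as.character(target_gene), component_id), unique)
}

#' Greedy contribution-ratio selection of the key components group
#'
#' @param ctmap Named list mapping component id to target genes
#'   (see [ct_map()]).
#' @param effective Character vector of effective proteins (the FRS genes);
#'   the coverage denominator.
#' @param threshold Stop once cumulative coverage W >= `threshold`
#'   (default 0.90, the 90% criterion defining the KFCG).
#' @return A list of class `coverage_state`: `trace` (data.frame with
#'   `rank`, `component_id`, `marginal_gain`, `cumulative_coverage`),
#'   `selected` (the KFCG, in selection order), `covered`, `coverage`
#'   (final W), `threshold`, `threshold_reached`.
#' @details Ties on marginal gain are broken by larger total target-set
#'   size, then lexicographically by component id, so output is
#'   deterministic. Components adding zero coverage are never selected.
#' @examples
#' m <- list(c1 = c("t1", "t2", "t3"), c2 = c("t3", "t4"), c3 = "t5")
#' s <- ccr_select(m, paste0("t", 1:5), threshold = 0.9)
#' s$trace$cumulative_coverage  # 0.6 0.8 1.0
#' @export
ccr_select <- function(ctmap, effective, threshold = 0.90) {
  effective <- unique(as.character(effective))
  if (length(effective) == 0L) stop("effective protein set is empty")
  stopifnot(threshold > 0, threshold <= 1)
  sets <- lapply(ctmap, function(t) intersect(unique(t), effective))
  total_size <- vapply(ctmap, function(t) length(unique(t)), integer(1L))
  remaining <- names(sets)
  covered <- character(0)
  trace <- list()
  repeat {
    gains <- vapply(sets[remaining],
                    function(t) length(setdiff(t, covered)), integer(1L))
    if (length(gains) == 0L || max(gains) == 0L) break
    cand <- remaining[gains == max(gains)]
    if (length(cand) > 1L) {
      cand <- cand[total_size[cand] == max(total_size[cand])]
      cand <- sort(cand)
    }
    pick <- cand[1L]
    covered <- union(covered, sets[[pick]])
    remaining <- setdiff(remaining, pick)
    w <- length(covered) / length(effective)
    trace[[length(trace) + 1L]] <- data.frame(
      rank = length(trace) + 1L, component_id = pick,
      marginal_gain = as.integer(max(gains)), cumulative_coverage = w,
      stringsAsFactors = FALSE)
    if (w >= threshold) break
  }
  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(rank = integer(0), component_id = character(0),
               marginal_gain = integer(0), cumulative_coverage = numeric(0))
  w <- length(covered) / length(effective)
  out <- list(trace = trace, selected = trace$component_id,
              covered = covered, coverage = w, threshold = threshold,
              threshold_reached = w >= threshold)
  class(out) <- "coverage_state"
  out
}

#' @export
print.coverage_state <- function(x, ...) {
  cat(sprintf(
    "KFCG selection: %d components, coverage %.2f%% (threshold %.0f%%%s)\n",
    length(x$selected), 100 * x$coverage, 100 * x$threshold,
    if (x$threshold_reached) ", reached" else ", NOT reached"))
  invisible(x)
}

#' Cumulative contribution curve with 50% / 90% marks
#'
#' @param state A `coverage_state` from [ccr_select()] (run with
#'   `threshold = 1` for the full curve).
#' @return A data.frame `rank`, `component_id`, `cumulative_coverage` with
#'   attributes `rank_50` and `rank_90`: the first ranks at which coverage
#'   reaches 50% and 90% (NA when not reached).
#' @export
contribution_curve <- function(state) {
  stopifnot(inherits(state, "coverage_state"))
  curve <- state$trace[, c("rank", "component_id", "cumulative_coverage")]
  first_at <- function(th) {
    i <- which(curve$cumulative_coverage >= th)
    if (length(i)) curve$rank[i[1L]] else NA_integer_
  }
  attr(curve, "rank_50") <- first_at(0.5)
  attr(curve, "rank_90") <- first_at(0.9)
  curve
}

#' Write the CCR trace TSV and the KFCG JSON
#'
#' @param state A `coverage_state`.
#' @param trace_path,kfcg_path Output files (either may be NULL to skip).
#' @export
write_ccr <- function(state, trace_path = NULL, kfcg_path = NULL) {
  if (!is.null(trace_path)) {
    utils::write.table(state$trace, trace_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(kfcg_path)) {
    jsonlite::write_json(
      list(kfcg = state$selected, coverage = state$coverage,
           threshold = state$threshold,
           threshold_reached = state$threshold_reached),
      kfcg_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(state)
}
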