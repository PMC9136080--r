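# ADME screening of candidate components.
#
# A component passes iff OB >= 30 (percent, inclusive), Caco-2 > -0.4
# (strict) and DL >= 0.18 (inclusive). Records with any missing property
# fail closed with reason "missing": literature-curated components (which
# typically lack database ADME predictions) enter the potential-active set
# only through merge_literature().

.ADME_OB_MIN <- 30
.ADME_CACO2_MIN <- -0.4
.ADME_DL_MIN <- 0.18

#' Read a component table TSV
#'
#' Columns: `component_id`, `name`, `herbs` (comma-separated codes), `ob`,
#' `caco2`, `dl`, `mw`, `source` (`database` or `literature`). Missing
#' numeric properties may be empty, `NA` or an em/en dash.
#'
#' @param path TSV file path.
#' @return data.frame with numeric `ob`, `caco2`, `dl`, `mw` (NA = missing).
#' @export
read_component_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          na.strings = c("NA", "", "—", "–", "-"))
  req <- c("component_id", "name", "herbs", "ob", "caco2", "dl", "mw",
           "source")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("component table lacks column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("ob", "caco2", "dl", "mw")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(v2))
      if (length(bad)) {
        stop("non-numeric ", col, " value in row(s) ",
             paste(bad, collapse = ", "), ": ",
             paste(v[bad], collapse = ", "))
      }
      df[[col]] <- v2
    }
  }
  df
}

#' Screen components by ADME thresholds
#'
#' @param records Component data.frame (see [read_component_table()]).
#' @return A list: `pass` (passing subset), `fail` (failing subset with a
#'   `fail_reason` column listing the violated criteria, or `"missing"`),
#'   and `report`, a named count of failures per criterion.
#' @examples
#' rec <- data.frame(component_id = c("a", "b"), name = c("A", "B"),
#'                   herbs = "H1", ob = c(36.16, 35.47),
#'                   caco2 = c(0.19, 0.43), dl = c(0.25, 0.04),
#'                   mw = c(286, 168), source = "database")
#' adme_filter(rec)$pass$component_id  # "a"
#' @export
adme_filter <- function(records) {
  stopifnot(is.data.frame(records))
  if (anyDuplicated(records$component_id)) {
    stop("duplicate component_id in ADME table")
  }
  missing <- is.na(records$ob) | is.na(records$caco2) | is.na(records$dl)
  ob_fail <- !missing & records$ob < .ADME_OB_MIN
  caco2_fail <- !missing & records$caco2 <= .ADME_CACO2_MIN
  dl_fail <- !missing & records$dl < .ADME_DL_MIN
  ok <- !missing & !ob_fail & !caco2_fail & !dl_fail
  reason <- character(nrow(records))
  reason[missing] <- "missing"
  for (i in which(!missing & !ok)) {
    reason[i] <- paste(c("ob", "caco2", "dl")[c(ob_fail[i], caco2_fail[i],
                                                dl_fail[i])],
                       collapse = ",")
  }
  fail <- records[!ok, , drop = FALSE]
  fail$fail_reason <- reason[!ok]
  list(pass = records[ok, , drop = FALSE],
       fail = fail,
       report = c(ob = sum(ob_fail), caco2 = sum(caco2_fail),
                  dl = sum(dl_fail), missing = sum(missing)))
}

#' Merge ADME-passing components with literature-curated ones
#'
#' Union by component identity: the same molecule appearing in several herbs
#' or in both sources is one record. Provenance is retained in the `source`
#' column; conflicting numeric properties for one id are an error.
#'
#' @param adme_pass data.frame of ADME-passing components.
#' @param literature data.frame of literature-curated components (same
#'   columns); may have zero rows.
#' @return Combined data.frame of potential active components, deduplicated
#'   by `component_id`.
#' @export
merge_literature <- function(adme_pass, literature) {
  cols <- intersect(names(adme_pass), names(literature))
  all <- rbind(adme_pass[, cols, drop = FALSE],
               literature[, cols, drop = FALSE])
  if (nrow(all) == 0L) return(all)
  dup_ids <- unique(all$component_id[duplicated(all$component_id)])
  for (id in dup_ids) {
    sub <- all[all$component_id == id, c("ob", "caco2", "dl", "mw"),
               drop = FALSE]
    for (col in names(sub)) {
      u <- unique(sub[[col]][!is.na(sub[[col]])])
      if (length(u) > 1L) {
        stop("conflicting ", col, " values for component ", id, ": ",
             paste(u, collapse = " vs "))
      }
    }
  }
  out <- all[!duplicated(all$component_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
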