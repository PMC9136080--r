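# Brain-concentration estimation of formula components by linear dose
# scaling from rodent brain-exposure anchors.
#
# Chain: total component mass in one formula dose (sum over herbs of
# grams x mg/g content) -> human mg/kg at the stated body weight ->
# brain ng/g by linear scaling against the animal anchor
# (dose mg/kg -> brain ng/g) -> molar concentration at tissue density
# 1 g/mL, where ng/g divided by MW (g/mol == ng/nmol) gives nmol/g == nM.
# Extraction and absorption are assumed complete (100%), and the
# cross-species scaling is linear, not allometric; both are stated
# presumptions of the estimation, implemented literally.

#' Estimate the brain concentration of a component after one formula dose
#'
#' @param contents data.frame (or list of lists) of herb contents with
#'   columns/fields `code` (herb code), `grams` (amount per formula dose)
#'   and `mg_per_g` (component content in that herb).
#' @param anchor List with `dose_mg_per_kg`, `brain_level` and
#'   `brain_level_unit` (`"ng/g"` or `"ug/g"`): the rodent dose and the
#'   brain level it produced.
#' @param mw Molecular weight, g/mol.
#' @param body_weight_kg Human body weight; default 70.
#' @param component Optional component name carried into the result.
#' @return List of class `brain_estimate`: `component`, `total_mg`,
#'   `human_mg_per_kg`, `brain_ng_per_g`, `nM`, `uM`, plus 2-decimal
#'   rounded copies `nM_rounded`, `uM_rounded` (half-even; applied only at
#'   reporting, intermediates kept at full precision).
#' @examples
#' est <- estimate_brain_concentration(
#'   contents = data.frame(code = c("CX", "RS"), grams = c(50, 50),
#'                         mg_per_g = c(0.19, 32.70)),
#'   anchor = list(dose_mg_per_kg = 63.75, brain_level = 120.01,
#'                 brain_level_unit = "ng/g"),
#'   mw = 194.18)
#' est$nM_rounded  # 227.76
#' @export
estimate_brain_concentration <- function(contents, anchor, mw,
                                         body_weight_kg = 70,
                                         component = NULL) {
  if (is.list(contents) && !is.data.frame(contents)) {
    contents <- do.call(rbind, lapply(contents, function(h)
      data.frame(code = h$code, grams = h$grams, mg_per_g = h$mg_per_g,
                 stringsAsFactors = FALSE)))
  }
  stopifnot(is.data.frame(contents), nrow(contents) >= 1L,
            all(c("grams", "mg_per_g") %in% names(contents)))
  if (any(contents$grams <= 0)) stop("herb amounts must be positive")
  if (any(contents$mg_per_g < 0)) stop("contents must be non-negative")
  if (!is.numeric(mw) || mw <= 0) stop("molecular weight must be positive")
  if (is.null(anchor$dose_mg_per_kg) || anchor$dose_mg_per_kg <= 0) {
    stop("anchor dose must be positive")
  }
  if (body_weight_kg <= 0) stop("body weight must be positive")
  unit <- if (is.null(anchor$brain_level_unit)) "ng/g" else
    anchor$brain_level_unit
  anchor_ng <- switch(unit,
    "ng/g" = anchor$brain_level,
    "ug/g" = ,
    "μg/g" = anchor$brain_level * 1000,
    stop("unknown anchor brain level unit: ", unit))
  total_mg <- sum(contents$grams * contents$mg_per_g)
  human_mg_per_kg <- total_mg / body_weight_kg
  brain_ng_per_g <- human_mg_per_kg / anchor$dose_mg_per_kg * anchor_ng
  nM <- brain_ng_per_g / mw * 1000  # ng/g over ng/nmol -> nmol/g == nM
  structure(list(component = component, total_mg = total_mg,
                 human_mg_per_kg = human_mg_per_kg,
                 brain_ng_per_g = brain_ng_per_g,
                 nM = nM, uM = nM / 1000,
                 nM_rounded = round(nM, 2), uM_rounded = round(nM / 1000, 2)),
            class = "brain_estimate")
}

#' @export
print.brain_estimate <- function(x, ...) {
  cat(sprintf("Brain estimate%s: %s (%s)\n",
              if (is.null(x$component)) "" else paste0(" for ", x$component),
              report_unit(x, "nM"), report_unit(x, "uM")))
  invisible(x)
}

#' Format a brain estimate in the requested unit
#'
#' @param estimate A `brain_estimate`.
#' @param unit `"nM"` or `"uM"` (`"μM"` accepted); 1 uM = 1000 nM.
#' @return A string such as `"227.76 nM"`, rounded half-even to 2 decimals.
#' @export
report_unit <- function(estimate, unit = c("nM", "uM", "μM")) {
  unit <- match.arg(unit)
  val <- switch(unit, nM = estimate$nM, estimate$nM / 1000)
  lab <- if (unit == "nM") "nM" else "μM"
  paste(formatC(round(val, 2), format = "f", digits = 2), lab)
}

#' Read a brain-estimation config JSON
#'
#' Schema: `{component, mw, herbs: [{code, grams, mg_per_g}], anchor:
#' {dose_mg_per_kg, brain_level, brain_level_unit}, body_weight_kg}`.
#'
#' @param path JSON file.
#' @return A `brain_estimate` (the estimation is run on load).
#' @export
estimate_from_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  estimate_brain_concentration(
    contents = as.data.frame(cfg$herbs),
    anchor = as.list(cfg$anchor),
    mw = cfg$mw,
    body_weight_kg = if (is.null(cfg$body_weight_kg)) 70 else
      cfg$body_weight_kg,
    component = cfg$component)
}
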