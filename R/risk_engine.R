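#' Threshold set: reference concentrations, BEIs and the cancer slope factor
#'
#' Bundles the regulatory comparison values used by the deterministic risk
#' surface: inhalation reference concentrations (RfC, ug/m3) per BTEX
#' species, ACGIH biological exposure indices (BEI, ug per g creatinine) per
#' urinary biomarker, and the benzene cancer slope factor SF
#' ((mg/kg/day)^-1).
#'
#' @param rfc Named numeric vector of reference concentrations (ug/m3).
#' @param bei Named numeric vector of biological exposure indices
#'   (ug/g crt).
#' @param sf Cancer slope factor, >= 0.
#' @return An object of class `threshold_set`.
#' @export
threshold_set <- function(rfc, bei = numeric(), sf = 0) {
  stopifnot(is.numeric(rfc), is.numeric(bei), is.numeric(sf),
            length(sf) == 1L)
  if (length(rfc) && (is.null(names(rfc)) || any(!nzchar(names(rfc))))) {
    stop("'rfc' must be a named vector", call. = FALSE)
  }
  if (length(bei) && (is.null(names(bei)) || any(!nzchar(names(bei))))) {
    stop("'bei' must be a named vector", call. = FALSE)
  }
  if (any(c(rfc, bei) <= 0)) {
    stop("all RfC and BEI thresholds must be > 0", call. = FALSE)
  }
  if (sf < 0) stop("'sf' must be >= 0", call. = FALSE)
  structure(list(rfc = rfc, bei = bei, sf = sf), class = "threshold_set")
}

#' Exposure scenario for chronic daily intake
#'
#' The parameter bundle of the intake equation
#' `CDI = C x IR x EF x ED / (BW x AT)`: inhalation rate IR (m3/day) and body
#' weight BW (kg) either as fixed numbers or as [dist_spec] objects (the
#' latter only usable by the Monte Carlo module), exposure frequency EF
#' (day/year), exposure duration ED (year) and averaging time AT (day). The
#' defaults describe lifetime-averaged adult exposure: daily exposure over a
#' 53-year adult window averaged over a 70-year lifetime (25,550 days).
#'
#' @param ir Inhalation rate: positive number or `dist_spec` (m3/day).
#' @param bw Body weight: positive number or `dist_spec` (kg).
#' @param ef Exposure frequency, day/year, in (0, 366].
#' @param ed Exposure duration, years, > 0.
#' @param at Averaging time, days, > 0 and >= 365.25 * ed implied by
#'   `ef * ed <= at` (intake is lifetime-averaged).
#' @param group_label Free-text population label, e.g. `"male"`.
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(ir, bw, ef = 365, ed = 53, at = 25550,
                              group_label = "") {
  ok_component <- function(x) is_dist_spec(x) ||
    (is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0)
  if (!ok_component(ir)) stop("'ir' must be a positive number or a dist_spec",
                              call. = FALSE)
  if (!ok_component(bw)) stop("'bw' must be a positive number or a dist_spec",
                              call. = FALSE)
  stopifnot(ef > 0, ef <= 366, ed > 0, at > 0)
  if (ef * ed > at) {
    stop("ef * ed must not exceed at (intake is lifetime-averaged): ",
         ef * ed, " > ", at, call. = FALSE)
  }
  structure(list(ir = ir, bw = bw, ef = ef, ed = ed, at = at,
                 group_label = group_label),
            class = "exposure_scenario")
}

risk_result <- function(quantity, value, inputs = list()) {
  stopifnot(quantity %in% c("HQ", "CDI", "LCR"), value >= 0)
  structure(list(quantity = quantity, value = value, inputs = inputs),
            class = "risk_result")
}

#' @export
print.risk_result <- function(x, ...) {
  cat(sprintf("<risk_result> %s = %g\n", x$quantity, x$value))
  invisible(x)
}

#' Hazard quotient of a concentration against its threshold
#'
#' `HQ = C / RfC` (or `C / BEI` for a urinary biomarker). Values below 1
#' indicate that adverse non-cancer effects are unlikely. Concentration and
#' threshold must be expressed in the same units; if unit tags are supplied
#' for both they are checked.
#'
#' @param concentration Concentration, >= 0, in threshold units.
#' @param threshold RfC or BEI, > 0.
#' @param unit,threshold_unit Optional unit tags; when both are non-empty
#'   they must match.
#' @return A `risk_result` with `quantity = "HQ"`.
#' @examples
#' hazard_quotient(5.14, 30)$value  # benzene at the site nearest the plant
#' @export
hazard_quotient <- function(concentration, threshold,
                            unit = NULL, threshold_unit = NULL) {
  stopifnot(is.numeric(concentration), length(concentration) == 1L)
  if (concentration < 0) stop("'concentration' must be >= 0", call. = FALSE)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("'threshold' must be a single value > 0", call. = FALSE)
  }
  if (!is.null(unit) && !is.null(threshold_unit) &&
      nzchar(unit) && nzchar(threshold_unit) && unit != threshold_unit) {
    stop("unit mismatch: concentration in '", unit,
         "' but threshold in '", threshold_unit, "'", call. = FALSE)
  }
  risk_result("HQ", concentration / threshold,
              inputs = list(concentration = concentration,
                            threshold = threshold))
}

#' Chronic daily intake via inhalation
#'
#' `CDI = C x IR x EF x ED / (BW x AT)` with C in ug/m3 and CDI in
#' mg/kg/day; the ug-to-mg conversion (factor 1e-3) is applied inside this
#' function, never at input parsing. Requires a scenario with fixed
#' (non-distributional) IR and BW; distribution-valued scenarios belong to
#' [simulate_lcr()].
#'
#' @param concentration Air concentration, ug/m3, >= 0.
#' @param scenario An [exposure_scenario] with numeric `ir` and `bw`.
#' @return A `risk_result` with `quantity = "CDI"` (mg/kg/day).
#' @export
chronic_daily_intake <- function(concentration, scenario) {
  stopifnot(inherits(scenario, "exposure_scenario"),
            is.numeric(concentration), length(concentration) == 1L,
            concentration >= 0)
  if (is_dist_spec(scenario$ir) || is_dist_spec(scenario$bw)) {
    stop("scenario has distribution-valued ir/bw; use simulate_lcr() ",
         "for probabilistic intake", call. = FALSE)
  }
  value <- concentration * 1e-3 * scenario$ir * scenario$ef * scenario$ed /
    (scenario$bw * scenario$at)
  risk_result("CDI", value,
              inputs = list(concentration = concentration,
                            scenario = scenario))
}

#' Lifetime cancer risk
#'
#' `LCR = CDI x SF`. A risk of 1e-6 is conventionally acceptable; 1e-4 or
#' greater is considered serious.
#'
#' @param cdi Chronic daily intake, mg/kg/day, >= 0 (a number or a
#'   `risk_result` from [chronic_daily_intake()]).
#' @param sf Cancer slope factor, (mg/kg/day)^-1, >= 0.
#' @return A `risk_result` with `quantity = "LCR"` (dimensionless).
#' @export
lifetime_cancer_risk <- function(cdi, sf) {
  if (inherits(cdi, "risk_result")) {
    stopifnot(cdi$quantity == "CDI")
    cdi <- cdi$value
  }
  stopifnot(is.numeric(cdi), length(cdi) == 1L, cdi >= 0,
            is.numeric(sf), length(sf) == 1L, sf >= 0)
  risk_result("LCR", cdi * sf, inputs = list(cdi = cdi, sf = sf))
}

#' Hazard-quotient table by site and analyte
#'
#' Computes one HQ per (site, analyte) pair from a long table of
#' concentration statistics (by default the site geometric means). Air
#' species are compared with their RfC and urinary biomarkers with their
#' BEI, whichever holds the analyte; an analyte present in neither is an
#' error. Sites missing an analyte produce `NA` cells, never zeros.
#'
#' @param concentrations Data frame with columns `site`, `analyte`, `value`
#'   (air in ug/m3, biomarkers in ug/g crt; geometric means recommended).
#' @param thresholds A [threshold_set].
#' @return A wide data frame: one row per site, one HQ column per analyte
#'   (ordered: RfC analytes then BEI analytes, each in threshold order).
#' @export
risk_table <- function(concentrations, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"),
            is.data.frame(concentrations),
            all(c("site", "analyte", "value") %in% names(concentrations)))
  known <- c(names(thresholds$rfc), names(thresholds$bei))
  if (nrow(concentrations) == 0L) {
    return(data.frame(site = character()))
  }
  unknown <- setdiff(unique(concentrations$analyte), known)
  if (length(unknown)) {
    stop("analyte(s) without an RfC or BEI: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sites <- unique(concentrations$site)
  analytes <- intersect(known, unique(concentrations$analyte))
  out <- data.frame(site = sites, stringsAsFactors = FALSE)
  for (an in analytes) {
    thr <- if (an %in% names(thresholds$rfc)) thresholds$rfc[[an]]
           else thresholds$bei[[an]]
    col <- rep(NA_real_, length(sites))
    sub <- concentrations[concentrations$analyte == an, , drop = FALSE]
    idx <- match(sub$site, sites)
    col[idx] <- vapply(sub$value, function(v) hazard_quotient(v, thr)$value,
                       numeric(1))
    out[[an]] <- col
  }
  out
}
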