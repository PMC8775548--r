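#' Creatinine correction of urinary biomarker concentrations
#'
#' Divides a raw urinary analyte concentration (ug/L) by urinary creatinine
#' (g/L), removing between-individual differences in urine dilution; the
#' corrected value is in ug per g creatinine. Vectorised. Samples with
#' non-positive creatinine cannot be corrected and return `NA` with the
#' offending indices listed in the `"excluded"` attribute (they are never
#' silently zeroed).
#'
#' @param raw_ugL Raw analyte concentration(s), ug/L, >= 0.
#' @param creatinine_gL Urinary creatinine concentration(s), g/L.
#' @return Corrected concentration(s), ug/g crt, with attribute `excluded`.
#' @examples
#' creatinine_correct(50, 0.5)  # 100 ug/g crt
#' @export
creatinine_correct <- function(raw_ugL, creatinine_gL) {
  stopifnot(is.numeric(raw_ugL), is.numeric(creatinine_gL),
            length(raw_ugL) == length(creatinine_gL))
  if (any(raw_ugL < 0, na.rm = TRUE)) {
    stop("raw concentrations must be >= 0", call. = FALSE)
  }
  excluded <- which(!is.finite(creatinine_gL) | creatinine_gL <= 0)
  out <- raw_ugL / creatinine_gL
  out[excluded] <- NA_real_
  attr(out, "excluded") <- excluded
  out
}

#' Per-region biomarker summary (GM and SD of corrected values)
#'
#' Summarises creatinine-corrected concentrations for one site and analyte
#' as the geometric mean (exp of the mean log, over strictly positive
#' values) paired with the arithmetic standard deviation (n - 1 denominator)
#' of all corrected values — the "GM +/- SD" convention used for cohort
#' tables. Geometric SD is available as an alternative dispersion measure.
#'
#' @param urine Data frame with columns `site`, `analyte`, `raw_ugL`,
#'   `creatinine_gL` (the cohort CSV dialect), or pre-corrected values via
#'   `corrected`.
#' @param site,analyte The group to summarise.
#' @param dispersion `"arithmetic"` (default) or `"geometric"` SD.
#' @return A one-row data frame: `site`, `analyte`, `n`, `gm`, `sd`,
#'   `n_excluded` (non-positive corrected values skipped by the GM),
#'   `sd_flag` (TRUE when n < 2 and the SD is reported as 0).
#' @export
region_summary <- function(urine, site, analyte,
                           dispersion = c("arithmetic", "geometric")) {
  dispersion <- match.arg(dispersion)
  stopifnot(is.data.frame(urine))
  sub <- urine[urine$site == site & urine$analyte == analyte, , drop = FALSE]
  if ("corrected" %in% names(sub)) {
    corrected <- sub$corrected
  } else {
    stopifnot(all(c("raw_ugL", "creatinine_gL") %in% names(sub)))
    corrected <- creatinine_correct(sub$raw_ugL, sub$creatinine_gL)
  }
  corrected <- corrected[is.finite(corrected)]
  pos <- corrected[corrected > 0]
  if (!length(pos)) {
    stop("no positive corrected values for site ", site, ", analyte ",
         analyte, call. = FALSE)
  }
  gm <- exp(mean(log(pos)))
  sd_flag <- length(corrected) < 2L
  s <- if (sd_flag) 0 else if (dispersion == "arithmetic") {
    stats::sd(corrected)
  } else {
    exp(stats::sd(log(pos)))
  }
  data.frame(site = site, analyte = analyte, n = length(corrected),
             gm = gm, sd = s, n_excluded = length(corrected) - length(pos),
             sd_flag = sd_flag, stringsAsFactors = FALSE)
}

#' Summarise a whole urine cohort
#'
#' Applies [region_summary()] to every (site, analyte) pair present,
#' mirroring the layout of a site-by-analyte biomarker table.
#'
#' @inheritParams region_summary
#' @return Data frame with one row per (site, analyte).
#' @export
biomarker_summary <- function(urine,
                              dispersion = c("arithmetic", "geometric")) {
  dispersion <- match.arg(dispersion)
  groups <- unique(urine[, c("site", "analyte")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    region_summary(urine, groups$site[i], groups$analyte[i],
                   dispersion = dispersion)
  })
  do.call(rbind, rows)
}

#' Internal-exposure hazard quotient from a biomarker summary
#'
#' Compares a site geometric mean of a creatinine-corrected biomarker with
#' its ACGIH biological exposure index: `HQ = GM / BEI`, via
#' [hazard_quotient()].
#'
#' @param summary A one-row data frame from [region_summary()] (or any list
#'   with `analyte` and `gm`).
#' @param thresholds A [threshold_set] whose `bei` covers the analyte.
#' @return A `risk_result` with `quantity = "HQ"`.
#' @export
biomarker_hq <- function(summary, thresholds) {
  stopifnot(inherits(thresholds, "threshold_set"))
  analyte <- as.character(summary$analyte)
  if (!analyte %in% names(thresholds$bei)) {
    stop("no BEI configured for analyte '", analyte, "'", call. = FALSE)
  }
  hazard_quotient(summary$gm, thresholds$bei[[analyte]],
                  unit = "ug/g crt", threshold_unit = "ug/g crt")
}
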