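BTEX_SPECIES <- c("benzene", "toluene", "ethylbenzene", "xylenes")

#' Site specification for synthetic air sampling
#'
#' Describes one sampling site: a named list of concentration distributions
#' (one [dist_spec] per BTEX species) and the number of canister samples
#' collected there (five per site in the emulated design).
#'
#' @param site_id Site label, e.g. `"R1"`.
#' @param dists Named list of `dist_spec`s; names must be a subset of
#'   benzene, toluene, ethylbenzene, xylenes.
#' @param n_air_samples Samples per site (default 5).
#' @return An object of class `site_spec`.
#' @export
site_spec <- function(site_id, dists, n_air_samples = 5L) {
  stopifnot(is.list(dists), length(dists) >= 1L, n_air_samples >= 0)
  if (!all(names(dists) %in% BTEX_SPECIES)) {
    stop("species must be among: ", paste(BTEX_SPECIES, collapse = ", "),
         call. = FALSE)
  }
  stopifnot(all(vapply(dists, is_dist_spec, logical(1))))
  structure(list(site_id = site_id, dists = dists,
                 n_air_samples = as.integer(n_air_samples)),
            class = "site_spec")
}

#' Cohort specification for synthetic urine sampling
#'
#' Describes one site's participant cohort: size, sex split, male smoking
#' rate, the age-group weights, per-analyte distributions of
#' creatinine-corrected biomarker levels (ug/g crt), and the urinary
#' creatinine distribution (g/L). Biomarker distributions are interpreted on
#' the corrected scale; raw concentrations are back-computed as
#' corrected x creatinine so that [creatinine_correct()] inverts the
#' generator exactly.
#'
#' @param site_id Site label.
#' @param n_participants Cohort size (>= 0).
#' @param n_male Number of male participants (<= n_participants).
#' @param smoker_rate_male Smoking prevalence among males, in \[0, 1\].
#' @param smoker_rate_female Smoking prevalence among females (default 0;
#'   the emulated survey reports male smoking only).
#' @param biomarker_dists Named list of `dist_spec`s (corrected scale).
#' @param creatinine_dist `dist_spec` for urinary creatinine (g/L).
#' @param age_weights Named numeric vector of age-group sampling weights.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(site_id, n_participants, n_male,
                        smoker_rate_male, smoker_rate_female = 0,
                        biomarker_dists,
                        creatinine_dist = dist_spec("lognormal10", 0, 0.17,
                                                    unit = "g/L"),
                        age_weights = c("20-30" = 1, "31-40" = 1, "41-50" = 1,
                                        "51-60" = 1, "61-70" = 1)) {
  stopifnot(n_participants >= 0, n_male >= 0, n_male <= n_participants,
            smoker_rate_male >= 0, smoker_rate_male <= 1,
            smoker_rate_female >= 0, smoker_rate_female <= 1,
            is.list(biomarker_dists), length(biomarker_dists) >= 1L,
            all(vapply(biomarker_dists, is_dist_spec, logical(1))),
            is_dist_spec(creatinine_dist),
            all(age_weights >= 0), sum(age_weights) > 0)
  structure(list(site_id = site_id,
                 n_participants = as.integer(n_participants),
                 n_male = as.integer(n_male),
                 smoker_rate_male = smoker_rate_male,
                 smoker_rate_female = smoker_rate_female,
                 biomarker_dists = biomarker_dists,
                 creatinine_dist = creatinine_dist,
                 age_weights = age_weights),
            class = "cohort_spec")
}

#' Generate synthetic air samples for one site
#'
#' Draws `n_air_samples` concentrations per species from the site's
#' distributions. Reproducible given the seed; identical seeds give
#' identical tables.
#'
#' @param spec A [site_spec].
#' @param seed Integer seed.
#' @return Data frame with columns `site`, `analyte`,
#'   `value` (ug/m3) — the shared concentrations dialect.
#' @export
generate_air_samples <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "site_spec"))
  set.seed(seed)
  n <- spec$n_air_samples
  if (n == 0L || !length(spec$dists)) {
    return(data.frame(site = character(), analyte = character(),
                      value = numeric(), stringsAsFactors = FALSE))
  }
  rows <- lapply(names(spec$dists), function(sp) {
    data.frame(site = spec$site_id, analyte = sp,
               value = as.numeric(dist_sample(spec$dists[[sp]], n)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a synthetic urine cohort for one site
#'
#' Assigns sex deterministically by the configured split, smoking by
#' Bernoulli draws at the sex-specific rates, age groups by weighted
#' sampling, one creatinine value per participant, and one corrected
#' biomarker level per (participant, analyte); raw concentrations are
#' corrected x creatinine.
#'
#' @param spec A [cohort_spec].
#' @param seed Integer seed.
#' @return Long data frame with columns `participant_id`, `site`, `sex`,
#'   `smoker`, `age_group`, `analyte`, `raw_ugL`, `creatinine_gL` — the
#'   urine CSV dialect.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n_participants
  empty <- data.frame(participant_id = character(), site = character(),
                      sex = character(), smoker = logical(),
                      age_group = character(), analyte = character(),
                      raw_ugL = numeric(), creatinine_gL = numeric(),
                      stringsAsFactors = FALSE)
  if (n == 0L) return(empty)
  sex <- c(rep("male", spec$n_male), rep("female", n - spec$n_male))
  smoker <- stats::rbinom(n, 1L,
                          ifelse(sex == "male", spec$smoker_rate_male,
                                 spec$smoker_rate_female)) == 1L
  age_group <- sample(names(spec$age_weights), n, replace = TRUE,
                      prob = spec$age_weights / sum(spec$age_weights))
  creatinine <- as.numeric(dist_sample(spec$creatinine_dist, n,
                                       truncate_positive = TRUE))
  pid <- sprintf("%s_%03d", spec$site_id, seq_len(n))
  rows <- lapply(names(spec$biomarker_dists), function(an) {
    corrected <- as.numeric(dist_sample(spec$biomarker_dists[[an]], n))
    data.frame(participant_id = pid, site = spec$site_id, sex = sex,
               smoker = smoker, age_group = age_group, analyte = an,
               raw_ugL = corrected * creatinine,
               creatinine_gL = creatinine, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Back out a base-10 log-normal from a geometric mean and arithmetic SD
#'
#' Cohort tables report biomarker levels as "GM +/- SD" with an arithmetic
#' SD. For a log-normal variate, GM = 10^a and
#' SD^2 = GM^2 e^{s^2}(e^{s^2} - 1) with s = ln(10) b, which inverts to
#' `e^{s^2} = (1 + sqrt(1 + 4 SD^2/GM^2)) / 2`. Used to parameterise the
#' per-site biomarker generators from published site summaries.
#'
#' @param gm Geometric mean, > 0.
#' @param sd Arithmetic standard deviation, >= 0.
#' @param unit Unit tag.
#' @return A `dist_spec("lognormal10", log10(gm), b)`.
#' @export
lognormal10_from_gm_sd <- function(gm, sd, unit = "") {
  stopifnot(gm > 0, sd >= 0)
  if (sd == 0) return(dist_spec("lognormal10", log10(gm), 0, unit = unit))
  u <- (1 + sqrt(1 + 4 * sd^2 / gm^2)) / 2
  dist_spec("lognormal10", log10(gm), sqrt(log(u)) / log(10), unit = unit)
}

#' Load the default study configuration
#'
#' Returns the packaged parameter bundle: the four air-concentration and two
#' biomarker base-10 log-normals, body-weight and inhalation-rate normals
#' for both sexes, RfC/BEI thresholds and the cancer slope factor, the
#' lifetime-exposure scenario constants (EF = 365 day/year, ED = 53 year,
#' AT = 25,550 day), Monte Carlo defaults, per-site benzene geometric means,
#' and per-site cohort structure (sizes, sex splits, male smoking rates,
#' site biomarker GM/SD pairs).
#'
#' @param path Optional path to an alternative configuration JSON.
#' @return A named list; distribution entries are `dist_spec` objects,
#'   `thresholds` is a [threshold_set], `scenarios` holds ready-made male
#'   and female [exposure_scenario]s.
#' @export
default_study_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "study_config.json",
                        package = "btexrisk", mustWork = TRUE)
  }
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  as_dists <- function(x) lapply(x, dist_from_list)
  cfg <- list(
    air = as_dists(raw$air_distributions),
    biomarkers = as_dists(raw$biomarker_distributions),
    exposure_factors = as_dists(raw$exposure_factors),
    creatinine = dist_from_list(raw$creatinine),
    thresholds = threshold_set(
      rfc = unlist(raw$thresholds$rfc),
      bei = unlist(raw$thresholds$bei),
      sf = raw$thresholds$sf),
    scenario_constants = list(ef = raw$scenario$ef, ed = raw$scenario$ed,
                              at = raw$scenario$at),
    monte_carlo = list(
      n_iterations = raw$monte_carlo$n_iterations,
      risk_lines = unlist(raw$monte_carlo$risk_lines),
      truncate_positive = isTRUE(raw$monte_carlo$truncate_positive)),
    sites = list(
      benzene_geomean = unlist(raw$sites$benzene_geomean),
      n_air_samples = raw$sites$n_air_samples),
    cohorts = raw$cohorts,
    concentration_source = raw$concentration_source %||% "configured"
  )
  mk_scenario <- function(which) {
    exposure_scenario(ir = cfg$exposure_factors[[paste0("ir_", which)]],
                      bw = cfg$exposure_factors[[paste0("bw_", which)]],
                      ef = cfg$scenario_constants$ef,
                      ed = cfg$scenario_constants$ed,
                      at = cfg$scenario_constants$at,
                      group_label = which)
  }
  cfg$scenarios <- list(male = mk_scenario("male"), female = mk_scenario("female"))
  cfg
}

#' Build per-site air and cohort specifications from a study configuration
#'
#' `air_site_specs()` gives each site the pooled species distributions, with
#' the benzene location parameter shifted to `log10` of that site's
#' geometric mean (site-structured means over a shared dispersion).
#' `cohort_specs()` parameterises each site's biomarker generators from the
#' configured site GM/SD pairs via [lognormal10_from_gm_sd()].
#'
#' @param config A configuration list from [default_study_config()].
#' @return A named list of [site_spec] / [cohort_spec] objects.
#' @export
air_site_specs <- function(config) {
  gms <- config$sites$benzene_geomean
  out <- lapply(names(gms), function(site) {
    dists <- config$air
    dists$benzene <- dist_spec("lognormal10", log10(gms[[site]]),
                               dists$benzene$b, unit = dists$benzene$unit)
    site_spec(site, dists, n_air_samples = config$sites$n_air_samples)
  })
  names(out) <- names(gms)
  out
}

#' @rdname air_site_specs
#' @export
cohort_specs <- function(config) {
  out <- lapply(names(config$cohorts), function(site) {
    cc <- config$cohorts[[site]]
    bd <- lapply(cc$biomarkers, function(bm) {
      lognormal10_from_gm_sd(bm$gm, bm$sd, unit = "ug/g crt")
    })
    cohort_spec(site_id = site, n_participants = cc$n, n_male = cc$n_male,
                smoker_rate_male = cc$smoker_rate_male,
                biomarker_dists = bd,
                creatinine_dist = config$creatinine,
                age_weights = unlist(cc$age_weights))
  })
  names(out) <- names(config$cohorts)
  out
}

#' Generate the full synthetic study
#'
#' Air samples for every site and a urine cohort for every site, using
#' per-site seeds derived deterministically from `seed`.
#'
#' @param config Configuration list ([default_study_config()]).
#' @param seed Integer master seed.
#' @return List with data frames `air` and `urine`.
#' @export
generate_study <- function(config = default_study_config(), seed = 1L) {
  aspecs <- air_site_specs(config)
  cspecs <- cohort_specs(config)
  air <- do.call(rbind, lapply(seq_along(aspecs), function(i) {
    generate_air_samples(aspecs[[i]], seed = seed + 1000L * i)
  }))
  urine <- do.call(rbind, lapply(seq_along(cspecs), function(i) {
    generate_cohort(cspecs[[i]], seed = seed + 2000L * i)
  }))
  list(air = air, urine = urine)
}
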