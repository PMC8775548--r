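test_that("air generator output refits to the generating parameters", {
  spec <- site_spec("R1",
                    list(benzene = dist_spec("lognormal10", 0.321, 0.426,
                                             unit = "ug/m3")),
                    n_air_samples = 5000)
  air <- generate_air_samples(spec, seed = 41)
  f <- fit_lognormal10(air$value)
  expect_lt(abs(f$a - 0.321), 0.02)
  expect_lt(abs(f$b - 0.426), 0.02)
})

test_that("air generator is seed-deterministic down to the written bytes", {
  spec <- site_spec("R2", list(benzene = dist_spec("lognormal10", 0.3, 0.4)),
                    n_air_samples = 5)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_concentrations(generate_air_samples(spec, seed = 9), f1)
  write_concentrations(generate_air_samples(spec, seed = 9), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # a degenerate spec produces exactly the point mass
  d0 <- site_spec("R2", list(benzene = dist_spec("lognormal10", 0.5, 0)),
                  n_air_samples = 1)
  expect_equal(generate_air_samples(d0, seed = 1)$value, 10^0.5)
})

test_that("cohort generator reproduces the configured biomarker level and covariates", {
  spec <- cohort_spec("R1", 10000, 5000, smoker_rate_male = 0.68,
                      biomarker_dists = list(
                        ttma = dist_spec("lognormal10", 2.102, 0.392,
                                         unit = "ug/g crt")))
  urine <- generate_cohort(spec, seed = 51)
  corrected <- as.numeric(creatinine_correct(urine$raw_ugL,
                                             urine$creatinine_gL))
  gm <- exp(mean(log(corrected)))
  expect_lt(abs(gm / 10^2.102 - 1), 0.02)  # pooled GM within 2%
  # male smoking rate within 3 binomial SE of the configured 68%
  males <- urine[urine$sex == "male" & urine$analyte == "ttma", ]
  se <- sqrt(0.68 * 0.32 / nrow(males))
  expect_lt(abs(mean(males$smoker) - 0.68), 3 * se)
  expect_equal(sum(urine$analyte == "ttma"), 10000)
  expect_equal(sum(urine$sex == "male" & urine$analyte == "ttma"), 5000)
})

test_that("creatinine correction inverts the generator exactly", {
  spec <- cohort_spec("R3", 200, 100, smoker_rate_male = 0.6,
                      biomarker_dists = list(
                        spma = dist_spec("lognormal10", 0.441, 0.298)))
  urine <- generate_cohort(spec, seed = 3)
  corrected <- as.numeric(creatinine_correct(urine$raw_ugL,
                                             urine$creatinine_gL))
  f <- fit_lognormal10(corrected)
  # refit of the corrected values recovers the corrected-scale parameters
  expect_lt(abs(f$a - 0.441), 3 * 0.298 / sqrt(200))
  expect_lt(abs(f$b - 0.298), 3 * 0.298 / sqrt(2 * 200))
})

test_that("empty cohorts and empty sites yield valid empty tables", {
  spec <- cohort_spec("R4", 0, 0, smoker_rate_male = 0.5,
                      biomarker_dists = list(
                        ttma = dist_spec("lognormal10", 2, 0.4)))
  urine <- generate_cohort(spec, seed = 1)
  expect_equal(nrow(urine), 0)
  expect_true(all(c("participant_id", "analyte", "raw_ugL",
                    "creatinine_gL") %in% names(urine)))
  f <- tempfile(fileext = ".csv")
  write_urine(urine, f)
  expect_equal(nrow(read_urine(f)), 0)
})

test_that("the packaged configuration carries the study parameter table", {
  cfg <- study_cfg()
  expect_equal(cfg$air$benzene$a, 0.321)
  expect_equal(cfg$air$benzene$b, 0.426)
  expect_equal(cfg$thresholds$rfc[["benzene"]], 30)
  expect_equal(cfg$thresholds$rfc[["toluene"]], 5000)
  expect_equal(cfg$thresholds$bei[["ttma"]], 500)
  expect_equal(cfg$thresholds$bei[["spma"]], 25)
  expect_equal(cfg$thresholds$sf, 0.029)
  expect_equal(cfg$exposure_factors$bw_male$a, 61.04)
  expect_equal(cfg$exposure_factors$bw_male$b, 12.26)
  expect_equal(cfg$scenario_constants,
               list(ef = 365, ed = 53, at = 25550))
  expect_equal(cfg$monte_carlo$n_iterations, 10000)
  # serialisation round trip is the identity on every distribution entry
  for (d in c(cfg$air, cfg$biomarkers, cfg$exposure_factors)) {
    rt <- dist_from_list(dist_to_list(d))
    expect_identical(rt[c("family", "a", "b")], d[c("family", "a", "b")])
  }
})

test_that("generated study files parse back through the package readers losslessly", {
  cfg <- study_cfg()
  study <- generate_study(cfg, seed = 23)
  fa <- tempfile(fileext = ".csv"); fu <- tempfile(fileext = ".csv")
  write_concentrations(study$air, fa)
  write_urine(study$urine, fu)
  expect_equal(read_concentrations(fa), study$air)
  expect_equal(read_urine(fu), study$urine)
  # design marginals: per-site air sample and participant counts
  expect_equal(unname(table(study$air$site)["R1"]),
               5L * 4L)  # 5 samples x 4 species
  urine_r <- study$urine[study$urine$analyte == "ttma", ]
  expect_equal(as.vector(table(urine_r$site)[c("R1", "R2", "R3", "R4")]),
               c(50L, 49L, 50L, 25L))
  males <- tapply(urine_r$sex == "male", urine_r$site, sum)
  expect_equal(as.vector(males[c("R1", "R2", "R3", "R4")]),
               c(25L, 25L, 24L, 11L))
})

test_that("GM/SD moment matching inverts the lognormal moments", {
  d <- lognormal10_from_gm_sd(213, 434)
  expect_equal(10^d$a, 213)
  s2 <- (log(10) * d$b)^2
  sd_back <- sqrt(213^2 * exp(s2) * (exp(s2) - 1))
  expect_equal(sd_back, 434, tolerance = 1e-9)
  expect_equal(lognormal10_from_gm_sd(42, 0)$b, 0)
})
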