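test_that("the same seed reproduces a study bit-identically", {
  cfg <- quick_config(seed = 99)
  s1 <- simulate_cohorts(cfg)
  s2 <- simulate_cohorts(cfg)
  expect_identical(s1$cohorts[[1]]$beta, s2$cohorts[[1]]$beta)
  expect_identical(s1$cohorts[[2]]$phenotypes, s2$cohorts[[2]]$phenotypes)
  expect_identical(s1$clock$coefficients, s2$clock$coefficients)
  expect_identical(s1$cohorts[[1]]$truth$sem_events,
                   s2$cohorts[[1]]$truth$sem_events)
})

null_effects <- function() {
  list(education = c(Medium = 0, Low = 0), smoking = c(Former = 0, Current = 0),
       obesity = c(Overweight = 0, Obese = 0),
       alcohol = c(Occasional = 0, Habitual = 0),
       physical_activity = c(Medium = 0, Low = 0))
}

test_that("null configuration yields no exposure signal in the truth", {
  cfg <- quick_config(n_cohorts = 1, n_per_cohort = 800,
                      exposure_effects_years = null_effects(),
                      between_cohort_sd = 0, seed = 5)
  st <- simulate_cohorts(cfg)
  co <- st$cohorts[[1]]
  d <- co$phenotypes
  d$delta <- co$truth$delta
  for (f in names(risk_factor_levels())) {
    fit <- summary(lm(reformulate(f, "delta"), data = d))$coefficients
    expect_true(all(abs(fit[-1, "t value"]) < 4),
                label = paste("null slope for", f))
  }
  # truth report echoes the all-zero effects
  rep_ <- truth_report(st)
  expect_true(all(rep_[, grep("^eff_", names(rep_))] == 0))
})

test_that("expected epimutation count follows the exponential age model", {
  # lambda0 * exp(r * age): 2 * exp(0.03 * 60) ~ 12.1 at age 60
  cfg <- quick_config(n_cohorts = 1, n_per_cohort = 3000,
                      age_range = c(60, 60), sem_rate_base = 2,
                      sem_age_slope = 0.03, n_sem_cpgs = 200,
                      sem_exposure_log_effects = null_effects(), seed = 8)
  st <- simulate_cohorts(cfg)
  counts <- st$cohorts[[1]]$truth$sem_count
  expected <- 2 * exp(0.03 * 60)
  mc_se <- sqrt(expected / length(counts))
  expect_lt(abs(mean(counts) - expected), 4 * mc_se + 0.05)
})

test_that("true SEM counts are log-linear in age at the configured slope", {
  cfg <- quick_config(n_cohorts = 1, n_per_cohort = 1500, n_sem_cpgs = 2000,
                      n_wbc_cpgs = 0, n_inert_cpgs = 0, sem_rate_base = 20,
                      sem_age_slope = 0.03,
                      sem_exposure_log_effects = null_effects(), seed = 21)
  st <- simulate_cohorts(cfg)
  co <- st$cohorts[[1]]
  d <- data.frame(age = co$phenotypes$age, lk = log(co$truth$sem_count + 1))
  fit <- summary(lm(lk ~ age, data = d))$coefficients
  expect_lt(abs(fit["age", "Estimate"] - 0.03), 3 * fit["age", "Std. Error"])
})

test_that("emitted true clock inverts the clock CpGs exactly when noise-free", {
  cfg <- quick_config(noise_sd_beta = 0, seed = 13)
  st <- simulate_cohorts(cfg)
  for (co in st$cohorts) {
    pred <- predict_dnam_age(co$beta, st$clock)
    truth <- co$phenotypes$age + co$truth$delta
    expect_lt(max(abs(pred - truth)), 1e-9)
  }
})

test_that("WBC fractions are a proper composition", {
  st <- simulate_cohorts(quick_config(seed = 3))
  ph <- st$cohorts[[1]]$phenotypes
  fr <- as.matrix(ph[, grep("^wbc_", names(ph))])
  expect_true(all(fr >= 0))
  expect_equal(rowSums(fr), rep(1, nrow(fr)), tolerance = 1e-9)
})

test_that("truth report has one row per cohort and echoes planted effects", {
  cfg <- quick_config(n_cohorts = 6, n_per_cohort = 40, seed = 4)
  rep_ <- truth_report(simulate_cohorts(cfg))
  expect_equal(nrow(rep_), 6L)
  expect_equal(rep_$eff_education_Low, rep(0.6, 6))
  expect_equal(rep_$sem_age_slope, rep(0.03, 6))
})

test_that("confounding matrix ties exposure prevalence to education", {
  cm <- matrix(c(0.9, 0.05, 0.05,
                 0.6, 0.20, 0.20,
                 0.2, 0.30, 0.50), 3, 3, byrow = TRUE,
               dimnames = list(c("High", "Medium", "Low"),
                               c("Never", "Former", "Current")))
  cfg <- quick_config(n_cohorts = 1, n_per_cohort = 2000,
                      confounding_matrix = list(smoking = cm), seed = 17)
  ph <- simulate_cohorts(cfg)$cohorts[[1]]$phenotypes
  p_cur_low <- mean(ph$smoking[ph$education == "Low"] == "Current")
  p_cur_high <- mean(ph$smoking[ph$education == "High"] == "Current")
  expect_gt(p_cur_low, p_cur_high + 0.2)
})

test_that("a study round-trips through its on-disk exchange formats", {
  st <- simulate_cohorts(quick_config(n_cohorts = 1, n_per_cohort = 30,
                                      n_sem_cpgs = 20, seed = 2))
  dir <- withr::local_tempdir()
  write_synthetic_study(st, dir)
  beta <- read_beta_matrix(file.path(dir, "cohort01_beta.tsv"))
  expect_equal(unclass(beta), unclass(st$cohorts[[1]]$beta),
               tolerance = 1e-12)
  ph <- read_phenotypes(file.path(dir, "cohort01_phenotypes.tsv"))
  expect_equal(ph$education, st$cohorts[[1]]$phenotypes$education)
  rs <- read_regions_bed(file.path(dir, "open_chromatin.bed"),
                         name = "open_chromatin")
  expect_equal(nrow(rs), nrow(st$region_sets$open_chromatin))
  ck <- read_clock_model(file.path(dir, "true_clock.csv"))
  expect_equal(unname(ck$coefficients),
               unname(st$clock$coefficients), tolerance = 1e-10)
})

test_that("yaml configs override generator defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_cohorts: 3", "n_per_cohort: 50", "sem_rate_base: 5",
               "exposure_effects_years:", "  education:", "    Medium: 0.1",
               "    Low: 0.9"), path)
  cfg <- read_simulation_config(path)
  expect_equal(cfg$n_cohorts, 3)
  expect_equal(cfg$sem_rate_base, 5)
  expect_equal(cfg$exposure_effects_years$education[["Low"]], 0.9)
  # untouched defaults survive
  expect_equal(cfg$exposure_effects_years$smoking[["Current"]], 0.5)
})
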