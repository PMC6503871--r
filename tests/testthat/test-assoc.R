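sim_phenotypes <- function(n, seed = 1) {
  set.seed(seed)
  lv <- risk_factor_levels()
  d <- data.frame(sample_id = paste0("s", seq_len(n)), cohort_id = "c1",
                  age = runif(n, 40, 70),
                  sex = sample(c("male", "female"), n, TRUE),
                  stringsAsFactors = FALSE)
  for (f in names(lv)) d[[f]] <- sample(lv[[f]], n, TRUE)
  d
}

test_that("treatment coding uses the fixed reference levels", {
  d <- sim_phenotypes(60)
  des <- encode_design(d, "education", "M1")
  expect_setequal(des$focal_cols, c("educationMedium", "educationLow"))
  expect_true(all(des$focal_cols %in% colnames(des$X)))
  # reference rows have zero dummies
  ref_rows <- d$education == "High"
  expect_true(all(des$X[ref_rows, des$focal_cols] == 0))

  des_smoke <- encode_design(d, "smoking", "M1")
  expect_setequal(des_smoke$categories, c("Former", "Current"))

  # M2 carries all five factors' dummies
  des2 <- encode_design(d, "education", "M2")
  expect_true(all(c("smokingCurrent", "obesityObese", "alcoholHabitual",
                    "physical_activityLow") %in% colnames(des2$X)))
})

test_that("an absent category drops its dummy with a warning", {
  d <- sim_phenotypes(50)
  d$education <- "High"
  expect_warning(des <- encode_design(d, "education", "M1"), "absent")
  expect_length(des$focal_cols, 0)
})

test_that("OLS estimates match the normal-equations oracle", {
  d <- sim_phenotypes(40, seed = 8)
  d$y <- 0.6 * (d$education == "Low") + 0.02 * d$age + rnorm(40, sd = 0.5)
  est <- fit_cohort_models(d, "y", factors = "education", models = "M1")

  des <- encode_design(d, "education", "M1")
  oracle <- normal_equations_ols(des$X, d$y)
  expect_equal(est$beta[est$category == "Low"],
               unname(oracle$beta["educationLow"]), tolerance = 1e-8)
  expect_equal(est$se[est$category == "Low"],
               unname(oracle$se["educationLow"]), tolerance = 1e-8)
  # Wald interval at the normal 97.5% quantile
  expect_equal(est$ci_hi - est$beta, qnorm(0.975) * est$se, tolerance = 1e-9)
})

test_that("a planted categorical effect is recovered in outcome units", {
  d <- sim_phenotypes(600, seed = 12)
  d$y <- 0.6 * (d$education == "Low") + rnorm(600, sd = 1.5)
  est <- fit_cohort_models(d, "y", factors = "education", models = "M1")
  low <- est[est$category == "Low", ]
  # beta is in the outcome's units (years for clock residuals), not d units
  expect_lt(abs(low$beta - 0.6), 3 * low$se)
})

test_that("estimates are invariant to row order and covariate rescaling", {
  d <- sim_phenotypes(120, seed = 30)
  d$y <- 0.4 * (d$smoking == "Current") + 0.05 * d$age + rnorm(120)
  est1 <- fit_cohort_models(d, "y", factors = "smoking", models = "M1")
  est2 <- fit_cohort_models(d[sample(nrow(d)), ], "y", factors = "smoking",
                            models = "M1")
  expect_equal(est1$beta, est2$beta, tolerance = 1e-10)
  d2 <- d
  d2$age <- (d2$age - 50) / 10  # affine rescale of an adjustment covariate
  est3 <- fit_cohort_models(d2, "y", factors = "smoking", models = "M1")
  expect_equal(est1$beta, est3$beta, tolerance = 1e-10)
})

test_that("collinear designs fail loudly naming the aliased column", {
  d <- sim_phenotypes(50, seed = 2)
  d$dup_age <- d$age
  d$y <- rnorm(50)
  expect_error(
    fit_cohort_models(d, "y", factors = "education", models = "M1",
                      covariates = "dup_age"),
    "aliased.*dup_age")
})

test_that("mutual adjustment attenuates a confounded education effect", {
  # smokers concentrated in the low-education group, and smoking (not
  # education) drives the outcome: M1 overstates education, M2 corrects it
  set.seed(44)
  reps <- 20
  att <- logical(reps)
  for (r in seq_len(reps)) {
    n <- 500
    d <- sim_phenotypes(n, seed = 100 + r)
    p_cur <- c(High = 0.05, Medium = 0.15, Low = 0.45)[d$education]
    d$smoking <- ifelse(runif(n) < p_cur, "Current",
                        sample(c("Never", "Former"), n, TRUE))
    d$y <- 1.0 * (d$smoking == "Current") + rnorm(n, sd = 1.5)
    est <- fit_cohort_models(d, "y", factors = "education")
    b1 <- est$beta[est$model == "M1" & est$category == "Low"]
    b2 <- est$beta[est$model == "M2" & est$category == "Low"]
    att[r] <- abs(b2) < abs(b1)
  }
  expect_gte(mean(att), 0.8)
})

test_that("interaction product terms are null-calibrated and detectable", {
  # null: rejection rate of the age product term near the nominal 5%
  set.seed(77)
  reps <- 200
  rej <- logical(reps)
  for (r in seq_len(reps)) {
    d <- sim_phenotypes(150, seed = 5000 + r)
    d$y <- 0.3 * (d$education == "Low") + rnorm(150)
    est <- fit_interaction(d, "y", "education", moderator = "age")
    low <- est[est$category == "Low:age", ]
    rej[r] <- abs(low$beta / low$se) > qnorm(0.975)
  }
  expect_gte(mean(rej), 0.02)
  expect_lte(mean(rej), 0.09)

  # a planted age-varying effect is detected at n = 2000
  d <- sim_phenotypes(2000, seed = 321)
  d$y <- (0.02 * (d$age - 55)) * (d$education == "Low") + rnorm(2000, sd = 0.5)
  est <- fit_interaction(d, "y", "education", moderator = "age")
  low <- est[est$category == "Low:age", ]
  expect_gt(low$beta / low$se, qnorm(0.975))
  expect_lt(abs(low$beta - 0.02), 3 * low$se)
})

test_that("sex moderation is centered on zero under a balanced null", {
  set.seed(55)
  zs <- replicate(40, {
    d <- sim_phenotypes(200, seed = sample.int(1e6, 1))
    d$y <- 0.5 * (d$education == "Low") + rnorm(200)
    est <- fit_interaction(d, "y", "education", moderator = "sex")
    low <- est[est$category == "Low:sex", ]
    low$beta / low$se
  })
  expect_lt(abs(mean(zs)), 3 / sqrt(40))
  strat <- fit_sex_stratified(sim_phenotypes(300, seed = 9), "age", "education")
  expect_equal(nrow(strat), 4L)
  expect_setequal(unique(strat$stratum), c("female", "male"))
})
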