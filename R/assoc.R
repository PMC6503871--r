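#' Treatment-coded design matrix for one focal risk factor
#'
#' Builds the ordinary least-squares design for a per-cohort exposure model
#' with dummy (treatment) coding against the fixed reference levels
#' (education High, smoking Never, obesity NormalWeight, alcohol Abstainer,
#' physical activity High). Model `"M1"` adjusts for age, sex and any
#' cohort-specific covariates; model `"M2"` additionally includes the
#' dummies of the other four risk factors (the mutually adjusted
#' specification). Categories absent from the data lose their dummy with a
#' warning (no estimate is produced for that contrast).
#'
#' @param phenotypes Phenotype `data.frame` for one cohort.
#' @param factor Focal risk factor name.
#' @param model `"M1"` or `"M2"`.
#' @param covariates Character vector of extra covariate column names.
#' @return List with `X` (design matrix including intercept), `focal_cols`
#'   (column names of the focal factor's dummies), `categories` (the
#'   non-reference categories they encode) and `dropped` (absent
#'   categories).
#' @export
encode_design <- function(phenotypes, factor, model = c("M1", "M2"),
                          covariates = character()) {
  model <- match.arg(model)
  lv <- risk_factor_levels()
  if (!factor %in% names(lv)) {
    stop("unknown risk factor '", factor, "'")
  }
  d <- as.data.frame(phenotypes)
  factors_in <- if (model == "M2") names(lv) else factor
  factors_in <- union(factor, factors_in)
  dropped <- character()
  usable <- character()
  for (f in factors_in) {
    if (!f %in% names(d)) stop("phenotype table lacks factor column '", f, "'")
    observed <- intersect(lv[[f]], unique(stats::na.omit(d[[f]])))
    absent <- setdiff(lv[[f]], observed)
    if (length(absent) > 0) {
      warning(sprintf("factor '%s': category(ies) %s absent; dummy dropped",
                      f, paste(absent, collapse = ", ")), call. = FALSE)
      if (f == factor) dropped <- setdiff(absent, lv[[f]][1])
    }
    d[[f]] <- base::factor(d[[f]], levels = intersect(lv[[f]], observed))
    # a single-level factor carries no contrast and leaves the formula
    if (length(observed) >= 2) usable <- c(usable, f)
  }
  d$.sex <- base::factor(d$sex, levels = intersect(c("female", "male"),
                                                   unique(d$sex)))
  rhs <- c(usable, "age", if (nlevels(d$.sex) >= 2) ".sex", covariates)
  fml <- stats::as.formula(paste("~", paste(rhs, collapse = " + ")))
  X <- stats::model.matrix(fml, data = d)
  categories <- if (factor %in% usable) {
    setdiff(levels(d[[factor]]), lv[[factor]][1])
  } else character()
  focal_cols <- paste0(factor, categories, recycle0 = TRUE)
  list(X = X, focal_cols = focal_cols, categories = categories,
       dropped = dropped, model = model)
}

#' Per-cohort linear exposure models for epigenetic aging outcomes
#'
#' For one cohort, regresses each outcome on each focal risk factor under
#' the requested model specification(s) by ordinary least squares, and
#' returns the focal factor's non-reference category estimates with
#' classical (homoskedastic) standard errors and normal Wald 95% confidence
#' intervals `beta +/- 1.959964 * se`. Rows with a missing outcome or
#' missing design entries are deleted listwise (a message reports the count
#' when more than 10% are lost). Robust (HC1) standard errors are available
#' as an option.
#'
#' @param data Per-cohort `data.frame` holding the outcome column(s), the
#'   phenotype columns and a single `cohort_id`.
#' @param outcomes Character vector of outcome column names (years for
#'   clock residuals; log counts for the SEM burden).
#' @param factors Risk factors to model (default all five).
#' @param models `"M1"`, `"M2"` or both.
#' @param covariates Extra cohort-specific covariate columns.
#' @param se_type `"classical"` (default) or `"hc1"`.
#' @return A `data.frame` of association estimates: `cohort_id`, `outcome`,
#'   `factor`, `category`, `model`, `beta`, `se`, `ci_lo`, `ci_hi`, `n`.
#' @export
fit_cohort_models <- function(data, outcomes,
                              factors = names(risk_factor_levels()),
                              models = c("M1", "M2"),
                              covariates = character(),
                              se_type = c("classical", "hc1")) {
  se_type <- match.arg(se_type)
  d <- as.data.frame(data)
  if (is.null(d$cohort_id)) d$cohort_id <- "cohort01"
  if (length(unique(d$cohort_id)) != 1) {
    stop("fit_cohort_models expects a single cohort per call")
  }
  rows <- list()
  for (outcome in outcomes) {
    if (!outcome %in% names(d)) stop("missing outcome column '", outcome, "'")
    for (model in models) {
      for (f in factors) {
        rows[[length(rows) + 1]] <-
          fit_one_model(d, outcome, f, model, covariates, se_type)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

fit_one_model <- function(d, outcome, factor, model, covariates, se_type,
                          extra_terms = NULL) {
  des <- encode_design(d, factor, model, covariates)
  y <- d[[outcome]]
  X <- des$X
  if (!is.null(extra_terms)) X <- cbind(X, extra_terms)
  ok <- !is.na(y) & stats::complete.cases(X)
  if (mean(!ok) > 0.10) {
    message(sprintf("%s/%s/%s: %d of %d rows dropped (missing data)",
                    outcome, factor, model, sum(!ok), length(ok)))
  }
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n < p + 1) stop("too few complete observations (", n, ") for ", p,
                      " design columns")
  fit <- stats::lm.fit(X, y)
  if (any(is.na(fit$coefficients))) {
    stop("collinear design; aliased column(s): ",
         paste(names(fit$coefficients)[is.na(fit$coefficients)],
               collapse = ", "))
  }
  piv <- fit$qr$pivot
  xtx_inv_piv <- chol2inv(qr.R(fit$qr))
  xtx_inv <- matrix(0, p, p)
  xtx_inv[piv, piv] <- xtx_inv_piv
  sigma2 <- sum(fit$residuals^2) / (n - p)
  se_all <- if (se_type == "classical") {
    sqrt(diag(xtx_inv) * sigma2)
  } else {
    # HC1 sandwich
    meat <- crossprod(X * fit$residuals)
    v <- xtx_inv %*% meat %*% xtx_inv * n / (n - p)
    sqrt(diag(v))
  }
  names(se_all) <- colnames(X)
  report_cols <- if (is.null(extra_terms)) des$focal_cols else
    colnames(extra_terms)
  categories <- if (is.null(extra_terms)) des$categories else
    colnames(extra_terms)
  z <- stats::qnorm(0.975)
  beta <- unname(fit$coefficients[report_cols])
  se <- unname(se_all[report_cols])
  data.frame(cohort_id = d$cohort_id[1], outcome = outcome, factor = factor,
             category = categories, model = model, beta = beta, se = se,
             ci_lo = beta - z * se, ci_hi = beta + z * se, n = n,
             stringsAsFactors = FALSE)
}

#' Exposure-by-age or exposure-by-sex interaction models
#'
#' Augments the minimally adjusted (M1) design with products of the focal
#' factor's dummies and the moderator (centered age, or the male indicator)
#' and reports the product-term coefficients. A positive age product term
#' for a category means the category's effect on the outcome grows with
#' age.
#'
#' @inheritParams fit_cohort_models
#' @param outcome Single outcome column name.
#' @param factor Focal risk factor.
#' @param moderator `"age"` or `"sex"`.
#' @return A `data.frame` like [fit_cohort_models()]'s, with `category`
#'   holding `"<category>:<moderator>"` product labels and `model`
#'   `"M1+<moderator>-interaction"`.
#' @export
fit_interaction <- function(data, outcome, factor,
                            moderator = c("age", "sex"),
                            covariates = character(),
                            se_type = c("classical", "hc1")) {
  moderator <- match.arg(moderator)
  se_type <- match.arg(se_type)
  d <- as.data.frame(data)
  if (is.null(d$cohort_id)) d$cohort_id <- "cohort01"
  des <- encode_design(d, factor, "M1", covariates)
  mod_vec <- if (moderator == "age") {
    d$age - mean(d$age, na.rm = TRUE)
  } else {
    as.numeric(d$sex == "male") - mean(d$sex == "male", na.rm = TRUE)
  }
  prods <- des$X[, des$focal_cols, drop = FALSE] * mod_vec
  colnames(prods) <- paste0(des$categories, ":", moderator)
  fit_one_model(d, outcome, factor, "M1", covariates, se_type,
                extra_terms = prods)
}

#' Sex-stratified per-cohort fits
#'
#' Fits the M1 specification (without the sex adjustment term) separately
#' in men and women, complementing the pooled product-term test of
#' [fit_interaction()].
#'
#' @inheritParams fit_interaction
#' @return A `data.frame` of estimates with an extra `stratum` column.
#' @export
fit_sex_stratified <- function(data, outcome, factor,
                               covariates = character()) {
  d <- as.data.frame(data)
  if (is.null(d$cohort_id)) d$cohort_id <- "cohort01"
  out <- lapply(c("female", "male"), function(sx) {
    ds <- d[d$sex == sx, , drop = FALSE]
    des <- encode_design(ds, factor, "M1", covariates)
    X <- des$X[, colnames(des$X) != ".sexmale", drop = FALSE]
    y <- ds[[outcome]]
    ok <- !is.na(y) & stats::complete.cases(X)
    y <- y[ok]
    X <- X[ok, , drop = FALSE]
    fit <- stats::lm.fit(X, y)
    piv <- fit$qr$pivot
    xtx_inv <- matrix(0, ncol(X), ncol(X))
    xtx_inv[piv, piv] <- chol2inv(qr.R(fit$qr))
    sigma2 <- sum(fit$residuals^2) / (length(y) - ncol(X))
    se_all <- stats::setNames(sqrt(diag(xtx_inv) * sigma2), colnames(X))
    z <- stats::qnorm(0.975)
    beta <- unname(fit$coefficients[des$focal_cols])
    se <- unname(se_all[des$focal_cols])
    data.frame(cohort_id = ds$cohort_id[1], outcome = outcome,
               factor = factor, category = des$categories,
               model = "M1+sex-stratified", stratum = sx,
               beta = beta, se = se,
               ci_lo = beta - z * se, ci_hi = beta + z * se, n = length(y),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
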