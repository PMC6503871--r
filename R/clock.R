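#' Predict DNA methylation age from a beta matrix
#'
#' Computes the linear predictor `intercept + sum_j w_j * beta_ij` over the
#' clock's CpGs, then applies the inverse age transform:
#' for `age_transform = "horvath_logadult"` with adult age `A`, a predictor
#' `y < 0` maps to `(1 + A) * exp(y) - 1` and `y >= 0` to
#' `(1 + A) * y + A`; the identity transform returns the predictor as is.
#'
#' At least `min_coverage` of the clock's probes must be present in the
#' matrix; probes entirely absent (within that allowance) are dropped from
#' the weighted sum. Missing cells of present probes are handled per
#' `missing_policy`: imputed with the probe's cross-sample mean, or an
#' error.
#'
#' @param beta A [beta_matrix()] or numeric samples x probes matrix with
#'   dimnames.
#' @param model A [clock_model()].
#' @param missing_policy `"impute_probe_mean"` (default) or `"error"`.
#' @param min_coverage Minimum fraction of model probes present (default
#'   0.95).
#' @return Named numeric vector of DNAm ages (years), one per sample.
#' @export
predict_dnam_age <- function(beta, model,
                             missing_policy = c("impute_probe_mean", "error"),
                             min_coverage = 0.95) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(model, "clock_model"))
  m <- as_sample_probe_matrix(beta)
  probes <- names(model$coefficients)
  present <- probes %in% colnames(m)
  coverage <- mean(present)
  if (coverage < min_coverage) {
    stop(sprintf(
      "only %.1f%% of clock '%s' probes present (floor %.1f%%); missing: %s%s",
      100 * coverage, model$name, 100 * min_coverage,
      paste(utils::head(probes[!present], 10), collapse = ", "),
      if (sum(!present) > 10) ", ..." else ""))
  }
  x <- m[, probes[present], drop = FALSE]
  if (anyNA(x)) {
    if (missing_policy == "error") {
      stop("missing beta values in clock probes and missing_policy = 'error'")
    }
    mu <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 2]]
  }
  y <- model$intercept + drop(x %*% model$coefficients[present])
  age <- if (model$age_transform == "horvath_logadult") {
    a <- model$adult_age
    ifelse(y < 0, (1 + a) * exp(y) - 1, (1 + a) * y + a)
  } else {
    y
  }
  stats::setNames(age, rownames(m))
}

#' Age acceleration and its extrinsic/intrinsic residuals
#'
#' Age acceleration is `aa = dnam_age - age`. Because `aa` can itself
#' correlate with chronological age, the extrinsic measure `eaa` is the
#' residual of the within-cohort ordinary least-squares regression of `aa`
#' on age (intercept included), which is by construction uncorrelated with
#' age and mean zero within each cohort. The intrinsic measure `ieaa`
#' additionally residualizes on the white-blood-cell fraction columns (last
#' one dropped, as fractions sum to 1).
#'
#' @param dnam_age Named numeric vector from [predict_dnam_age()].
#' @param phenotypes Phenotype `data.frame` with `sample_id`, `age`,
#'   optionally `cohort_id` (a single cohort is assumed when absent) and
#'   `wbc_*` columns.
#' @param use_wbc Compute `ieaa` (requires `wbc_*` columns).
#' @param clock_name Carried into the output.
#' @return A `data.frame` with columns `sample_id`, `cohort_id`, `age`,
#'   `dnam_age`, `aa`, `eaa` and, when `use_wbc`, `ieaa`.
#' @export
compute_acceleration <- function(dnam_age, phenotypes, use_wbc = FALSE,
                                 clock_name = "clock") {
  ph <- as.data.frame(phenotypes)
  if (!all(ph$sample_id %in% names(dnam_age))) {
    stop("dnam_age missing for some samples in the phenotype table")
  }
  if (is.null(ph$cohort_id)) ph$cohort_id <- "cohort01"
  if (anyNA(ph$age)) stop("ages must be non-missing")
  ph$dnam_age <- dnam_age[ph$sample_id]
  ph$aa <- ph$dnam_age - ph$age
  wcols <- wbc_columns(ph)
  if (use_wbc && length(wcols) == 0) {
    stop("use_wbc = TRUE but no wbc_* columns present")
  }
  out <- lapply(split(ph, ph$cohort_id), function(d) {
    if (nrow(d) < 10) {
      stop("cohort '", d$cohort_id[1], "' has fewer than 10 samples")
    }
    d$eaa <- stats::resid(stats::lm(aa ~ age, data = d))
    if (use_wbc) {
      w <- as.matrix(d[, wcols, drop = FALSE])
      w <- w[, -ncol(w), drop = FALSE]
      d$ieaa <- stats::resid(stats::lm(d$aa ~ d$age + w))
    }
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  keep <- c("sample_id", "cohort_id", "age", "dnam_age", "aa", "eaa",
            if (use_wbc) "ieaa")
  res <- out[, keep]
  attr(res, "clock_name") <- clock_name
  res
}
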