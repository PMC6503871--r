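#' Random-effects meta-analysis by restricted maximum likelihood
#'
#' Pools k independent cohort estimates `beta_i` with sampling variances
#' `v_i = se_i^2` under the random-effects model
#' `beta_i ~ N(mu, v_i + tau2)`. The between-cohort variance `tau2`
#' maximizes the REML profile log-likelihood
#' \deqn{-\tfrac12 \sum \log(v_i+\tau^2) - \tfrac12 \log \sum w_i
#'   - \tfrac12 \sum w_i (\beta_i - \hat\beta)^2,}
#' with `w_i = 1/(v_i + tau2)` and `betahat = sum(w_i beta_i)/sum(w_i)`,
#' over `[0, tau2_max]` by bounded one-dimensional optimization (tolerance
#' `1e-10`, `tau2_max = 10 * max(v_i) * k`), with the boundary `tau2 = 0`
#' checked explicitly. The pooled standard error is
#' `(sum w_i)^(-1/2)` and the confidence interval is the normal Wald
#' interval `betahat +/- 1.959964 * se` (no small-sample adjustment, which
#' is available via `knha`). Heterogeneity is summarized by Cochran's
#' `Q = sum((beta_i - betahat_FE)^2 / v_i)` with fixed-effect weights, and
#' `I2 = max(0, (Q - (k-1)) / Q) * 100` percent.
#'
#' @param estimates `data.frame` with columns `beta` and `se` (one row per
#'   cohort), e.g. from [fit_cohort_models()]. `k >= 2`, all `se > 0`.
#' @param tau2_max Upper bound of the tau2 search (default
#'   `10 * max(se^2) * k`).
#' @param knha Use the Knapp-Hartung small-sample adjustment (t quantile
#'   and scaled variance) for the pooled interval. Default `FALSE`.
#' @return A one-row `data.frame` of class `meta_result`: `k`,
#'   `beta_pooled`, `se_pooled`, `ci_lo`, `ci_hi`, `tau2`, `i2`, `q_stat`,
#'   `method`; the input estimates are attached as attribute
#'   `"estimates_in"`.
#' @export
reml_pool <- function(estimates, tau2_max = NULL, knha = FALSE) {
  b <- estimates$beta
  v <- estimates$se^2
  check_meta_inputs(b, estimates$se)
  k <- length(b)
  if (is.null(tau2_max)) tau2_max <- 10 * max(v) * k
  # optimize on a variance-standardized scale so the estimator is exactly
  # equivariant under rescaling of the outcome (and well-conditioned)
  s <- max(v)
  vs <- v / s
  bs <- b / sqrt(s)
  nll <- function(t2) {
    w <- 1 / (vs + t2)
    bh <- sum(w * bs) / sum(w)
    0.5 * (sum(log(vs + t2)) + log(sum(w)) + sum(w * (bs - bh)^2))
  }
  opt <- stats::optimize(nll, c(0, tau2_max / s), tol = 1e-10)
  tau2 <- if (nll(0) <= opt$objective) 0 else opt$minimum * s
  finish_pool(b, v, tau2, "REML", knha, estimates)
}

#' DerSimonian-Laird meta-analysis (closed-form comparator)
#'
#' Moment estimator
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))` with
#' fixed-effect weights `w = 1/v`; pooling and heterogeneity statistics as
#' in [reml_pool()].
#'
#' @inheritParams reml_pool
#' @return A `meta_result` as in [reml_pool()], with `method = "DL"`.
#' @export
dl_pool <- function(estimates, knha = FALSE) {
  b <- estimates$beta
  v <- estimates$se^2
  check_meta_inputs(b, estimates$se)
  k <- length(b)
  w <- 1 / v
  bfe <- sum(w * b) / sum(w)
  q <- sum(w * (b - bfe)^2)
  c_const <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / c_const)
  finish_pool(b, v, tau2, "DL", knha, estimates)
}

check_meta_inputs <- function(b, se) {
  if (length(b) < 2) stop("meta-analysis needs at least 2 cohort estimates")
  if (anyNA(b) || anyNA(se)) stop("missing beta or se in estimates")
  if (any(se <= 0)) stop("all standard errors must be positive")
  invisible(TRUE)
}

finish_pool <- function(b, v, tau2, method, knha, estimates) {
  k <- length(b)
  w <- 1 / (v + tau2)
  beta_pooled <- sum(w * b) / sum(w)
  se_pooled <- 1 / sqrt(sum(w))
  wfe <- 1 / v
  bfe <- sum(wfe * b) / sum(wfe)
  q <- sum(wfe * (b - bfe)^2)
  i2 <- if (q > (k - 1)) (q - (k - 1)) / q * 100 else 0
  if (knha) {
    s2 <- sum(w * (b - beta_pooled)^2) / (k - 1)
    se_pooled <- sqrt(max(s2, 1)) * se_pooled
    crit <- stats::qt(0.975, df = k - 1)
  } else {
    crit <- stats::qnorm(0.975)
  }
  out <- data.frame(k = k, beta_pooled = beta_pooled, se_pooled = se_pooled,
                    ci_lo = beta_pooled - crit * se_pooled,
                    ci_hi = beta_pooled + crit * se_pooled,
                    tau2 = tau2, i2 = i2, q_stat = q, method = method,
                    stringsAsFactors = FALSE)
  attr(out, "estimates_in") <- estimates
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Pool a table of cohort estimates over a grouping grid
#'
#' Applies [reml_pool()] (or [dl_pool()]) within each combination of the
#' grouping columns — by default the full outcome x factor x category x
#' model grid of the pipeline.
#'
#' @param estimates `data.frame` of per-cohort estimates (the
#'   [fit_cohort_models()] schema).
#' @param by Grouping columns.
#' @param method `"REML"` (default) or `"DL"`.
#' @param knha Passed to the pooling function.
#' @return A `data.frame` with one pooled row per group, carrying the
#'   grouping columns plus the `meta_result` columns and a two-sided normal
#'   `p_value`.
#' @export
pool_estimates <- function(estimates,
                           by = c("outcome", "factor", "category", "model"),
                           method = c("REML", "DL"), knha = FALSE) {
  method <- match.arg(method)
  by <- intersect(by, names(estimates))
  key <- interaction(estimates[by], drop = TRUE, lex.order = TRUE)
  pooled <- lapply(split(estimates, key), function(d) {
    res <- if (method == "REML") reml_pool(d, knha = knha) else
      dl_pool(d, knha = knha)
    cbind(d[1, by, drop = FALSE], as.data.frame(res))
  })
  out <- do.call(rbind, pooled)
  rownames(out) <- NULL
  out$p_value <- 2 * stats::pnorm(-abs(out$beta_pooled / out$se_pooled))
  out
}

#' Forest plot of pooled effects
#'
#' One marker with its 95% confidence interval per outcome within each
#' factor x category panel, against a dashed null line — the standard
#' display for comparing effects of lifestyle factors across epigenetic
#' aging outcomes (in years once SEM effects are rescaled).
#'
#' @param results `data.frame` from [pool_estimates()] (a single `model`).
#' @param path Optional output file (vector format, e.g. `.pdf`); when
#'   `NULL` the ggplot object is returned without writing.
#' @return The ggplot object, invisibly when written.
#' @export
forest_plot <- function(results, path = NULL) {
  if (nrow(results) == 0) stop("no results to plot")
  if ("model" %in% names(results) && length(unique(results$model)) > 1) {
    stop("forest_plot expects results from a single model")
  }
  d <- results
  d$label <- paste(d$factor, d$category, sep = ": ")
  p <- ggplot2::ggplot(
    d, ggplot2::aes(x = .data$beta_pooled, y = .data$outcome,
                    colour = .data$outcome)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_lo,
                                          xmax = .data$ci_hi)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$label)) +
    ggplot2::labs(x = "Effect (years of epigenetic age)", y = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = "none",
                   strip.text.y = ggplot2::element_text(angle = 0))
  if (!is.null(path)) {
    n_panels <- length(unique(d$label))
    ggplot2::ggsave(path, p, width = 7,
                    height = max(3, 0.8 * n_panels + 1))
    return(invisible(p))
  }
  p
}
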