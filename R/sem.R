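#' Per-probe interquartile-range fences for epimutation calling
#'
#' For each CpG, the cross-sample distribution of beta values yields
#' quartiles Q1 and Q3 (linear-interpolation quantiles, Hyndman-Fan type 7
#' by default; type 2 available) and the outlier fences
#' `lower = Q1 - 3 * IQR`, `upper = Q3 + 3 * IQR` with `IQR = Q3 - Q1`.
#' A stochastic epigenetic mutation (SEM) is a value strictly beyond a
#' fence. Missing values are excluded from the quantiles; probes with fewer
#' than `min_samples` non-missing values are excluded (and reported in the
#' `excluded` attribute), not an error.
#'
#' @param beta A [beta_matrix()] or any numeric samples x probes matrix with
#'   dimnames (e.g. a residual matrix from [wbc_adjust_betas()]).
#' @param min_samples Minimum non-missing samples per probe (default 8).
#' @param quantile_type Quantile convention, 7 (default) or 2.
#' @return A `data.frame` with columns `probe_id`, `q1`, `q3`, `iqr`,
#'   `lower`, `upper`, `n_used`; attribute `excluded` lists dropped probes.
#' @export
compute_fences <- function(beta, min_samples = 8, quantile_type = 7) {
  m <- as_sample_probe_matrix(beta)
  if (!quantile_type %in% c(2, 7)) stop("quantile_type must be 2 or 7")
  n_used <- colSums(!is.na(m))
  keep <- n_used >= min_samples
  excluded <- colnames(m)[!keep]
  if (length(excluded) > 0) {
    message(length(excluded), " probe(s) below the ", min_samples,
            "-sample floor excluded from fence computation")
  }
  qs <- apply(m[, keep, drop = FALSE], 2, stats::quantile,
              probs = c(0.25, 0.75), na.rm = TRUE, names = FALSE,
              type = quantile_type)
  q1 <- qs[1, ]
  q3 <- qs[2, ]
  iqr <- q3 - q1
  out <- data.frame(probe_id = colnames(m)[keep], q1 = q1, q3 = q3,
                    iqr = iqr, lower = q1 - 3 * iqr, upper = q3 + 3 * iqr,
                    n_used = n_used[keep], stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "excluded") <- excluded
  out
}

#' Call stochastic epigenetic mutations and per-sample burden
#'
#' Flags every cell strictly below its probe's lower fence or strictly above
#' its upper fence. Missing values are never SEMs. The per-sample burden is
#' the row count of flagged cells over the probes that carry fences; the
#' modelled outcome is its logarithm — `log(burden + 1)` by default, since
#' small panels can yield zero burdens, or `log(burden)` with zeros mapped
#' to `NA`.
#'
#' @param beta Matrix as in [compute_fences()].
#' @param fences Optional precomputed fences; computed from `beta` when
#'   omitted. Probe sets must match (fences on probes absent from `beta`
#'   are an error).
#' @param log_transform `"log1p"` (default) or `"log"`.
#' @param ... Passed to [compute_fences()] when `fences` is omitted.
#' @return An object of class `sem_result`: list with `fences`, logical
#'   `sem_mask` (samples x fenced probes), integer `burden`, numeric
#'   `log_burden`, and `variant` (`"raw"` here; `"wbc_adjusted"` when called
#'   on residuals via [wbc_adjust_betas()]).
#' @export
call_sems <- function(beta, fences = NULL, log_transform = c("log1p", "log"),
                      ...) {
  log_transform <- match.arg(log_transform)
  m <- as_sample_probe_matrix(beta)
  if (is.null(fences)) fences <- compute_fences(m, ...)
  missing_probes <- setdiff(fences$probe_id, colnames(m))
  if (length(missing_probes) > 0) {
    stop("fences refer to probes absent from the matrix: ",
         paste(utils::head(missing_probes, 5), collapse = ", "))
  }
  m <- m[, fences$probe_id, drop = FALSE]
  lower <- rep(fences$lower, each = nrow(m))
  upper <- rep(fences$upper, each = nrow(m))
  sem_mask <- !is.na(m) & (m < lower | m > upper)
  dimnames(sem_mask) <- dimnames(m)
  burden <- as.integer(rowSums(sem_mask))
  names(burden) <- rownames(m)
  log_burden <- if (log_transform == "log1p") {
    log1p(burden)
  } else {
    ifelse(burden > 0, log(burden), NA_real_)
  }
  names(log_burden) <- rownames(m)
  variant <- attr(beta, "sem_variant")
  structure(list(fences = fences, sem_mask = sem_mask, burden = burden,
                 log_burden = log_burden,
                 variant = if (is.null(variant)) "raw" else variant),
            class = "sem_result")
}

#' @export
print.sem_result <- function(x, ...) {
  cat(sprintf(
    "<sem_result> (%s) %d samples x %d probes; median burden %g, %d SEM calls\n",
    x$variant, nrow(x$sem_mask), ncol(x$sem_mask),
    stats::median(x$burden), sum(x$burden)))
  invisible(x)
}

#' Residualize betas on white-blood-cell fractions
#'
#' For each CpG, fits an ordinary least-squares regression of beta on the
#' estimated leukocyte fractions (intercept included; the last fraction
#' column is dropped since fractions sum to 1) and returns the residual
#' matrix. Applying [compute_fences()] / [call_sems()] to the residuals
#' yields the cell-composition-adjusted SEM variant.
#'
#' @param beta Matrix as in [compute_fences()].
#' @param wbc_fractions Numeric samples x cell-types matrix or data.frame
#'   (rows aligned with `beta`'s samples, or named `wbc_*` columns of a
#'   phenotype table).
#' @return Numeric residual matrix with the same dimnames as `beta`,
#'   carrying attribute `sem_variant = "wbc_adjusted"`.
#' @export
wbc_adjust_betas <- function(beta, wbc_fractions) {
  m <- as_sample_probe_matrix(beta)
  if (is.data.frame(wbc_fractions)) {
    wcols <- wbc_columns(wbc_fractions)
    if (length(wcols) > 0) {
      rn <- if ("sample_id" %in% names(wbc_fractions)) {
        wbc_fractions$sample_id
      } else rownames(wbc_fractions)
      wbc_fractions <- as.matrix(wbc_fractions[, wcols, drop = FALSE])
      rownames(wbc_fractions) <- rn
    } else {
      wbc_fractions <- as.matrix(wbc_fractions)
    }
  }
  if (!is.null(rownames(wbc_fractions))) {
    if (!all(rownames(m) %in% rownames(wbc_fractions))) {
      stop("WBC fractions missing for some samples")
    }
    wbc_fractions <- wbc_fractions[rownames(m), , drop = FALSE]
  } else if (nrow(wbc_fractions) != nrow(m)) {
    stop("WBC fraction rows do not match samples")
  }
  k <- ncol(wbc_fractions)
  if (k < 1) stop("no WBC fraction columns")
  kept <- if (k > 1) wbc_fractions[, -k, drop = FALSE] else
    wbc_fractions[, 0, drop = FALSE]
  x <- cbind(`(Intercept)` = 1, kept)
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    aliased <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("rank-deficient WBC design; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  res <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  complete <- !is.na(m)
  all_complete <- colSums(complete) == nrow(m)
  if (any(all_complete)) {
    res[, all_complete] <- qr.resid(qx, m[, all_complete, drop = FALSE])
  }
  for (j in which(!all_complete)) {
    ok <- complete[, j]
    if (sum(ok) > ncol(x)) {
      res[ok, j] <- stats::lm.fit(x[ok, , drop = FALSE], m[ok, j])$residuals
    }
  }
  attr(res, "sem_variant") <- "wbc_adjusted"
  res
}

# Accept beta_matrix objects or plain numeric matrices with dimnames.
as_sample_probe_matrix <- function(beta) {
  m <- unclass(beta)
  if (!is.matrix(m) || !is.numeric(m)) stop("expected a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop("matrix must carry sample row names and probe column names")
  }
  m
}

#' Positions of probes carrying at least `min_recurrence` SEM calls
#'
#' Collects the SEM loci used by the region-enrichment stage: probes whose
#' column of the SEM mask (summed over one or more [call_sems()] results)
#' reaches the recurrence floor.
#'
#' @param sem_results A `sem_result` or list of them (e.g. one per cohort,
#'   sharing the probe panel).
#' @param min_recurrence Minimum total number of SEM calls at a probe
#'   (default 1).
#' @return Character vector of probe ids.
#' @export
sem_loci <- function(sem_results, min_recurrence = 1) {
  if (inherits(sem_results, "sem_result")) sem_results <- list(sem_results)
  counts <- Reduce(`+`, lapply(sem_results, function(r) colSums(r$sem_mask)))
  names(counts)[counts >= min_recurrence]
}
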