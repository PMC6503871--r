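#' Run the full synthetic-study analysis pipeline
#'
#' Orchestrates one reproducible run: simulate the cohorts, call SEMs (raw
#' and WBC-adjusted), apply the clock and derive extrinsic/intrinsic age
#' acceleration, fit the per-cohort exposure models under both
#' specifications, pool them by random-effects meta-analysis across the
#' four-outcome x five-factor x two-category x two-model grid, re-express
#' the SEM effects in years, and test SEM loci for region enrichment.
#' The four outcomes are `sem_log_burden`, `eaa`, `sem_log_burden_wbc` and
#' `ieaa`. All randomness flows from `config$seed`; the enrichment stage
#' uses the derived substream `config$seed + 1000`.
#'
#' @param config A [simulation_config()].
#' @param meta_method `"REML"` (default) or `"DL"`.
#' @param n_perm Permutations for the enrichment stage.
#' @param min_recurrence SEM-locus recurrence floor, see [sem_loci()].
#' @param quantile_type Fence quantile convention, see [compute_fences()].
#' @param output_dir Optional directory; when given, every stage's table is
#'   written there in the package's exchange formats.
#' @return List of class `pipeline_result` with elements `assoc`
#'   (per-cohort estimates; SEM rows carry rescaled-years columns), `meta`
#'   (the pooled grid, SEM rows pooled on the years scale), `enrichment`,
#'   `table2` (formatted summary table), `outcome_data` (per-sample outcome
#'   table), `study` (the synthetic study) and `manifest` (seed, per-stage
#'   timings and row counts, config hash).
#' @export
run_pipeline <- function(config = simulation_config(),
                         meta_method = "REML", n_perm = 1000,
                         min_recurrence = 1, quantile_type = 7,
                         output_dir = NULL) {
  manifest <- list(seed = config$seed, config_hash = config_hash(config),
                   timings = list(), counts = list())
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    manifest$timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  study <- tick("simulate", simulate_cohorts(config))

  per_cohort <- tick("outcomes", lapply(study$cohorts, function(co) {
    sem_raw <- call_sems(co$beta, quantile_type = quantile_type)
    resid_m <- wbc_adjust_betas(co$beta, co$phenotypes)
    sem_wbc <- call_sems(resid_m, quantile_type = quantile_type)
    dnam <- predict_dnam_age(co$beta, study$clock)
    acc <- compute_acceleration(dnam, co$phenotypes, use_wbc = TRUE,
                                clock_name = study$clock$name)
    d <- merge(co$phenotypes, acc[, c("sample_id", "dnam_age", "aa", "eaa",
                                      "ieaa")], by = "sample_id")
    d$sem_burden <- sem_raw$burden[d$sample_id]
    d$sem_log_burden <- sem_raw$log_burden[d$sample_id]
    d$sem_log_burden_wbc <- sem_wbc$log_burden[d$sample_id]
    list(data = d, sem_raw = sem_raw, sem_wbc = sem_wbc)
  }))

  outcomes <- c("sem_log_burden", "eaa", "sem_log_burden_wbc", "ieaa")
  assoc <- tick("assoc", do.call(rbind, lapply(per_cohort, function(pc) {
    fit_cohort_models(pc$data, outcomes = outcomes)
  })))
  rownames(assoc) <- NULL

  # SEM effects to years: per-cohort Cohen's-d standardization against the
  # cohort's own AA spread, applied before pooling.
  sigmas <- do.call(rbind, lapply(per_cohort, function(pc) {
    data.frame(cohort_id = pc$data$cohort_id[1],
               sigma_sem = stats::sd(pc$data$sem_log_burden),
               sigma_sem_wbc = stats::sd(pc$data$sem_log_burden_wbc),
               sigma_aa = stats::sd(pc$data$aa), stringsAsFactors = FALSE)
  }))
  assoc <- tick("rescale", {
    is_sem <- assoc$outcome %in% c("sem_log_burden", "sem_log_burden_wbc")
    sg <- sigmas[match(assoc$cohort_id, sigmas$cohort_id), ]
    sig_out <- ifelse(assoc$outcome == "sem_log_burden_wbc",
                      sg$sigma_sem_wbc, sg$sigma_sem)
    resc <- rescale_sem_effect(assoc[is_sem, ], sig_out[is_sem],
                               sg$sigma_aa[is_sem])
    for (col in c("cohen_d", "se_d", "beta_years", "se_years",
                  "ci_lo_years", "ci_hi_years")) {
      assoc[[col]] <- NA_real_
      assoc[[col]][is_sem] <- resc[[col]]
    }
    assoc
  })

  meta <- tick("meta", {
    pool_input <- assoc
    is_sem <- pool_input$outcome %in% c("sem_log_burden", "sem_log_burden_wbc")
    pool_input$beta[is_sem] <- pool_input$beta_years[is_sem]
    pool_input$se[is_sem] <- pool_input$se_years[is_sem]
    pooled <- pool_estimates(pool_input, method = meta_method)
    pooled$scale <- ifelse(
      pooled$outcome %in% c("sem_log_burden", "sem_log_burden_wbc"),
      "years (Cohen's d rescaled)", "years")
    pooled
  })

  enrichment <- tick("enrich", {
    loci <- sem_loci(lapply(per_cohort, `[[`, "sem_raw"),
                     min_recurrence = min_recurrence)
    enrichment_batch(loci, study$annotation, study$region_sets,
                     n_perm = n_perm, seed = config$seed + 1000L)
  })

  table2 <- make_table2_like(meta)
  manifest$counts <- list(
    cohorts = length(study$cohorts),
    samples = sum(vapply(per_cohort, function(pc) nrow(pc$data), 0L)),
    assoc_rows = nrow(assoc), meta_rows = nrow(meta),
    enrichment_rows = nrow(enrichment))

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_synthetic_study(study, file.path(output_dir, "synthetic_study"))
    write_results_table(assoc, file.path(output_dir, "assoc_estimates.tsv"))
    write_results_table(meta, file.path(output_dir, "meta_results.tsv"))
    write_results_table(enrichment, file.path(output_dir, "enrichment.tsv"))
    utils::write.table(table2, file.path(output_dir, "table2_like.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(manifest, file.path(output_dir, "manifest.yaml"))
  }

  structure(list(assoc = assoc, meta = meta, enrichment = enrichment,
                 table2 = table2,
                 outcome_data = do.call(rbind, c(lapply(per_cohort, `[[`,
                                                        "data"),
                                                 make.row.names = FALSE)),
                 sigmas = sigmas, study = study, manifest = manifest),
            class = "pipeline_result")
}

config_hash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(unclass(config), tf, version = 2)
  unname(tools::md5sum(tf))
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d cohorts, %d pooled rows, %d region sets; seed %d\n",
    x$manifest$counts$cohorts, nrow(x$meta), nrow(x$enrichment),
    x$manifest$seed))
  invisible(x)
}

#' Format pooled results as a risk-factor by outcome summary table
#'
#' Rows are the five risk factors' non-reference categories (with reference
#' labels); columns are outcome x model cells formatted as
#' `"beta (lo; hi)"` with significance stars at two-sided normal p < 0.05
#' (`*`), < 0.01 (`**`) and < 0.001 (`***`). Missing grid cells render as
#' an em dash.
#'
#' @param meta_results Pooled grid from [pool_estimates()] /
#'   [run_pipeline()].
#' @return A character `data.frame`, one row per factor x category.
#' @export
make_table2_like <- function(meta_results) {
  lv <- risk_factor_levels()
  grid <- do.call(rbind, lapply(names(lv), function(f) {
    data.frame(factor = f, category = lv[[f]][-1], stringsAsFactors = FALSE)
  }))
  grid$label <- sprintf("%s (ref: %s): %s", grid$factor,
                        vapply(grid$factor, function(f) lv[[f]][1], ""),
                        grid$category)
  cells <- unique(meta_results[, c("outcome", "model")])
  cells <- cells[order(cells$outcome, cells$model), ]
  out <- data.frame(risk_factor = grid$label, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cells))) {
    cn <- paste(cells$outcome[i], cells$model[i], sep = "_")
    hit <- merge(grid, meta_results[meta_results$outcome == cells$outcome[i] &
                                      meta_results$model == cells$model[i], ],
                 by = c("factor", "category"), all.x = TRUE, sort = FALSE)
    hit <- hit[match(paste(grid$factor, grid$category),
                     paste(hit$factor, hit$category)), ]
    p <- 2 * stats::pnorm(-abs(hit$beta_pooled / hit$se_pooled))
    stars <- ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
    out[[cn]] <- ifelse(
      is.na(hit$beta_pooled), "—",
      sprintf("%.2f (%.2f; %.2f)%s", hit$beta_pooled, hit$ci_lo, hit$ci_hi,
              stars))
  }
  out
}
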