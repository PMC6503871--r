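#' Configuration for the synthetic multi-cohort generator
#'
#' Builds and validates the parameter set that [simulate_cohorts()] turns
#' into multi-cohort methylation data with recorded ground truth. Defaults
#' describe a scaled-down consortium: several hundred samples per cohort,
#' adult age range, clock CpGs linear in age, an epimutation burden whose
#' expectation grows exponentially with age, categorical lifestyle exposures
#' with additive effects (in years) on latent age acceleration, Dirichlet
#' white-blood-cell composition, and a cohort-level random intercept.
#'
#' @param n_cohorts Number of cohorts.
#' @param n_per_cohort Samples per cohort (minimum 30).
#' @param age_range Length-2 numeric, years, sampled uniformly.
#' @param n_clock_cpgs,n_sem_cpgs,n_wbc_cpgs,n_inert_cpgs Panel composition:
#'   clock CpGs (beta linear in age), SEM-prone CpGs (tight background plus
#'   planted epimutations), cell-composition-sensitive CpGs, and inert CpGs.
#' @param exposure_prevalences Named list (factor -> named probability
#'   vector over its categories, summing to 1).
#' @param exposure_effects_years Named list (factor -> named numeric over
#'   non-reference categories): additive effect on latent age acceleration
#'   delta, in years.
#' @param sem_rate_base Expected epimutation count at age 0 (lambda0 > 0).
#' @param sem_age_slope Per-year log-rate slope r; the expected burden is
#'   `lambda0 * exp(r * age + ...)`.
#' @param sem_exposure_log_effects Named list like `exposure_effects_years`:
#'   additive log-rate terms on the epimutation rate.
#' @param sem_exposure_age_log_effects Optional named list: additional
#'   log-rate per year of age (centered at the midpoint of `age_range`),
#'   producing an exposure-by-age interaction on the burden.
#' @param between_cohort_sd SD (years) of the cohort-level random intercept
#'   on delta.
#' @param delta_sd SD (years) of the individual-level noise on delta.
#' @param noise_sd_beta SD of the Gaussian beta-scale noise added to clock,
#'   WBC-sensitive and inert CpGs (values clipped to \[0, 1\]).
#' @param wbc_dirichlet_alpha Dirichlet concentration for the six simulated
#'   leukocyte fractions (granulocytes, CD4T, CD8T, B, monocytes, NK).
#' @param confounding_matrix Optional named list (factor -> 3x3 numeric
#'   matrix, rows = education level High/Medium/Low, columns = that factor's
#'   categories, rows summing to 1) making exposure prevalences depend on
#'   education.
#' @param enrichment_fold Sampling-weight multiplier for placing planted
#'   epimutations on SEM-prone probes inside the designated region set.
#' @param designated_region Name of the region set receiving the enrichment
#'   weighting.
#' @param seed Integer seed; the same config reproduces output
#'   bit-identically.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cohorts = 6,
                              n_per_cohort = 300,
                              age_range = c(35, 75),
                              n_clock_cpgs = 60,
                              n_sem_cpgs = 500,
                              n_wbc_cpgs = 40,
                              n_inert_cpgs = 40,
                              exposure_prevalences = list(
                                education = c(High = 0.30, Medium = 0.40, Low = 0.30),
                                smoking = c(Never = 0.50, Former = 0.30, Current = 0.20),
                                obesity = c(NormalWeight = 0.40, Overweight = 0.40, Obese = 0.20),
                                alcohol = c(Abstainer = 0.30, Occasional = 0.50, Habitual = 0.20),
                                physical_activity = c(High = 0.35, Medium = 0.40, Low = 0.25)),
                              exposure_effects_years = list(
                                education = c(Medium = 0.3, Low = 0.6),
                                smoking = c(Former = 0.2, Current = 0.5),
                                obesity = c(Overweight = 0.2, Obese = 0.4),
                                alcohol = c(Occasional = 0.0, Habitual = 0.2),
                                physical_activity = c(Medium = 0.1, Low = 0.2)),
                              sem_rate_base = 2,
                              sem_age_slope = 0.03,
                              sem_exposure_log_effects = list(
                                education = c(Medium = 0.05, Low = 0.10),
                                smoking = c(Former = 0.10, Current = 0.15),
                                obesity = c(Overweight = 0.00, Obese = 0.05),
                                alcohol = c(Occasional = 0.00, Habitual = 0.05),
                                physical_activity = c(Medium = 0.00, Low = 0.00)),
                              sem_exposure_age_log_effects = NULL,
                              between_cohort_sd = 0.5,
                              delta_sd = 4,
                              noise_sd_beta = 0.01,
                              wbc_dirichlet_alpha = c(gran = 18, cd4t = 5, cd8t = 3,
                                                      bcell = 2, mono = 2, nk = 2),
                              confounding_matrix = NULL,
                              enrichment_fold = 3,
                              designated_region = "open_chromatin",
                              seed = 1L) {
  cfg <- list(n_cohorts = n_cohorts, n_per_cohort = n_per_cohort,
              age_range = age_range, n_clock_cpgs = n_clock_cpgs,
              n_sem_cpgs = n_sem_cpgs, n_wbc_cpgs = n_wbc_cpgs,
              n_inert_cpgs = n_inert_cpgs,
              exposure_prevalences = exposure_prevalences,
              exposure_effects_years = exposure_effects_years,
              sem_rate_base = sem_rate_base, sem_age_slope = sem_age_slope,
              sem_exposure_log_effects = sem_exposure_log_effects,
              sem_exposure_age_log_effects = sem_exposure_age_log_effects,
              between_cohort_sd = between_cohort_sd, delta_sd = delta_sd,
              noise_sd_beta = noise_sd_beta,
              wbc_dirichlet_alpha = wbc_dirichlet_alpha,
              confounding_matrix = confounding_matrix,
              enrichment_fold = enrichment_fold,
              designated_region = designated_region,
              seed = as.integer(seed))
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$n_cohorts >= 1, length(cfg$age_range) == 2,
            cfg$age_range[1] <= cfg$age_range[2], cfg$age_range[1] > 0,
            cfg$n_clock_cpgs >= 2, cfg$n_sem_cpgs >= 1,
            cfg$sem_rate_base > 0, cfg$delta_sd >= 0,
            cfg$between_cohort_sd >= 0, cfg$noise_sd_beta >= 0,
            cfg$enrichment_fold > 0)
  if (cfg$n_per_cohort < 30) stop("n_per_cohort must be at least 30")
  lv <- risk_factor_levels()
  for (f in names(lv)) {
    p <- cfg$exposure_prevalences[[f]]
    if (is.null(p)) stop("missing prevalences for factor ", f)
    if (!setequal(names(p), lv[[f]])) {
      stop("prevalences for ", f, " must be named by its categories")
    }
    if (any(p < 0) || any(p > 1) || abs(sum(p) - 1) > 1e-8) {
      stop("prevalences for ", f, " must be probabilities summing to 1")
    }
    e <- cfg$exposure_effects_years[[f]]
    if (is.null(e) || !all(names(e) %in% lv[[f]][-1])) {
      stop("exposure_effects_years for ", f,
           " must be named by non-reference categories")
    }
    cm <- cfg$confounding_matrix[[f]]
    if (!is.null(cm)) {
      if (!is.matrix(cm) || nrow(cm) != 3 ||
          !identical(rownames(cm), lv$education) ||
          !setequal(colnames(cm), lv[[f]])) {
        stop("confounding_matrix[['", f, "']] must be 3x3 with education ",
             "rows High/Medium/Low and columns = its categories")
      }
      if (any(abs(rowSums(cm) - 1) > 1e-8)) {
        stop("confounding_matrix rows must sum to 1")
      }
    }
  }
  structure(cfg, class = c("simulation_config", "list"))
}

#' Read a simulation config from YAML
#'
#' Scalars and nested maps in the YAML override the defaults of
#' [simulation_config()]; `confounding_matrix` entries are given as
#' row-ordered lists (High, Medium, Low) of per-category probabilities.
#'
#' @param path Path to a YAML file.
#' @return A `simulation_config`.
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("exposure_prevalences", "exposure_effects_years",
              "sem_exposure_log_effects", "sem_exposure_age_log_effects")) {
    if (!is.null(raw[[f]])) raw[[f]] <- lapply(raw[[f]], unlist)
  }
  if (!is.null(raw$confounding_matrix)) {
    lv <- risk_factor_levels()
    raw$confounding_matrix <- lapply(raw$confounding_matrix, function(m) {
      m <- do.call(rbind, lapply(m, unlist))
      rownames(m) <- lv$education
      m
    })
  }
  if (!is.null(raw$wbc_dirichlet_alpha)) {
    raw$wbc_dirichlet_alpha <- unlist(raw$wbc_dirichlet_alpha)
  }
  merged <- utils::modifyList(unclass(simulation_config()), raw)
  merged$seed <- as.integer(merged$seed)
  validate_simulation_config(merged)
}

# ---------------------------------------------------------------------------
# Panel: probe roles, synthetic 2-chromosome genome, region sets, per-probe
# generative parameters, and the true clock implied by the clock CpGs.
build_panel <- function(cfg) {
  m <- cfg$n_clock_cpgs + cfg$n_sem_cpgs + cfg$n_wbc_cpgs + cfg$n_inert_cpgs
  probe_id <- sprintf("cg%06d", seq_len(m))
  role <- rep(c("clock", "sem", "wbc", "inert"),
              c(cfg$n_clock_cpgs, cfg$n_sem_cpgs, cfg$n_wbc_cpgs,
                cfg$n_inert_cpgs))
  half <- ceiling(m / 2)
  chrom <- rep(c("chr1", "chr2"), c(half, m - half))
  pos <- c(seq_len(half), seq_len(m - half)) * 1000L
  annotation <- data.frame(probe_id = probe_id, chrom = chrom, pos = pos,
                           role = role, stringsAsFactors = FALSE)

  # Deterministically tiled region sets on the synthetic genome: small blocks
  # around every k-th probe, so expected overlaps are computable by hand.
  idx <- seq_len(m)
  tile <- function(name, sel) {
    region_set(name, chrom[sel], pos[sel], pos[sel] + 100L)
  }
  region_sets <- list(
    open_chromatin = tile("open_chromatin", idx %% 4 == 1),
    polycomb_repressed = tile("polycomb_repressed", idx %% 10 %in% c(2, 3)),
    shore = tile("shore", idx %% 5 == 0)
  )
  if (!cfg$designated_region %in% names(region_sets)) {
    stop("designated_region must be one of: ",
         paste(names(region_sets), collapse = ", "))
  }

  # Clock CpGs: beta_ij = mu_j + s_j * (age_i + delta_i) (+ noise, clipped).
  # mu_j is drawn inside the feasible band so that any transformed age within
  # a 5-sigma delta margin keeps the noise-free beta strictly inside (0, 1)
  # and the emitted true clock is exact on clip-free data.
  eff_pos <- sum(vapply(cfg$exposure_effects_years, function(e) max(c(e, 0)), 0))
  eff_neg <- sum(vapply(cfg$exposure_effects_years, function(e) min(c(e, 0)), 0))
  margin <- 5 * cfg$delta_sd + 5 * cfg$between_cohort_sd
  a_min <- max(0, cfg$age_range[1] - margin + eff_neg)
  a_max <- cfg$age_range[2] + margin + eff_pos
  nc <- cfg$n_clock_cpgs
  s <- stats::runif(nc, 0.002, 0.004) * sample(c(-1, 1), nc, replace = TRUE)
  mu_lo <- ifelse(s > 0, 0.02 - s * a_min, 0.02 - s * a_max)
  mu_hi <- ifelse(s > 0, 0.98 - s * a_max, 0.98 - s * a_min)
  if (any(mu_hi <= mu_lo)) {
    stop("clock CpG slopes infeasible for the configured age range")
  }
  mu_clock <- stats::runif(nc, pmax(mu_lo, 0.05), pmin(mu_hi, 0.95))

  w <- 1 / (nc * s)
  true_clock <- clock_model(
    name = "synthetic_true_clock",
    intercept = -sum(mu_clock / s) / nc,
    coefficients = stats::setNames(w, probe_id[role == "clock"]),
    age_transform = "identity")

  # SEM-prone CpGs: tight Beta background; the planted epimutation value is a
  # deterministic push to the far extreme (0.01 / 0.99) so planted events are
  # recoverable ground truth.
  ns <- cfg$n_sem_cpgs
  sem_mean <- stats::runif(ns, 0.25, 0.75)
  sem_conc <- 300
  sem_target <- ifelse(sem_mean < 0.5, 0.99, 0.01)
  sem_in_designated <- probe_in_regions(
    annotation[role == "sem", c("chrom", "pos")],
    region_sets[[cfg$designated_region]])
  sem_weight <- ifelse(sem_in_designated, cfg$enrichment_fold, 1)

  # WBC-sensitive CpGs: additive load on the centered granulocyte fraction.
  nw <- cfg$n_wbc_cpgs
  wbc_mu <- if (nw > 0) stats::runif(nw, 0.3, 0.7) else numeric(0)
  wbc_gamma <- if (nw > 0) {
    stats::runif(nw, 0.4, 0.8) * sample(c(-1, 1), nw, replace = TRUE)
  } else numeric(0)

  ni <- cfg$n_inert_cpgs
  inert_mu <- if (ni > 0) stats::runif(ni, 0.1, 0.9) else numeric(0)

  list(annotation = annotation, region_sets = region_sets,
       true_clock = true_clock,
       clock = list(mu = mu_clock, s = s),
       sem = list(mean = sem_mean, conc = sem_conc, target = sem_target,
                  weight = sem_weight),
       wbc = list(mu = wbc_mu, gamma = wbc_gamma),
       inert = list(mu = inert_mu))
}

rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), nrow = n,
              byrow = TRUE)
  sw <- g / rowSums(g)
  colnames(sw) <- names(alpha)
  sw
}

draw_categories <- function(n, prob, levels_) {
  prob <- prob[levels_]
  levels_[sample.int(length(levels_), n, replace = TRUE, prob = prob)]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

simulate_one_cohort <- function(cfg, panel, ci) {
  lv <- risk_factor_levels()
  n <- cfg$n_per_cohort
  cohort_id <- sprintf("cohort%02d", ci)
  sample_id <- sprintf("%s_s%04d", cohort_id, seq_len(n))
  age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
  sex <- c("male", "female")[1 + stats::rbinom(n, 1, 0.5)]

  education <- draw_categories(n, cfg$exposure_prevalences$education,
                               lv$education)
  exposures <- list(education = education)
  for (f in setdiff(names(lv), "education")) {
    cm <- cfg$confounding_matrix[[f]]
    if (is.null(cm)) {
      exposures[[f]] <- draw_categories(n, cfg$exposure_prevalences[[f]],
                                        lv[[f]])
    } else {
      exposures[[f]] <- vapply(education, function(ed) {
        draw_categories(1, cm[ed, ], lv[[f]])
      }, "")
    }
  }

  eff_years <- rep(0, n)
  log_rate_eff <- rep(0, n)
  age_c <- age - mean(cfg$age_range)
  for (f in names(lv)) {
    e <- cfg$exposure_effects_years[[f]]
    hit <- match(exposures[[f]], names(e))
    eff_years <- eff_years + ifelse(is.na(hit), 0, e[hit])
    le <- cfg$sem_exposure_log_effects[[f]]
    if (!is.null(le)) {
      hit <- match(exposures[[f]], names(le))
      log_rate_eff <- log_rate_eff + ifelse(is.na(hit), 0, le[hit])
    }
    ae <- cfg$sem_exposure_age_log_effects[[f]]
    if (!is.null(ae)) {
      hit <- match(exposures[[f]], names(ae))
      log_rate_eff <- log_rate_eff + ifelse(is.na(hit), 0, ae[hit]) * age_c
    }
  }

  cohort_effect <- stats::rnorm(1, 0, cfg$between_cohort_sd)
  delta <- eff_years + cohort_effect + stats::rnorm(n, 0, cfg$delta_sd)
  a <- age + delta

  wbc <- rdirichlet(n, cfg$wbc_dirichlet_alpha)
  colnames(wbc) <- paste0("wbc_", names(cfg$wbc_dirichlet_alpha))
  gran_c <- wbc[, 1] - cfg$wbc_dirichlet_alpha[1] / sum(cfg$wbc_dirichlet_alpha)

  noise <- function(nr, nc_) {
    if (cfg$noise_sd_beta > 0) {
      matrix(stats::rnorm(nr * nc_, 0, cfg$noise_sd_beta), nr, nc_)
    } else 0
  }

  beta_clock <- clip01(outer(a, panel$clock$s) +
                         rep(panel$clock$mu, each = n) +
                         noise(n, cfg$n_clock_cpgs))

  # SEM-prone background, then planted epimutations.
  ns <- cfg$n_sem_cpgs
  shape1 <- rep(panel$sem$mean * panel$sem$conc, each = n)
  shape2 <- rep((1 - panel$sem$mean) * panel$sem$conc, each = n)
  beta_sem <- matrix(stats::rbeta(n * ns, shape1, shape2), n, ns)
  lambda <- cfg$sem_rate_base * exp(cfg$sem_age_slope * age + log_rate_eff)
  k_true <- pmin(stats::rpois(n, lambda), ns)
  ev_sample <- rep(seq_len(n), k_true)
  ev_probe <- unlist(lapply(seq_len(n), function(i) {
    if (k_true[i] == 0) return(integer(0))
    sample.int(ns, k_true[i], prob = panel$sem$weight)
  }))
  beta_sem[cbind(ev_sample, ev_probe)] <- panel$sem$target[ev_probe]

  beta_wbc <- if (cfg$n_wbc_cpgs > 0) {
    clip01(rep(panel$wbc$mu, each = n) + outer(gran_c, panel$wbc$gamma) +
             noise(n, cfg$n_wbc_cpgs))
  } else matrix(numeric(0), n, 0)
  beta_inert <- if (cfg$n_inert_cpgs > 0) {
    clip01(matrix(rep(panel$inert$mu, each = n), n, cfg$n_inert_cpgs) +
             noise(n, cfg$n_inert_cpgs))
  } else matrix(numeric(0), n, 0)

  values <- cbind(beta_clock, beta_sem, beta_wbc, beta_inert)
  beta <- beta_matrix(values, sample_ids = sample_id,
                      probe_ids = panel$annotation$probe_id)

  sem_probe_ids <- panel$annotation$probe_id[panel$annotation$role == "sem"]
  phenotypes <- data.frame(sample_id = sample_id, cohort_id = cohort_id,
                           age = age, sex = sex,
                           education = exposures$education,
                           smoking = exposures$smoking,
                           obesity = exposures$obesity,
                           alcohol = exposures$alcohol,
                           physical_activity = exposures$physical_activity,
                           stringsAsFactors = FALSE)
  phenotypes <- cbind(phenotypes, as.data.frame(wbc))
  validate_phenotypes(phenotypes)

  list(cohort_id = cohort_id, beta = beta, phenotypes = phenotypes,
       truth = list(delta = stats::setNames(delta, sample_id),
                    sem_count = stats::setNames(k_true, sample_id),
                    sem_events = data.frame(
                      sample_id = sample_id[ev_sample],
                      probe_id = sem_probe_ids[ev_probe],
                      stringsAsFactors = FALSE),
                    cohort_effect = cohort_effect))
}

#' Simulate a multi-cohort synthetic methylation study
#'
#' Generates, per cohort, a beta matrix, a phenotype table, and per-sample
#' ground truth (latent age acceleration delta, true epimutation count and
#' the planted epimutation cells), sharing one probe panel, probe annotation
#' on a synthetic two-chromosome genome, deterministically tiled region
#' sets, and the true linear clock implied by the clock CpGs. Applying the
#' emitted clock to noise-free, clip-free betas returns `age + delta`
#' exactly.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_study`: list with elements
#'   `cohorts` (each with `cohort_id`, `beta`, `phenotypes`, `truth`),
#'   `annotation` (probe_id/chrom/pos/role), `region_sets`, `clock` (the
#'   true [clock_model()]) and `config`.
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  panel <- build_panel(config)
  cohorts <- lapply(seq_len(config$n_cohorts), function(ci) {
    simulate_one_cohort(config, panel, ci)
  })
  names(cohorts) <- vapply(cohorts, `[[`, "", "cohort_id")
  structure(list(cohorts = cohorts, annotation = panel$annotation,
                 region_sets = panel$region_sets, clock = panel$true_clock,
                 config = config),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d cohorts x %d samples, %d probes (%s)\n",
              length(x$cohorts), x$config$n_per_cohort, nrow(x$annotation),
              paste(names(table(x$annotation$role)), collapse = "/")))
  invisible(x)
}

#' Tabulate the ground truth of a synthetic study
#'
#' One row per cohort: sample size, realized cohort random effect, the
#' configured epimutation rate parameters and enrichment fold, and one
#' `eff_<factor>_<category>` column per planted exposure effect (years) —
#' the targets for parameter-recovery tests.
#'
#' @param study A [simulate_cohorts()] result.
#' @return A `data.frame` with `n_cohorts` rows.
#' @export
truth_report <- function(study) {
  stopifnot(inherits(study, "synthetic_study"))
  cfg <- study$config
  base <- do.call(rbind, lapply(study$cohorts, function(co) {
    data.frame(cohort_id = co$cohort_id, n = nrow(co$phenotypes),
               cohort_effect = co$truth$cohort_effect,
               mean_true_sem = mean(co$truth$sem_count),
               sem_rate_base = cfg$sem_rate_base,
               sem_age_slope = cfg$sem_age_slope,
               enrichment_fold = cfg$enrichment_fold,
               stringsAsFactors = FALSE)
  }))
  rownames(base) <- NULL
  for (f in names(cfg$exposure_effects_years)) {
    e <- cfg$exposure_effects_years[[f]]
    for (cat in names(e)) base[[paste0("eff_", f, "_", cat)]] <- unname(e[cat])
  }
  base
}

#' Write a synthetic study to disk in the pipeline's exchange formats
#'
#' Per cohort, a beta TSV and phenotype TSV; shared probe annotation TSV,
#' one BED per region set, and the true clock coefficient CSV — all readable
#' by the package's own readers.
#'
#' @param study A [simulate_cohorts()] result.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (co in study$cohorts) {
    write_beta_matrix(co$beta, file.path(dir, paste0(co$cohort_id, "_beta.tsv")))
    utils::write.table(co$phenotypes,
                       file.path(dir, paste0(co$cohort_id, "_phenotypes.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(study$annotation, file.path(dir, "probe_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (rs in study$region_sets) {
    write_regions_bed(rs, file.path(dir, paste0(attr(rs, "name"), ".bed")))
  }
  write_clock_model(study$clock, file.path(dir, "true_clock.csv"))
  invisible(dir)
}
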