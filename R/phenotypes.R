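#' Risk-factor category levels and reference categories
#'
#' The five lifestyle risk factors are harmonized to three categories each;
#' the first level of each set is the reference used in all models:
#' education High, smoking Never, obesity NormalWeight (BMI < 25), alcohol
#' Abstainer, physical activity High.
#'
#' @return Named list of character vectors; the first element of each is the
#'   reference level.
#' @export
risk_factor_levels <- function() {
  list(
    education = c("High", "Medium", "Low"),
    smoking = c("Never", "Former", "Current"),
    obesity = c("NormalWeight", "Overweight", "Obese"),
    alcohol = c("Abstainer", "Occasional", "Habitual"),
    physical_activity = c("High", "Medium", "Low")
  )
}

#' Validate a phenotype table
#'
#' Checks identifier uniqueness, positive ages, sex coding, exact
#' (case-sensitive) category labels for every risk factor present, and that
#' white-blood-cell fraction columns (prefix `wbc_`), when present, are
#' non-negative and sum to 1 within `1e-6` per sample. A `relabel` map
#' allows cohort-idiosyncratic codings to be harmonized on load.
#'
#' @param phenotypes A `data.frame` with at least `sample_id`, `age`, `sex`;
#'   optionally `cohort_id`, the five risk factors, `wbc_*` columns, and any
#'   extra covariate columns.
#' @param relabel Optional named list: factor name -> named character vector
#'   mapping observed labels to canonical ones.
#' @return The validated (possibly relabelled) `data.frame`, invisibly
#'   classed `phenotype_table`.
#' @export
validate_phenotypes <- function(phenotypes, relabel = NULL) {
  stopifnot(is.data.frame(phenotypes))
  req <- c("sample_id", "age", "sex")
  missing_cols <- setdiff(req, names(phenotypes))
  if (length(missing_cols) > 0) {
    stop("phenotype table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(phenotypes$sample_id)) stop("duplicate sample_id values")
  if (any(!is.na(phenotypes$age) & phenotypes$age <= 0)) {
    stop("ages must be positive")
  }
  bad_sex <- setdiff(unique(stats::na.omit(phenotypes$sex)), c("male", "female"))
  if (length(bad_sex) > 0) {
    stop("sex must be 'male'/'female'; found: ", paste(bad_sex, collapse = ", "))
  }
  lv <- risk_factor_levels()
  for (f in intersect(names(lv), names(phenotypes))) {
    x <- as.character(phenotypes[[f]])
    if (!is.null(relabel[[f]])) {
      hit <- x %in% names(relabel[[f]])
      x[hit] <- unname(relabel[[f]][x[hit]])
    }
    bad <- setdiff(unique(stats::na.omit(x)), lv[[f]])
    if (length(bad) > 0) {
      stop(sprintf("factor '%s' has labels outside {%s}: %s", f,
                   paste(lv[[f]], collapse = ", "), paste(bad, collapse = ", ")))
    }
    phenotypes[[f]] <- x
  }
  wbc <- wbc_columns(phenotypes)
  if (length(wbc) > 0) {
    fr <- as.matrix(phenotypes[, wbc, drop = FALSE])
    if (any(fr < 0, na.rm = TRUE)) stop("negative WBC fraction")
    s <- rowSums(fr)
    off <- which(!is.na(s) & abs(s - 1) > 1e-6)
    if (length(off) > 0) {
      stop(sprintf("WBC fractions of sample '%s' sum to %.8f, not 1",
                   phenotypes$sample_id[off[1]], s[off[1]]))
    }
  }
  class(phenotypes) <- unique(c("phenotype_table", class(phenotypes)))
  invisible(phenotypes)
}

# Names of the WBC fraction columns of a phenotype table.
wbc_columns <- function(phenotypes) {
  grep("^wbc_", names(phenotypes), value = TRUE)
}

#' Read a phenotype table from delimited text
#' @param path Path to a TSV.
#' @param relabel Optional relabel map, see [validate_phenotypes()].
#' @param sep Field separator.
#' @return A validated phenotype `data.frame`.
#' @export
read_phenotypes <- function(path, relabel = NULL, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  df$sample_id <- as.character(df$sample_id)
  validate_phenotypes(df, relabel = relabel)
}
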