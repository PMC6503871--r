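#' Construct a linear CpG clock model
#'
#' A clock is a linear predictor over probe betas,
#' `intercept + sum_j w_j * beta_j`, optionally followed by the inverse of
#' the log-linear age transform used by pan-tissue clocks trained on
#' transformed age (`horvath_logadult`). Blood clocks in the Hannum/Levine
#' style use the identity transform.
#'
#' @param name Clock name (free text, carried through outputs).
#' @param intercept Numeric intercept of the linear predictor.
#' @param coefficients Named numeric vector, probe id -> weight. Non-empty,
#'   unique names.
#' @param age_transform `"identity"` or `"horvath_logadult"`.
#' @param adult_age Adult-age parameter (years) of the log-linear transform,
#'   default 20.
#' @return An object of class `clock_model`.
#' @export
clock_model <- function(name, intercept, coefficients,
                        age_transform = c("identity", "horvath_logadult"),
                        adult_age = 20) {
  age_transform <- match.arg(age_transform)
  if (length(coefficients) == 0) stop("clock must have at least one coefficient")
  if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
    stop("clock coefficients must be named by probe id")
  }
  if (anyDuplicated(names(coefficients))) {
    stop("duplicate probe ids in clock coefficients")
  }
  structure(list(name = name, intercept = as.numeric(intercept),
                 coefficients = coefficients, age_transform = age_transform,
                 adult_age = adult_age),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model> '%s': %d CpGs, intercept %.4g, transform %s\n",
              x$name, length(x$coefficients), x$intercept, x$age_transform))
  invisible(x)
}

#' Read a clock coefficient table
#'
#' Expects a delimited file with a header and two used columns: probe id and
#' weight. Exactly one row must carry the reserved probe id `"(Intercept)"`.
#' Published clock coefficient files (353-CpG pan-tissue, 71-CpG blood,
#' 513-CpG phenotypic-age) are supplied by the user in this layout; none are
#' vendored with the package.
#'
#' @param path Path to a CSV (or `sep`-delimited) file.
#' @param name Clock name; defaults to the file base name.
#' @param age_transform,adult_age Passed to [clock_model()].
#' @param sep Field separator, default comma.
#' @return A [clock_model()].
#' @export
read_clock_model <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                             age_transform = "identity", adult_age = 20,
                             sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("clock file needs probe and weight columns")
  probes <- as.character(df[[1]])
  weights <- df[[2]]
  if (!is.numeric(weights)) stop("clock weight column is not numeric")
  is_int <- probes == "(Intercept)"
  if (sum(is_int) != 1) {
    stop("clock file must contain exactly one '(Intercept)' row, found ",
         sum(is_int))
  }
  coef_probes <- probes[!is_int]
  if (anyDuplicated(coef_probes)) {
    stop("duplicate probe rows in clock file: ",
         paste(unique(coef_probes[duplicated(coef_probes)]), collapse = ", "))
  }
  clock_model(name = name, intercept = weights[is_int],
              coefficients = stats::setNames(weights[!is_int], coef_probes),
              age_transform = age_transform, adult_age = adult_age)
}

#' Write a clock model to a coefficient table
#' @param model A [clock_model()].
#' @param path Output path.
#' @export
write_clock_model <- function(model, path) {
  df <- data.frame(probe_id = c("(Intercept)", names(model$coefficients)),
                   weight = c(model$intercept, unname(model$coefficients)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a genomic region set
#'
#' Intervals are 0-based half-open `[start, end)`, BED-native. Probe loci are
#' treated as single-base intervals `[pos, pos + 1)` throughout, so overlap
#' semantics are uniform.
#'
#' @param name Region set name.
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors, 0-based half-open. `start < end`.
#' @return A `data.frame` of class `region_set` with columns
#'   `chrom`, `start`, `end` and a `name` attribute.
#' @export
region_set <- function(name, chrom, start, end) {
  if (any(start >= end)) {
    i <- which(start >= end)[1]
    stop(sprintf("invalid interval (start >= end): %s %d %d",
                 chrom[i], start[i], end[i]))
  }
  if (any(start < 0)) stop("negative interval start")
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  attr(df, "name") <- name
  class(df) <- c("region_set", "data.frame")
  df
}

#' Read a BED file of genomic regions
#'
#' @param path Path to a 3+ column BED file (0-based half-open).
#' @param name Region set name; defaults to the file base name.
#' @param merge If `TRUE`, overlapping or abutting intervals are merged on
#'   load.
#' @return A [region_set()].
#' @export
read_regions_bed <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                             merge = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0) {
    return(region_set(name, character(), integer(), integer()))
  }
  fields <- strsplit(lines, "[ \t]+")
  n_fields <- lengths(fields)
  if (any(n_fields < 3)) {
    stop(sprintf("BED line %d has fewer than 3 fields", line_no[n_fields < 3][1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("non-integer coordinate at BED line %d",
                 line_no[which(is.na(start) | is.na(end))[1]]))
  }
  bad <- which(start >= end)
  if (length(bad) > 0) {
    stop(sprintf("invalid interval (start >= end) at BED line %d: %s %d %d",
                 line_no[bad[1]], chrom[bad[1]], start[bad[1]], end[bad[1]]))
  }
  rs <- region_set(name, chrom, start, end)
  if (merge) merge_regions(rs) else rs
}

#' Merge overlapping or abutting intervals within a region set
#' @param regions A [region_set()].
#' @return A [region_set()] with disjoint, sorted intervals.
#' @export
merge_regions <- function(regions) {
  if (nrow(regions) == 0) return(regions)
  out <- lapply(split(regions, regions$chrom), function(d) {
    d <- d[order(d$start, d$end), ]
    # half-open: [a,b) and [b,c) abut and merge into [a,c)
    grp <- cumsum(c(1, d$start[-1] > cummax(d$end[-nrow(d)])))
    data.frame(chrom = d$chrom[1],
               start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max),
               stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, out)
  region_set(attr(regions, "name"), merged$chrom, merged$start, merged$end)
}

#' Write a region set to BED
#' @param regions A [region_set()].
#' @param path Output path.
#' @export
write_regions_bed <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a results table to delimited text
#'
#' Column order is preserved; numerics are written at full double precision
#' (15 significant digits) so a write-read round trip is lossless to
#' at least 12 significant digits.
#'
#' @param records A `data.frame` of results (association estimates, pooled
#'   meta-analysis rows, enrichment results, ...). May have zero rows.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  stopifnot(is.data.frame(records))
  df <- records
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]]) && !is.integer(df[[j]])) {
      df[[j]] <- sprintf("%.15g", df[[j]])
      df[[j]][df[[j]] == "NA"] <- NA
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#' @param path Path to the TSV.
#' @return A `data.frame`.
#' @export
read_results_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, quote = "", comment.char = "")
}
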