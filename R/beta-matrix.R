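#' Construct and validate a methylation beta matrix
#'
#' A beta matrix holds DNA methylation beta values (fraction methylated,
#' bounded in \[0, 1\]) with samples in rows and CpG probes in columns.
#' Missing values (`NA`) are allowed; they represent cells removed by
#' detection-p filtering upstream and every downstream operation states its
#' own missing-data rule.
#'
#' @param values Numeric matrix, samples x probes, with row and column names.
#' @param sample_ids Optional character vector of sample identifiers
#'   (defaults to `rownames(values)`). Must be unique.
#' @param probe_ids Optional character vector of probe identifiers
#'   (defaults to `colnames(values)`). Must be unique.
#' @return A numeric matrix of class `beta_matrix` with dimnames set.
#' @export
beta_matrix <- function(values, sample_ids = rownames(values),
                        probe_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix")
  }
  if (is.null(sample_ids) || is.null(probe_ids)) {
    stop("sample and probe identifiers are required (dimnames or arguments)")
  }
  sample_ids <- as.character(sample_ids)
  probe_ids <- as.character(probe_ids)
  if (length(sample_ids) != nrow(values) || length(probe_ids) != ncol(values)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe ids: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  dimnames(values) <- list(sample_ids, probe_ids)
  check_beta_bounds(values)
  class(values) <- c("beta_matrix", class(values))
  values
}

# Error on any non-missing value outside [0,1], naming the offending cell.
check_beta_bounds <- function(values) {
  bad <- which(!is.na(values) & (values < 0 | values > 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf(
      "beta value out of [0,1]: %g at sample '%s', probe '%s' (%d offending cell(s))",
      values[i, j], rownames(values)[i], colnames(values)[j], nrow(bad)))
  }
  invisible(values)
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf("<beta_matrix> %d samples x %d probes; %d missing cells\n",
              nrow(x), ncol(x), sum(is.na(x))))
  invisible(x)
}

#' Read a beta matrix from delimited text
#'
#' The first column holds identifiers; orientation is explicit and never
#' auto-detected (a silently transposed matrix is a worse failure mode than
#' an error).
#'
#' @param path Path to a TSV/CSV file.
#' @param orientation `"samples_in_rows"` (default) or `"probes_in_rows"`.
#' @param sep Field separator, default tab.
#' @return A [beta_matrix()].
#' @export
read_beta_matrix <- function(path,
                             orientation = c("samples_in_rows", "probes_in_rows"),
                             sep = "\t") {
  orientation <- match.arg(orientation)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("beta matrix file needs an id column plus data columns")
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = list(ids, colnames(raw))))
  bad <- which(is.na(num) & !is.na(raw) & raw != "" & toupper(raw) != "NA",
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at row '%s', column '%s' in %s",
                 raw[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
                 colnames(raw)[bad[1, 2]], path))
  }
  if (orientation == "probes_in_rows") num <- t(num)
  beta_matrix(num)
}

#' Write a beta matrix to delimited text
#'
#' @param beta A [beta_matrix()] (or any numeric matrix with dimnames).
#' @param path Output path.
#' @param orientation Orientation to write, see [read_beta_matrix()].
#' @param sep Field separator.
#' @export
write_beta_matrix <- function(beta, path,
                              orientation = c("samples_in_rows", "probes_in_rows"),
                              sep = "\t") {
  orientation <- match.arg(orientation)
  m <- unclass(beta)
  if (orientation == "probes_in_rows") m <- t(m)
  id_col <- if (orientation == "samples_in_rows") "sample_id" else "probe_id"
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
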