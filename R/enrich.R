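#' Count loci overlapping a region set
#'
#' Loci are single-base probe positions, treated as half-open intervals
#' `[pos, pos + 1)`; a locus overlaps if it intersects any interval of the
#' set on the same chromosome. Chromosomes absent from the region set
#' simply contribute no overlaps.
#'
#' @param loci `data.frame` with columns `chrom` and `pos` (0-based).
#' @param regions A [region_set()].
#' @return Integer count of overlapping loci.
#' @export
overlap_count <- function(loci, regions) {
  sum(probe_in_regions(loci, regions))
}

#' Per-locus region membership indicator
#'
#' @inheritParams overlap_count
#' @return Logical vector along the rows of `loci`.
#' @export
probe_in_regions <- function(loci, regions) {
  out <- logical(nrow(loci))
  if (nrow(loci) == 0 || nrow(regions) == 0) return(out)
  for (ch in intersect(unique(loci$chrom), unique(regions$chrom))) {
    li <- which(loci$chrom == ch)
    r <- regions[regions$chrom == ch, ]
    # 0-based half-open -> 1-based closed IRanges
    q <- IRanges::IRanges(start = loci$pos[li] + 1L, width = 1L)
    s <- IRanges::IRanges(start = r$start + 1L, end = r$end)
    out[li] <- IRanges::countOverlaps(q, s) > 0
  }
  out
}

#' Permutation test for enrichment of SEM loci in a region set
#'
#' Tests whether the observed loci fall inside the region set more (or
#' less) often than random draws from the probe universe. Because
#' methylation arrays are a fixed probe design, the null resamples probe
#' identities — `|loci|` probes drawn uniformly without replacement from the
#' universe per permutation — rather than shuffling genomic coordinates,
#' which respects probe density. The p-value uses the add-one rule
#' `p = (b + 1) / (n_perm + 1)` where `b` counts permutations with overlap
#' at least (alternative `"greater"`) or at most (`"less"`) the observed
#' one, so p is never zero.
#'
#' @param sem_probes Character vector of SEM locus probe ids (a subset of
#'   the universe).
#' @param universe Probe annotation `data.frame` (`probe_id`, `chrom`,
#'   `pos`) defining the array universe.
#' @param regions A [region_set()].
#' @param n_perm Number of permutations (at least 100).
#' @param seed Optional integer seed for reproducibility.
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion).
#' @return One-row `data.frame` of class `enrichment_result`:
#'   `region_set`, `n_loci`, `observed_overlap`, `perm_mean`, `perm_sd`,
#'   `fold`, `p_value`, `n_perm`, `alternative`.
#' @export
permutation_test <- function(sem_probes, universe, regions, n_perm = 1000,
                             seed = NULL, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) stop("n_perm must be at least 100")
  idx <- match(sem_probes, universe$probe_id)
  if (anyNA(idx)) {
    stop("SEM loci not in universe: ",
         paste(utils::head(sem_probes[is.na(idx)], 5), collapse = ", "))
  }
  n_loci <- length(idx)
  if (n_loci > nrow(universe)) stop("more loci than universe probes")
  if (n_loci == 0) stop("no SEM loci supplied")
  inside <- probe_in_regions(universe[, c("chrom", "pos")], regions)
  observed <- sum(inside[idx])
  if (!is.null(seed)) set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i) {
    sum(inside[sample.int(nrow(universe), n_loci)])
  }, 0L)
  b <- if (alternative == "greater") sum(perm >= observed) else
    sum(perm <= observed)
  perm_mean <- mean(perm)
  out <- data.frame(region_set = attr(regions, "name"), n_loci = n_loci,
                    observed_overlap = observed, perm_mean = perm_mean,
                    perm_sd = stats::sd(perm),
                    fold = if (perm_mean > 0) observed / perm_mean else NA_real_,
                    p_value = (b + 1) / (n_perm + 1), n_perm = n_perm,
                    alternative = alternative, stringsAsFactors = FALSE)
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Enrichment tests over several region sets
#'
#' Runs [permutation_test()] once per region set, deriving one seed per set
#' from the master seed (`seed + set index`) so the batch is reproducible
#' while sets remain independent. Region set names must be unique. An
#' optional Bonferroni-adjusted p column is appended (the raw per-set p is
#' the primary report).
#'
#' @inheritParams permutation_test
#' @param region_sets Non-empty list of [region_set()] objects.
#' @param bonferroni Append `p_bonferroni` column (default `TRUE`).
#' @return A `data.frame` with one row per region set.
#' @export
enrichment_batch <- function(sem_probes, universe, region_sets,
                             n_perm = 1000, seed = 1L,
                             alternative = "greater", bonferroni = TRUE) {
  if (length(region_sets) == 0) stop("at least one region set required")
  nms <- vapply(region_sets, attr, "", "name")
  if (anyDuplicated(nms)) {
    stop("duplicate region set names: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  rows <- lapply(seq_along(region_sets), function(i) {
    permutation_test(sem_probes, universe, region_sets[[i]], n_perm = n_perm,
                     seed = seed + i, alternative = alternative)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (bonferroni) {
    out$p_bonferroni <- pmin(1, out$p_value * length(region_sets))
  }
  out
}
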