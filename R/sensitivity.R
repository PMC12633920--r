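# Observed-minus-expected range analysis ("spectrum-style" sensitivity
# assessment): for a focal subset of runs (e.g. thriving societies with
# declining religiosity) and a reference set containing it (e.g. all
# thriving societies), compare the percentage of each group falling into
# equal-width bins of a parameter's sampled range. A positive difference
# marks a range that over-produces the focal outcome.

bin_index <- function(x, lo, hi, n_bins) {
  w <- (hi - lo) / n_bins
  idx <- ceiling((x - lo) / w)
  idx[x <= lo] <- 1L
  pmin(pmax(idx, 1L), n_bins)
}

resolve_range <- function(results, parameter, range) {
  if (!is.null(range)) return(as.numeric(range))
  rg <- attr(results, "ranges")
  if (!is.null(rg) && parameter %in% rg$parameter) {
    i <- match(parameter, rg$parameter)
    return(c(rg$min[i], rg$max[i]))
  }
  range(results[[parameter]], na.rm = TRUE)
}

#' Observed vs expected percentages across equal-width parameter bins
#'
#' Splits the declared range of `parameter` into `n_bins` equal-width bins
#' and, per bin, reports the percentage of focal runs in the bin (observed),
#' the percentage of reference runs in the bin (expected), and their
#' difference in percentage points. Within a parameter the observed and
#' expected columns each sum to 100, so the differences sum to 0.
#'
#' @param results a results table from [run_experiment_batch()].
#' @param focal_mask logical vector marking the focal subset (must be
#'   non-empty and contained in the reference subset).
#' @param reference_mask logical vector marking the reference subset.
#' @param parameter parameter (column) name.
#' @param n_bins number of equal-width bins (5 by convention).
#' @param range optional `c(min, max)` overriding the design's declared
#'   range.
#' @return data.frame with one row per bin: `parameter`, `bin_lo`,
#'   `bin_hi`, `observed_pct`, `expected_pct`, `difference`.
#' @export
observed_expected_by_range <- function(results, focal_mask, reference_mask,
                                       parameter, n_bins = 5, range = NULL) {
  if (!parameter %in% names(results))
    stop(sprintf("parameter '%s' is not a column of the results table",
                 parameter))
  focal_mask <- focal_mask & !is.na(results[[parameter]])
  reference_mask <- reference_mask & !is.na(results[[parameter]])
  if (!any(focal_mask)) stop("focal set is empty")
  if (any(focal_mask & !reference_mask))
    stop("focal set must be a subset of the reference set")
  if (n_bins < 2) stop("n_bins must be at least 2")
  rg <- resolve_range(results, parameter, range)
  x <- results[[parameter]]
  idx_f <- bin_index(x[focal_mask], rg[1], rg[2], n_bins)
  idx_r <- bin_index(x[reference_mask], rg[1], rg[2], n_bins)
  obs <- 100 * tabulate(idx_f, n_bins) / sum(focal_mask)
  exp_ <- 100 * tabulate(idx_r, n_bins) / sum(reference_mask)
  edges <- seq(rg[1], rg[2], length.out = n_bins + 1)
  data.frame(parameter = parameter,
             bin_lo = edges[-length(edges)], bin_hi = edges[-1],
             observed_pct = obs, expected_pct = exp_,
             difference = obs - exp_,
             stringsAsFactors = FALSE)
}

#' Pairwise half-range observed vs expected analysis
#'
#' Splits the declared ranges of two parameters at their midpoints and
#' reports observed/expected percentages and differences for the four
#' lower/upper half combinations, computed exactly as in
#' [observed_expected_by_range()].
#'
#' @inheritParams observed_expected_by_range
#' @param parameter_a,parameter_b the two parameter names.
#' @param range_a,range_b optional range overrides.
#' @return data.frame with four rows; `half_a` and `half_b` label the
#'   lower/upper halves.
#' @export
observed_expected_pairwise <- function(results, focal_mask, reference_mask,
                                       parameter_a, parameter_b,
                                       range_a = NULL, range_b = NULL) {
  for (p in c(parameter_a, parameter_b))
    if (!p %in% names(results))
      stop(sprintf("parameter '%s' is not a column of the results table", p))
  focal_mask <- focal_mask & !is.na(results[[parameter_a]]) &
    !is.na(results[[parameter_b]])
  reference_mask <- reference_mask & !is.na(results[[parameter_a]]) &
    !is.na(results[[parameter_b]])
  if (!any(focal_mask)) stop("focal set is empty")
  if (any(focal_mask & !reference_mask))
    stop("focal set must be a subset of the reference set")
  ra <- resolve_range(results, parameter_a, range_a)
  rb <- resolve_range(results, parameter_b, range_b)
  ha <- ifelse(results[[parameter_a]] <= mean(ra), "lower", "upper")
  hb <- ifelse(results[[parameter_b]] <= mean(rb), "lower", "upper")
  cells <- expand.grid(half_a = c("lower", "upper"),
                       half_b = c("lower", "upper"),
                       stringsAsFactors = FALSE)
  nf <- sum(focal_mask); nr <- sum(reference_mask)
  obs <- exp_ <- numeric(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    incell <- ha == cells$half_a[k] & hb == cells$half_b[k]
    obs[k] <- 100 * sum(incell & focal_mask) / nf
    exp_[k] <- 100 * sum(incell & reference_mask) / nr
  }
  data.frame(parameter_a = parameter_a, parameter_b = parameter_b,
             cells, observed_pct = obs, expected_pct = exp_,
             difference = obs - exp_, stringsAsFactors = FALSE)
}

#' Propose narrowed parameter ranges from an outcome column
#'
#' For each parameter, runs the observed-minus-expected bin analysis with
#' the outcome column as focal set (reference = all complete runs) and
#' proposes, as a narrowed range for the next analysis round, the smallest
#' contiguous union of bins whose summed difference exceeds `min_effect`
#' percentage points (ties broken towards the larger summed difference).
#' Parameters with no such union yield no proposal.
#'
#' @param results a results table.
#' @param success_column name of a logical outcome column (e.g.
#'   `"success"`).
#' @param parameters parameter names to scan.
#' @param min_effect minimum summed observed-minus-expected difference, in
#'   percentage points.
#' @param n_bins equal-width bins per parameter.
#' @return named list of proposed `c(min, max)` ranges (possibly empty).
#' @export
propose_range_restrictions <- function(results, success_column, parameters,
                                       min_effect = 10, n_bins = 5) {
  stopifnot(success_column %in% names(results))
  focal <- !is.na(results[[success_column]]) & results[[success_column]]
  reference <- !is.na(results[[success_column]])
  proposals <- list()
  for (p in parameters) {
    tab <- observed_expected_by_range(results, focal, reference, p,
                                      n_bins = n_bins)
    d <- tab$difference
    best <- NULL
    for (i in seq_len(n_bins)) for (j in i:n_bins) {
      s <- sum(d[i:j])
      if (s > min_effect) {
        len <- j - i + 1
        if (is.null(best) || len < best$len ||
            (len == best$len && s > best$s))
          best <- list(i = i, j = j, len = len, s = s)
      }
    }
    if (!is.null(best))
      proposals[[p]] <- c(tab$bin_lo[best$i], tab$bin_hi[best$j])
  }
  proposals
}
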