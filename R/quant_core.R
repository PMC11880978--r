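# Band-record data model, loading-control normalization, relative levels,
# replicate summaries and significance testing. Every downstream figure
# quantification is built on these primitives.

BAND_COLS <- c("experiment_id", "blot_id", "lane", "condition", "analyte",
               "antibody", "dilution", "intensity", "loading_intensity")

#' Construct a table of band records
#'
#' A band record is one measured immunoblot band: which analyte was probed
#' with which antibody, in which lane of which blot, at which lysate
#' dilution, together with the densitometry intensity and (optionally) the
#' same-lane loading-control intensity (e.g. alpha-tubulin).
#'
#' @param experiment_id character, the independent biological replicate.
#' @param blot_id character, the physical blot/gel.
#' @param lane positive integer lane number.
#' @param condition character condition label (cell line and/or treatment).
#' @param analyte character, the probed protein (e.g. "AXIN1", "GFP-AXIN1").
#' @param antibody character, the detecting antibody.
#' @param dilution fraction of undiluted lysate loaded, in (0, 1].
#' @param intensity non-negative densitometry intensity (arbitrary units).
#' @param loading_intensity positive same-lane loading-control intensity,
#'   or `NA` when no loading control was run on that lane.
#' @return a `data.frame` with one row per band, validated.
#' @export
band_records <- function(experiment_id, blot_id, lane, condition, analyte,
                         antibody, dilution, intensity,
                         loading_intensity = NA_real_) {
  df <- data.frame(
    experiment_id = as.character(experiment_id),
    blot_id = as.character(blot_id),
    lane = as.integer(lane),
    condition = as.character(condition),
    analyte = as.character(analyte),
    antibody = as.character(antibody),
    dilution = as.numeric(dilution),
    intensity = as.numeric(intensity),
    loading_intensity = as.numeric(loading_intensity),
    stringsAsFactors = FALSE
  )
  validate_band_records(df)
}

#' Validate a band-record table
#'
#' Enforces the band-record invariants: intensities non-negative, loading
#' intensities strictly positive when present, dilutions in (0, 1], lanes
#' positive, and (blot_id, lane, analyte) unique.
#'
#' @param df a data frame with the band-record columns.
#' @return `df`, invisibly validated (returned for chaining).
#' @export
validate_band_records <- function(df) {
  assert_cols(df, BAND_COLS, "band-record table")
  if (any(!is.finite(df$intensity) | df$intensity < 0)) {
    stop_ap("band intensities must be finite and >= 0")
  }
  li <- df$loading_intensity
  if (any(!is.na(li) & (!is.finite(li) | li <= 0))) {
    stop_ap("loading_intensity must be > 0 when present")
  }
  if (any(!is.finite(df$dilution) | df$dilution <= 0 | df$dilution > 1)) {
    stop_ap("dilution must lie in (0, 1]")
  }
  if (any(df$lane < 1L)) stop_ap("lane numbers must be >= 1")
  key <- paste(df$blot_id, df$lane, df$analyte, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stop_ap("duplicate band record for blot '%s', lane %d, analyte '%s'",
            dup$blot_id, dup$lane, dup$analyte)
  }
  df
}

#' Normalize band intensities to the same-lane loading control
#'
#' Divides each band's intensity by its same-lane loading-control intensity
#' (alpha-tubulin in the source assays). The dilution factor is deliberately
#' NOT applied here: dilution correction belongs to the dilution-series fit
#' of the bridging calibration, while loading normalization corrects
#' lane-to-lane loading only.
#'
#' @param records band-record data frame (see [band_records()]).
#' @return data frame with columns `condition`, `analyte`, `replicate_id`
#'   and `value` (= intensity / loading_intensity).
#' @export
normalize_to_loading <- function(records) {
  records <- validate_band_records(records)
  bad <- is.na(records$loading_intensity) | records$loading_intensity <= 0
  if (any(bad)) {
    b <- records[bad, , drop = FALSE][1L, ]
    stop_ap("missing or non-positive loading control for blot '%s', lane %d",
            b$blot_id, b$lane)
  }
  data.frame(
    condition = records$condition,
    analyte = records$analyte,
    replicate_id = records$experiment_id,
    value = records$intensity / records$loading_intensity,
    stringsAsFactors = FALSE
  )
}

#' Express normalized levels as percent of a reference condition
#'
#' Within each replicate (and analyte), levels are rescaled so that the
#' reference condition is exactly 100. This mirrors the convention of
#' setting untreated cells to 100% per clone before comparing treatments.
#'
#' @param levels data frame with `condition`, `analyte`, `replicate_id`,
#'   `value` (output of [normalize_to_loading()], or any table in that
#'   schema).
#' @param reference_condition the condition set to 100%.
#' @return data frame with `condition`, `analyte`, `replicate_id`,
#'   `percent_of_reference`. The reference rows are exactly 100.
#' @export
relative_to_reference <- function(levels, reference_condition) {
  assert_cols(levels, c("condition", "analyte", "replicate_id", "value"),
              "normalized-level table")
  split_key <- paste(levels$analyte, levels$replicate_id, sep = "\r")
  groups <- split(seq_len(nrow(levels)), split_key)
  out <- levels
  out$percent_of_reference <- NA_real_
  missing_in <- character(0)
  for (idx in groups) {
    ref <- idx[levels$condition[idx] == reference_condition]
    if (length(ref) == 0L) {
      missing_in <- c(missing_in, unique(levels$replicate_id[idx]))
      next
    }
    ref_value <- mean(levels$value[ref])
    if (ref_value <= 0) {
      stop_ap("reference condition '%s' has non-positive level in replicate '%s'",
              reference_condition, levels$replicate_id[idx[1L]])
    }
    out$percent_of_reference[idx] <- 100 * levels$value[idx] / ref_value
    out$percent_of_reference[ref] <- 100  # exact, by construction
  }
  if (length(missing_in) > 0L) {
    stop_ap("reference condition '%s' absent in replicate(s): %s",
            reference_condition,
            paste(unique(missing_in), collapse = ", "))
  }
  out$value <- NULL
  out
}

#' Summarize replicate values as mean, SEM and n
#'
#' SEM is the sample standard deviation (n - 1 denominator) divided by
#' sqrt(n); a single value has SEM 0 by convention.
#'
#' @param values numeric vector of per-replicate values.
#' @return list with `mean`, `sem`, `n` (class `replicate_summary`).
#' @export
summarize_replicates <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values))) {
    stop_ap("summarize_replicates() needs at least one finite value")
  }
  n <- length(values)
  sem <- if (n == 1L) 0 else stats::sd(values) / sqrt(n)
  structure(list(mean = mean(values), sem = sem, n = n),
            class = "replicate_summary")
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("mean %.4g +/- %.4g SEM (n = %d)\n", x$mean, x$sem, x$n))
  invisible(x)
}

#' Map a p-value to significance stars
#'
#' Convention: `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05,
#' `ns` otherwise.
#'
#' @param p p-value in (0, 1].
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p) {
  if (!is.finite(p) || p < 0 || p > 1) stop_ap("p must lie in [0, 1]")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Two-tailed Student's t-test with the study's conventions
#'
#' Unpaired comparisons use the classical equal-variance (pooled) Student's
#' t-test; Welch's unequal-variance test is available behind `welch = TRUE`.
#' Paired comparisons require equal lengths in matched replicate order.
#' The degenerate paired case of all-zero differences reports p = 1
#' (no evidence of a difference) rather than NaN.
#'
#' @param a,b numeric vectors of per-replicate values (each n >= 2).
#' @param paired logical; pair by position (replicates in matched order).
#' @param welch logical; use Welch's test for unpaired comparisons.
#' @return list with `p_value`, `stars`, `paired` (class
#'   `significance_call`).
#' @export
student_t_test <- function(a, b, paired = FALSE, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    stop_ap("t-test needs at least two values per group (got %d and %d)",
            length(a), length(b))
  }
  if (paired && length(a) != length(b)) {
    stop_ap("paired t-test needs equal group sizes (got %d and %d)",
            length(a), length(b))
  }
  if (paired && all(a - b == 0)) {
    p <- 1.0  # degenerate but user-reachable: identical paired measurements
  } else if (!paired && stats::sd(a) == 0 && stats::sd(b) == 0 &&
             mean(a) == mean(b)) {
    p <- 1.0
  } else {
    p <- stats::t.test(a, b, paired = paired, var.equal = !welch,
                       alternative = "two.sided")$p.value
  }
  structure(list(p_value = p, stars = significance_stars(p), paired = paired),
            class = "significance_call")
}

#' @export
print.significance_call <- function(x, ...) {
  cat(sprintf("%s t-test: p = %.4g [%s]\n",
              if (x$paired) "paired" else "unpaired", x$p_value, x$stars))
  invisible(x)
}
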