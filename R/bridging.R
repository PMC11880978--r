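# Three-antibody bridging calibration for the endogenous AXIN1:AXIN2
# protein ratio. The two endogenous proteins cannot be compared directly
# because the two primary antibodies have unknown, different affinities.
# The bridge runs three same-antibody pairwise comparisons instead:
#
#   endo-AXIN1 vs GFP-AXIN1   (anti-AXIN1 antibody)
#   GFP-AXIN1  vs GFP-AXIN2   (anti-GFP antibody)
#   GFP-AXIN2  vs endo-AXIN2  (anti-AXIN2 antibody)
#
# Within one comparison both analytes are detected by the same antibody, so
# its affinity cancels in the intensity ratio; the product of the three
# ratios telescopes through the GFP fusions and every affinity cancels,
# leaving endo-AXIN1 / endo-AXIN2.

#' Construct a pairwise same-antibody comparison
#'
#' One side of the bridge: two analytes detected on one gel with one
#' antibody, each loaded as a short dilution series (e.g. 1:10, 1:2,
#' undiluted).
#'
#' @param antibody the common detecting antibody.
#' @param analyte_a,analyte_b the two analytes compared (must differ).
#' @param lanes_a,lanes_b data frames with columns `dilution`, `intensity`
#'   (>= 1 row each); full band-record tables are accepted and subset.
#' @return object of class `pairwise_comparison`.
#' @export
pairwise_comparison <- function(antibody, analyte_a, analyte_b,
                                lanes_a, lanes_b) {
  if (identical(analyte_a, analyte_b)) {
    stop_ap("a pairwise comparison needs two distinct analytes (got '%s' twice)",
            analyte_a)
  }
  take <- function(lanes, who) {
    assert_cols(lanes, c("dilution", "intensity"),
                sprintf("lanes for %s", who))
    if (nrow(lanes) < 1L) stop_ap("no lanes provided for analyte '%s'", who)
    if ("antibody" %in% names(lanes) &&
        !all(lanes$antibody == antibody)) {
      stop_ap("all lanes of one comparison must share antibody '%s'", antibody)
    }
    lanes[, c("dilution", "intensity"), drop = FALSE]
  }
  structure(list(antibody = antibody,
                 analyte_a = analyte_a, analyte_b = analyte_b,
                 lanes_a = take(lanes_a, analyte_a),
                 lanes_b = take(lanes_b, analyte_b)),
            class = "pairwise_comparison")
}

#' Assemble a bridge experiment from its three comparisons
#'
#' Validates chain connectivity: comparison 1's second analyte must be
#' comparison 2's first, and comparison 2's second must be comparison 3's
#' first, so the product of ratios telescopes.
#'
#' @param experiment_id identifier of the independent experiment.
#' @param comp1,comp2,comp3 [pairwise_comparison()] objects forming the
#'   chain endo-AXIN1 -> GFP-AXIN1 -> GFP-AXIN2 -> endo-AXIN2.
#' @return object of class `bridge_experiment`.
#' @export
bridge_experiment <- function(experiment_id, comp1, comp2, comp3) {
  if (!identical(comp1$analyte_b, comp2$analyte_a)) {
    stop_ap("broken bridge chain in '%s': comparison 1 ends at '%s' but comparison 2 starts at '%s'",
            experiment_id, comp1$analyte_b, comp2$analyte_a)
  }
  if (!identical(comp2$analyte_b, comp3$analyte_a)) {
    stop_ap("broken bridge chain in '%s': comparison 2 ends at '%s' but comparison 3 starts at '%s'",
            experiment_id, comp2$analyte_b, comp3$analyte_a)
  }
  structure(list(experiment_id = experiment_id,
                 comp1 = comp1, comp2 = comp2, comp3 = comp3),
            class = "bridge_experiment")
}

#' Fit a through-origin line to a dilution series, flagging saturation
#'
#' Band intensity should be proportional to the amount loaded. The fit is
#' least squares through the origin, intensity = slope x dilution, after
#' removing detector-saturated points. Saturation is judged against the
#' origin line anchored at the lowest-dilution point (low-signal lanes are
#' the least likely to saturate): working from the highest dilution
#' downward, a point is flagged while its intensity falls below
#' (1 - saturation_tolerance) of that anchored prediction; flagging stops
#' at the first point on the line, and at least one point is always
#' retained.
#'
#' @param points data frame with columns `dilution`, `intensity`.
#' @param saturation_tolerance allowed fractional shortfall before a point
#'   is called saturated (default 0.20).
#' @return object of class `dilution_fit`: `slope` (intensity per unit
#'   undiluted-equivalent amount), `used_points`, `excluded_points`.
#' @export
fit_dilution_response <- function(points, saturation_tolerance = 0.20) {
  assert_cols(points, c("dilution", "intensity"), "dilution series")
  d <- as.numeric(points$dilution)
  y <- as.numeric(points$intensity)
  if (any(d <= 0 | d > 1)) stop_ap("dilutions must lie in (0, 1]")
  if (any(y < 0)) stop_ap("intensities must be >= 0")
  if (all(y == 0)) stop_ap("all intensities are zero; no dilution response to fit")
  ord <- order(d)
  d <- d[ord]; y <- y[ord]
  # anchor: lowest dilution with signal
  anchor <- which(y > 0)[1L]
  slope_ref <- y[anchor] / d[anchor]
  n <- length(d)
  keep <- rep(TRUE, n)
  if (n > anchor) {
    for (i in seq.int(n, anchor + 1L)) {
      if (y[i] < (1 - saturation_tolerance) * slope_ref * d[i]) {
        keep[i] <- FALSE
      } else break  # saturation affects the top of the series only
    }
  }
  if (!any(keep)) keep[anchor] <- TRUE
  slope <- sum(y[keep] * d[keep]) / sum(d[keep]^2)
  if (!is.finite(slope) || slope <= 0) {
    stop_ap("dilution fit produced a non-positive slope")
  }
  structure(list(slope = slope,
                 used_points = sum(keep),
                 excluded_points = sum(!keep)),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf("dilution fit: slope %.4g (%d used, %d saturation-excluded)\n",
              x$slope, x$used_points, x$excluded_points))
  invisible(x)
}

#' Amount ratio of two analytes detected with one antibody
#'
#' Fits the dilution response of each side and returns slope_a / slope_b.
#' Because both analytes are detected by the same antibody, the (unknown)
#' antibody affinity multiplies both slopes and cancels, so the slope ratio
#' is the amount ratio.
#'
#' @param comp a [pairwise_comparison()].
#' @param saturation_tolerance passed to [fit_dilution_response()].
#' @return positive ratio analyte_a : analyte_b.
#' @export
pairwise_ratio <- function(comp, saturation_tolerance = 0.20) {
  stopifnot(inherits(comp, "pairwise_comparison"))
  fa <- fit_dilution_response(comp$lanes_a, saturation_tolerance)
  fb <- fit_dilution_response(comp$lanes_b, saturation_tolerance)
  fa$slope / fb$slope
}

#' Chained endogenous AXIN1 : AXIN2 ratio for one experiment
#'
#' The product r1 x r2 x r3 of the three pairwise ratios. Every antibody
#' affinity and every GFP-construct abundance cancels exactly, leaving the
#' ratio of the endogenous protein amounts. The anti-GFP step assumes equal
#' detection of GFP-AXIN1 and GFP-AXIN2 (the constructs carry the same tag);
#' `gfp_affinity_correction` divides r2 if an empirically determined
#' correction is available.
#'
#' @param exp a [bridge_experiment()].
#' @param saturation_tolerance passed to the dilution fits.
#' @param gfp_affinity_correction anti-GFP affinity for analyte_a relative
#'   to analyte_b in comparison 2; default 1 (equal detection).
#' @return positive endo-AXIN1 : endo-AXIN2 ratio.
#' @export
chained_ratio <- function(exp, saturation_tolerance = 0.20,
                          gfp_affinity_correction = 1.0) {
  stopifnot(inherits(exp, "bridge_experiment"))
  if (gfp_affinity_correction <= 0) {
    stop_ap("gfp_affinity_correction must be > 0")
  }
  r1 <- pairwise_ratio(exp$comp1, saturation_tolerance)
  r2 <- pairwise_ratio(exp$comp2, saturation_tolerance) / gfp_affinity_correction
  r3 <- pairwise_ratio(exp$comp3, saturation_tolerance)
  r1 * r2 * r3
}

#' Aggregate chained ratios over independent experiments
#'
#' Per-experiment chained ratios are averaged arithmetically on the ratio
#' scale with SEM, matching the reporting convention of the source assay
#' (mean +/- SEM of n independent experiments). Log-scale aggregation
#' (geometric mean, SEM of log-ratios) is available via `log_scale = TRUE`.
#'
#' @param experiments list of [bridge_experiment()] objects.
#' @param saturation_tolerance passed to the dilution fits.
#' @param log_scale aggregate on the log scale instead of the ratio scale.
#' @param gfp_affinity_correction passed to [chained_ratio()].
#' @return object of class `ratio_estimate`: `per_experiment`, `mean`,
#'   `sem`, `n`, and `qc` (saturation-excluded lane counts per experiment).
#' @export
aggregate_ratio <- function(experiments, saturation_tolerance = 0.20,
                            log_scale = FALSE, gfp_affinity_correction = 1.0) {
  if (length(experiments) == 0L) stop_ap("no bridge experiments supplied")
  ratios <- vapply(experiments, chained_ratio, numeric(1),
                   saturation_tolerance = saturation_tolerance,
                   gfp_affinity_correction = gfp_affinity_correction)
  excluded <- vapply(experiments, function(e) {
    sides <- list(e$comp1$lanes_a, e$comp1$lanes_b, e$comp2$lanes_a,
                  e$comp2$lanes_b, e$comp3$lanes_a, e$comp3$lanes_b)
    sum(vapply(sides, function(s) {
      fit_dilution_response(s, saturation_tolerance)$excluded_points
    }, numeric(1)))
  }, numeric(1))
  if (log_scale) {
    s <- summarize_replicates(log(ratios))
    est <- list(per_experiment = ratios, mean = exp(s$mean), sem = s$sem,
                n = s$n, scale = "log",
                qc = list(excluded_saturated = excluded))
  } else {
    s <- summarize_replicates(ratios)
    est <- list(per_experiment = ratios, mean = s$mean, sem = s$sem,
                n = s$n, scale = "linear",
                qc = list(excluded_saturated = excluded))
  }
  structure(est, class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("AXIN1:AXIN2 ratio estimate: %.3f +/- %.3f SEM (n = %d, %s scale)\n",
              x$mean, x$sem, x$n, x$scale))
  invisible(x)
}

#' Build bridge experiments from band and design tables
#'
#' `bands` is a band-record table ([band_records()] schema); `design` maps
#' each comparison of each experiment to its antibody and analyte pair,
#' with columns `experiment_id`, `comparison` (1, 2 or 3), `antibody`,
#' `analyte_a`, `analyte_b`. Lanes are matched on (experiment_id, antibody,
#' analyte).
#'
#' @param bands band-record data frame.
#' @param design bridge design data frame.
#' @return list of [bridge_experiment()] objects, ordered by experiment_id.
#' @export
assemble_bridge_experiments <- function(bands, design) {
  bands <- validate_band_records(bands)
  assert_cols(design, c("experiment_id", "comparison", "antibody",
                        "analyte_a", "analyte_b"), "bridge design")
  lanes_for <- function(eid, antibody, analyte) {
    sel <- bands$experiment_id == eid & bands$antibody == antibody &
      bands$analyte == analyte
    if (!any(sel)) {
      stop_ap("no bands for experiment '%s', antibody '%s', analyte '%s'",
              eid, antibody, analyte)
    }
    bands[sel, c("dilution", "intensity"), drop = FALSE]
  }
  lapply(split(design, design$experiment_id), function(dd) {
    dd <- dd[order(dd$comparison), , drop = FALSE]
    if (!identical(as.integer(dd$comparison), 1:3)) {
      stop_ap("experiment '%s' must define comparisons 1, 2 and 3",
              dd$experiment_id[1L])
    }
    comps <- lapply(seq_len(3L), function(i) {
      pairwise_comparison(
        dd$antibody[i], dd$analyte_a[i], dd$analyte_b[i],
        lanes_for(dd$experiment_id[i], dd$antibody[i], dd$analyte_a[i]),
        lanes_for(dd$experiment_id[i], dd$antibody[i], dd$analyte_b[i])
      )
    })
    bridge_experiment(dd$experiment_id[1L], comps[[1L]], comps[[2L]],
                      comps[[3L]])
  })
}
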