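# Ground-truth generators for every input the pipeline consumes. The band
# model mirrors the measurement model implicit in quantitative
# immunoblotting:
#
#   intensity = min(cap, affinity x abundance x dilution x lane_load x exp(e))
#
# with lane_load ~ LogNormal(0, lane_loading_cv^2) shared by all bands of a
# lane (loading error) and e ~ Normal(0, noise_sigma^2) per band
# (multiplicative densitometry error — errors scale with signal and
# intensities stay positive). Draw order is fixed — lanes in output row
# order, lane load before band noise, loading-control band before target
# band within a lane — so a seed fully determines the output.

#' Ground truth for the synthetic generators
#'
#' @param abundances data frame with columns `condition`, `analyte`,
#'   `abundance` (> 0, arbitrary molar units).
#' @param affinities named numeric vector of antibody affinities (> 0).
#' @param lane_loading_cv SD of log lane-loading error (default 0.1).
#' @param noise_sigma SD of log multiplicative band error (default 0.15).
#' @param saturation_cap detector saturation cap on intensity, or `NULL`.
#' @param dilutions loading dilution series (default 1:10, 1:2, undiluted).
#' @param seed integer RNG seed.
#' @return object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(abundances, affinities,
                            lane_loading_cv = 0.1, noise_sigma = 0.15,
                            saturation_cap = NULL,
                            dilutions = c(0.1, 0.5, 1.0), seed = 1L) {
  assert_cols(abundances, c("condition", "analyte", "abundance"),
              "abundance table")
  if (any(abundances$abundance <= 0)) stop_ap("abundances must be > 0")
  if (is.null(names(affinities)) || any(affinities <= 0)) {
    stop_ap("affinities must be a named vector of positive values")
  }
  if (lane_loading_cv < 0 || noise_sigma < 0) {
    stop_ap("noise parameters must be >= 0")
  }
  if (!is.null(saturation_cap) && saturation_cap <= 0) {
    stop_ap("saturation_cap must be > 0 when present")
  }
  if (any(dilutions <= 0 | dilutions > 1)) {
    stop_ap("dilutions must lie in (0, 1]")
  }
  structure(list(abundances = abundances, affinities = affinities,
                 lane_loading_cv = lane_loading_cv,
                 noise_sigma = noise_sigma,
                 saturation_cap = saturation_cap,
                 dilutions = sort(dilutions), seed = as.integer(seed)),
            class = "synthetic_truth")
}

truth_abundance <- function(truth, condition, analyte) {
  hit <- truth$abundances$abundance[
    truth$abundances$condition == condition &
      truth$abundances$analyte == analyte]
  if (length(hit) != 1L) {
    stop_ap("no ground-truth abundance for condition '%s', analyte '%s'",
            condition, analyte)
  }
  hit
}

truth_affinity <- function(truth, antibody) {
  if (!antibody %in% names(truth$affinities)) {
    stop_ap("no ground-truth affinity for antibody '%s'", antibody)
  }
  truth$affinities[[antibody]]
}

# One band intensity from the current RNG state; abundance may be 0
# (knockout component). lane_load may be supplied to share one lane's
# loading error across its bands.
draw_intensity <- function(truth, abundance, affinity, dilution,
                           lane_load = NULL) {
  if (is.null(lane_load)) {
    lane_load <- exp(stats::rnorm(1L, 0, truth$lane_loading_cv))
  }
  eps <- exp(stats::rnorm(1L, 0, truth$noise_sigma))
  intensity <- affinity * abundance * dilution * lane_load * eps
  if (!is.null(truth$saturation_cap)) {
    intensity <- min(intensity, truth$saturation_cap)
  }
  intensity
}

#' Simulate a single band record
#'
#' Deterministic given `truth$seed` (the seed is set on entry; study-level
#' generators draw many bands under one seed instead).
#'
#' @param truth a [synthetic_truth()].
#' @param condition,analyte,antibody keys into the ground truth.
#' @param dilution fraction of undiluted lysate loaded.
#' @param lane lane number for the emitted record.
#' @param reset_seed set `truth$seed` before drawing (default `TRUE`).
#' @return one-row band-record data frame (no loading control).
#' @export
simulate_band <- function(truth, condition, analyte, antibody, dilution,
                          lane = 1L, reset_seed = TRUE) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (reset_seed) set.seed(truth$seed)
  intensity <- draw_intensity(truth,
                              truth_abundance(truth, condition, analyte),
                              truth_affinity(truth, antibody), dilution)
  band_records(experiment_id = "sim", blot_id = "sim-blot", lane = lane,
               condition = condition, analyte = analyte,
               antibody = antibody, dilution = dilution,
               intensity = intensity)
}

#' Simulate a full bridging study
#'
#' Generates `n_experiments` independent bridge experiments for a known
#' endogenous AXIN1:AXIN2 ratio. Endogenous AXIN1 abundance is
#' `true_ratio` x the endogenous AXIN2 abundance; GFP-construct abundances
#' are drawn independently per experiment (log-normal spread around the
#' endogenous scale), as transfection levels vary between experiments.
#' Each experiment carries the full three-comparison design with each
#' analyte loaded at `truth$dilutions`.
#'
#' @param true_ratio positive ground-truth endo-AXIN1 : endo-AXIN2 ratio.
#' @param n_experiments number of independent experiments (>= 1).
#' @param truth a [synthetic_truth()] whose affinities name the three
#'   antibodies `anti-AXIN1`, `anti-GFP`, `anti-AXIN2`; its abundance table
#'   must provide (`WT`, `AXIN2`), the endogenous AXIN2 scale.
#' @param construct_spread SD of log GFP-construct abundance across
#'   experiments (default 0.5).
#' @return list of [bridge_experiment()] objects.
#' @export
simulate_bridge_study <- function(true_ratio, n_experiments, truth,
                                  construct_spread = 0.5) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.finite(true_ratio) || true_ratio <= 0) {
    stop_ap("true_ratio must be > 0")
  }
  if (n_experiments < 1L) stop_ap("need at least one experiment")
  a2 <- truth_abundance(truth, "WT", "AXIN2")
  a1 <- true_ratio * a2
  set.seed(truth$seed)
  lapply(seq_len(n_experiments), function(e) {
    gfp1 <- a2 * exp(stats::rnorm(1L, 0, construct_spread))
    gfp2 <- a2 * exp(stats::rnorm(1L, 0, construct_spread))
    side <- function(abundance, antibody) {
      do.call(rbind, lapply(truth$dilutions, function(d) {
        data.frame(dilution = d,
                   intensity = draw_intensity(truth, abundance,
                                              truth_affinity(truth, antibody),
                                              d))
      }))
    }
    comp1 <- pairwise_comparison("anti-AXIN1", "AXIN1", "GFP-AXIN1",
                                 side(a1, "anti-AXIN1"),
                                 side(gfp1, "anti-AXIN1"))
    comp2 <- pairwise_comparison("anti-GFP", "GFP-AXIN1", "GFP-AXIN2",
                                 side(gfp1, "anti-GFP"),
                                 side(gfp2, "anti-GFP"))
    comp3 <- pairwise_comparison("anti-AXIN2", "GFP-AXIN2", "AXIN2",
                                 side(gfp2, "anti-AXIN2"),
                                 side(a2, "anti-AXIN2"))
    bridge_experiment(sprintf("exp%02d", e), comp1, comp2, comp3)
  })
}

#' Flatten bridge experiments to the band/design CSV schemas
#'
#' Emits the same tables the analysis stage reads back with
#' [read_bands_csv()] and [assemble_bridge_experiments()]: one blot per
#' antibody per experiment, lanes numbered within blot.
#'
#' @param experiments list of [bridge_experiment()] objects.
#' @param condition condition label stamped on the bands.
#' @return list with `bands` (band-record data frame) and `design`
#'   (bridge-design data frame).
#' @export
bridge_study_tables <- function(experiments, condition = "WT") {
  bands <- do.call(rbind, lapply(experiments, function(e) {
    do.call(rbind, lapply(list(e$comp1, e$comp2, e$comp3), function(cc) {
      rbind(
        data.frame(experiment_id = e$experiment_id, antibody = cc$antibody,
                   analyte = cc$analyte_a, cc$lanes_a,
                   stringsAsFactors = FALSE),
        data.frame(experiment_id = e$experiment_id, antibody = cc$antibody,
                   analyte = cc$analyte_b, cc$lanes_b,
                   stringsAsFactors = FALSE))
    }))
  }))
  bands$blot_id <- paste(bands$experiment_id, bands$antibody)
  bands$lane <- stats::ave(seq_len(nrow(bands)),
                           paste(bands$blot_id, bands$analyte),
                           FUN = seq_along)
  bands$condition <- condition
  bands$loading_intensity <- NA_real_
  bands <- validate_band_records(bands[, BAND_COLS])
  design <- do.call(rbind, lapply(experiments, function(e) data.frame(
    experiment_id = e$experiment_id, comparison = 1:3,
    antibody = c(e$comp1$antibody, e$comp2$antibody, e$comp3$antibody),
    analyte_a = c(e$comp1$analyte_a, e$comp2$analyte_a, e$comp3$analyte_a),
    analyte_b = c(e$comp1$analyte_b, e$comp2$analyte_b, e$comp3$analyte_b),
    stringsAsFactors = FALSE)))
  list(bands = bands, design = design)
}

#' Default ground truth for a bridging simulation
#'
#' @param true_ratio endo-AXIN1 : endo-AXIN2 ratio to encode.
#' @param ... overrides passed to [synthetic_truth()].
#' @return a `synthetic_truth`.
#' @export
bridge_truth <- function(true_ratio = 3.56, ...) {
  args <- list(
    abundances = data.frame(
      condition = "WT",
      analyte = c("AXIN2", "AXIN1"),
      abundance = c(10, 10 * true_ratio),
      stringsAsFactors = FALSE),
    affinities = c(`anti-AXIN1` = 5, `anti-GFP` = 0.2, `anti-AXIN2` = 11)
  )
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_truth, args)
}

#' Simulate a condition panel of target and loading-control bands
#'
#' Emulates the fold-change figure designs: per replicate and condition,
#' one lane carrying the loading-control band (alpha-tubulin, constant true
#' abundance) and the target-analyte band whose true abundance is
#' fold x the reference abundance. Shared lane loading cancels in
#' normalization, so at `noise_sigma = 0` the full pipeline (normalize ->
#' relative-to-reference -> fold) returns `fold_map` exactly.
#'
#' @param truth a [synthetic_truth()]; its abundance table provides the
#'   reference abundance per analyte (condition = `reference`) and a
#'   `tubulin` abundance; affinities must cover each analyte's antibody
#'   (named `anti-<analyte>`) and `anti-tubulin`.
#' @param fold_map data frame `condition`, `analyte`, `fold` (>= 0; include
#'   the reference condition at fold 1). Fold 0 encodes a knockout: the
#'   band is genuinely absent.
#' @param n_replicates independent experiments to simulate.
#' @param reference name of the reference condition (default `"WT"`).
#' @return band-record data frame with `loading_intensity` filled.
#' @export
simulate_condition_panel <- function(truth, fold_map, n_replicates,
                                     reference = "WT") {
  stopifnot(inherits(truth, "synthetic_truth"))
  assert_cols(fold_map, c("condition", "analyte", "fold"), "fold map")
  if (any(fold_map$fold < 0)) stop_ap("folds must be >= 0")
  if (n_replicates < 1L) stop_ap("need at least one replicate")
  tub <- truth_abundance(truth, reference, "tubulin")
  aff_tub <- truth_affinity(truth, "anti-tubulin")
  set.seed(truth$seed)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    lane <- 0L
    for (i in seq_len(nrow(fold_map))) {
      lane <- lane + 1L
      analyte <- fold_map$analyte[i]
      base <- truth_abundance(truth, reference, analyte)
      abundance <- base * fold_map$fold[i]
      lane_load <- exp(stats::rnorm(1L, 0, truth$lane_loading_cv))
      loading <- draw_intensity(truth, tub, aff_tub, 1.0,
                                lane_load = lane_load)
      target <- draw_intensity(truth, abundance,
                               truth_affinity(truth,
                                              paste0("anti-", analyte)),
                               1.0, lane_load = lane_load)
      rows[[length(rows) + 1L]] <- data.frame(
        experiment_id = sprintf("rep%02d", r),
        blot_id = sprintf("blot%02d", r),
        lane = lane,
        condition = fold_map$condition[i],
        analyte = analyte,
        antibody = paste0("anti-", analyte),
        dilution = 1.0,
        intensity = target,
        loading_intensity = loading,
        stringsAsFactors = FALSE)
    }
  }
  validate_band_records(do.call(rbind, rows))
}

#' Default ground truth for a condition-panel simulation
#'
#' @param analytes analyte names to cover (default the study's blot panel).
#' @param ... overrides passed to [synthetic_truth()].
#' @return a `synthetic_truth`.
#' @export
panel_truth <- function(analytes = c("AXIN1", "AXIN2", "beta-catenin"), ...) {
  affinities <- c(stats::setNames(rep(1.5, length(analytes)),
                                  paste0("anti-", analytes)),
                  `anti-tubulin` = 2)
  args <- list(
    abundances = data.frame(
      condition = "WT",
      analyte = c(analytes, "tubulin"),
      abundance = c(rep(10, length(analytes)), 50),
      stringsAsFactors = FALSE),
    affinities = affinities
  )
  args <- utils::modifyList(args, list(...))
  do.call(synthetic_truth, args)
}

#' Simulate a cycloheximide chase
#'
#' True level is 100 exp(-k t) percent; timepoints after 0 carry
#' multiplicative log-normal noise (t = 0 is the normalization anchor and
#' stays at 100 exactly).
#'
#' @param k_true decay rate per hour (>= 0).
#' @param timepoints chase times in hours, starting at 0.
#' @param sigma SD of log multiplicative noise.
#' @param seed RNG seed.
#' @param condition label.
#' @return a [decay_series()].
#' @export
simulate_chx <- function(k_true, timepoints = c(0, 4, 8), sigma = 0,
                         seed = 1L, condition = "WT") {
  if (!is.finite(k_true) || k_true < 0) stop_ap("k_true must be >= 0")
  if (sigma < 0) stop_ap("sigma must be >= 0")
  set.seed(seed)
  levels <- 100 * exp(-k_true * timepoints)
  noisy <- timepoints > 0
  levels[noisy] <- levels[noisy] *
    exp(stats::rnorm(sum(noisy), 0, sigma))
  decay_series(timepoints, levels, condition = condition)
}

#' Simulate TOP/FOP reporter measurements
#'
#' Each replicate gets TOP and FOP wells with transfection efficiencies
#' (beta-gal) drawn log-normally and luciferase readouts proportional to
#' the condition's true activity, under multiplicative noise.
#'
#' @param activities named numeric of true TOP/FOP activities per condition.
#' @param n_replicates replicates per condition.
#' @param sigma SD of log multiplicative noise on luciferase readouts.
#' @param seed RNG seed.
#' @return reporter data frame (see [reporter_activities()]).
#' @export
simulate_reporter <- function(activities, n_replicates = 4L, sigma = 0,
                              seed = 1L) {
  if (is.null(names(activities)) || any(activities <= 0)) {
    stop_ap("activities must be a named vector of positive values")
  }
  if (sigma < 0) stop_ap("sigma must be >= 0")
  set.seed(seed)
  rows <- list()
  for (cond in names(activities)) {
    for (r in seq_len(n_replicates)) {
      top_bgal <- exp(stats::rnorm(1L, 0, 0.2))
      fop_bgal <- exp(stats::rnorm(1L, 0, 0.2))
      fop_scale <- 100
      top_luc <- activities[[cond]] * fop_scale * top_bgal *
        exp(stats::rnorm(1L, 0, sigma))
      fop_luc <- fop_scale * fop_bgal * exp(stats::rnorm(1L, 0, sigma))
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = sprintf("rep%02d", r), condition = cond,
        top_luc = top_luc, top_bgal = top_bgal,
        fop_luc = fop_luc, fop_bgal = fop_bgal,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate recruitment counts
#'
#' Per experiment, the number of cells showing recruitment is binomial
#' with the true per-cell probability.
#'
#' @param p_true true recruitment probability in [0, 1].
#' @param n_cells cells scored per experiment (recycled).
#' @param n_experiments number of independent experiments.
#' @param seed RNG seed.
#' @param setup setup label.
#' @return recruitment-count data frame (see [recruitment_summary()]).
#' @export
simulate_recruitment <- function(p_true, n_cells, n_experiments, seed = 1L,
                                 setup = "setup") {
  if (!is.finite(p_true) || p_true < 0 || p_true > 1) {
    stop_ap("p_true must lie in [0, 1]")
  }
  if (n_experiments < 1L) stop_ap("need at least one experiment")
  set.seed(seed)
  n_cells <- rep_len(as.integer(n_cells), n_experiments)
  data.frame(
    experiment_id = sprintf("exp%02d", seq_len(n_experiments)),
    setup = setup,
    n_recruited = stats::rbinom(n_experiments, n_cells, p_true),
    n_total = n_cells,
    stringsAsFactors = FALSE)
}
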