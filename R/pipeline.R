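# End-to-end runner and input validation. The pipeline stages are
# bridging -> pools -> reporter -> decay -> recruitment; stages whose
# inputs are not configured are marked "skipped" in the run report.

REQUIRED_COLS <- list(
  bands = BAND_COLS,
  bridge_design = c("experiment_id", "comparison", "antibody", "analyte_a",
                    "analyte_b"),
  folds = c("condition", "analyte", "percent"),
  conditions = c("condition", "axin2_absent"),
  reporter = c("replicate_id", "condition", "top_luc", "top_bgal",
               "fop_luc", "fop_bgal"),
  chx = c("condition", "time_h", "level_pct"),
  recruitment = c("experiment_id", "setup", "n_recruited", "n_total")
)

#' Read a band-record CSV
#'
#' Expects exactly the band-record columns as a header; UTF-8, dot decimal
#' separator. An empty `loading_intensity` cell means "no loading control
#' on this lane".
#'
#' @param path CSV path.
#' @return validated band-record data frame.
#' @export
read_bands_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_cols(df, BAND_COLS, sprintf("'%s'", path))
  validate_band_records(df)
}

#' Validate pipeline input files
#'
#' Collects every schema violation — missing files, missing columns,
#' non-numeric cells, broken bridge chains — without stopping at the first.
#'
#' @param paths named list of paths; recognized names are `bands`,
#'   `bridge_design`, `folds`, `conditions`, `reporter`, `chx`,
#'   `recruitment`. Unset entries are ignored.
#' @return character vector of diagnostics; empty when everything is clean.
#' @export
validate_inputs <- function(paths) {
  diags <- character(0)
  note <- function(fmt, ...) diags <<- c(diags, sprintf(fmt, ...))
  tables <- list()
  for (nm in intersect(names(REQUIRED_COLS), names(paths))) {
    p <- paths[[nm]]
    if (is.null(p)) next
    if (!file.exists(p)) {
      note("%s: file not found: %s", nm, p)
      next
    }
    df <- tryCatch(utils::read.csv(p, stringsAsFactors = FALSE),
                   error = function(e) e)
    if (inherits(df, "error")) {
      note("%s: unreadable CSV (%s)", nm, conditionMessage(df))
      next
    }
    missing <- setdiff(REQUIRED_COLS[[nm]], names(df))
    if (length(missing) > 0L) {
      note("%s: missing column(s): %s", nm, paste(missing, collapse = ", "))
      next
    }
    numeric_cols <- switch(nm,
      bands = c("lane", "dilution", "intensity", "loading_intensity"),
      folds = "percent",
      reporter = c("top_luc", "top_bgal", "fop_luc", "fop_bgal"),
      chx = c("time_h", "level_pct"),
      recruitment = c("n_recruited", "n_total"),
      character(0))
    for (cc in numeric_cols) {
      if (!is.numeric(df[[cc]]) && !all(is.na(df[[cc]]))) {
        note("%s: column '%s' contains non-numeric values", nm, cc)
      }
    }
    tables[[nm]] <- df
  }
  if (!is.null(tables$bridge_design)) {
    dd <- tables$bridge_design
    for (eid in unique(dd$experiment_id)) {
      d <- dd[dd$experiment_id == eid, , drop = FALSE]
      d <- d[order(d$comparison), , drop = FALSE]
      if (!identical(as.integer(d$comparison), 1:3)) {
        note("bridge_design: experiment '%s' must define comparisons 1, 2, 3",
             eid)
        next
      }
      if (d$analyte_b[1L] != d$analyte_a[2L]) {
        note("bridge_design: experiment '%s' chain break between comparison 1 ('%s') and 2 ('%s')",
             eid, d$analyte_b[1L], d$analyte_a[2L])
      }
      if (d$analyte_b[2L] != d$analyte_a[3L]) {
        note("bridge_design: experiment '%s' chain break between comparison 2 ('%s') and 3 ('%s')",
             eid, d$analyte_b[2L], d$analyte_a[3L])
      }
    }
  }
  if (!is.null(tables$bands)) {
    v <- tryCatch(validate_band_records(tables$bands), error = function(e) e)
    if (inherits(v, "error")) note("bands: %s", conditionMessage(v))
  }
  diags
}

#' Assemble a run configuration
#'
#' @param bands,bridge_design,folds,conditions,reporter,chx,recruitment
#'   input CSV paths (any may be `NULL` to skip the stage they feed).
#' @param reference_condition reference (100%) condition name.
#' @param rounding `"table"` or `"exact"` pool rounding mode.
#' @param saturation_tolerance dilution-fit saturation tolerance.
#' @param ratio optional fixed AXIN1:AXIN2 ratio for the pool stage when no
#'   bridging inputs are supplied.
#' @param output_dir directory for stage outputs and the run report.
#' @return list of class `run_config`.
#' @export
run_config <- function(bands = NULL, bridge_design = NULL, folds = NULL,
                       conditions = NULL, reporter = NULL, chx = NULL,
                       recruitment = NULL, reference_condition = "WT",
                       rounding = c("table", "exact"),
                       saturation_tolerance = 0.20, ratio = NULL,
                       output_dir = tempfile("axinpool-run-")) {
  rounding <- match.arg(rounding)
  structure(list(bands = bands, bridge_design = bridge_design,
                 folds = folds, conditions = conditions,
                 reporter = reporter, chx = chx,
                 recruitment = recruitment,
                 reference_condition = reference_condition,
                 rounding = rounding,
                 saturation_tolerance = saturation_tolerance,
                 ratio = ratio, output_dir = output_dir),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the configured stages in order bridging -> pools -> reporter ->
#' decay -> recruitment, writes per-stage outputs (`ratio.json`,
#' `pools.csv`, `pools.json`, `reporter_summary.csv`, `decay.csv`,
#' `recruitment.csv`) under `config$output_dir`, and returns the run report
#' (also written as `report.json`): package version, config echo, stage
#' status, result tables, and QC. Input schema violations abort with
#' file-level diagnostics.
#'
#' @param config a [run_config()].
#' @return the run report, invisibly (list with `version`, `config`,
#'   `stages`, `tables`, `qc`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  paths <- config[c("bands", "bridge_design", "folds", "conditions",
                    "reporter", "chx", "recruitment")]
  diags <- validate_inputs(paths[!vapply(paths, is.null, logical(1))])
  if (length(diags) > 0L) {
    stop_ap("invalid inputs:\n%s", paste("  -", diags, collapse = "\n"))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(); tables <- list(); qc <- list()
  out <- function(f) file.path(config$output_dir, f)

  # -- bridging ---------------------------------------------------------
  ratio <- config$ratio
  if (!is.null(config$bands) && !is.null(config$bridge_design)) {
    bands <- read_bands_csv(config$bands)
    design <- utils::read.csv(config$bridge_design, stringsAsFactors = FALSE)
    exps <- assemble_bridge_experiments(bands, design)
    est <- aggregate_ratio(exps,
                           saturation_tolerance = config$saturation_tolerance)
    jsonlite::write_json(
      list(per_experiment = est$per_experiment, mean = est$mean,
           sem = est$sem, n = est$n,
           qc = list(excluded_saturated = est$qc$excluded_saturated)),
      out("ratio.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ratio <- est$mean
    stages$bridging <- "run"
    tables$ratio <- list(mean = est$mean, sem = est$sem, n = est$n)
    qc$excluded_saturated <- sum(est$qc$excluded_saturated)
  } else {
    stages$bridging <- "skipped"
  }

  # -- pools ------------------------------------------------------------
  if (!is.null(config$folds) && !is.null(config$conditions) &&
      !is.null(ratio)) {
    folds <- read_fold_inputs(config$folds, rounding = config$rounding)
    conditions <- utils::read.csv(config$conditions,
                                  stringsAsFactors = FALSE)
    conditions$axin2_absent <- as.logical(conditions$axin2_absent)
    pools <- build_pool_table(ratio, folds, conditions,
                              reference = config$reference_condition,
                              rounding = config$rounding)
    export_pools(pools, out("pools.csv"), out("pools.json"))
    stages$pools <- "run"
    tables$pools <- as.data.frame(pools)
  } else {
    stages$pools <- "skipped"
  }

  # -- reporter ---------------------------------------------------------
  if (!is.null(config$reporter)) {
    rep_df <- utils::read.csv(config$reporter, stringsAsFactors = FALSE)
    act <- reporter_activities(rep_df)
    summ <- do.call(rbind, lapply(split(act, act$condition), function(g) {
      s <- summarize_replicates(g$activity)
      data.frame(condition = g$condition[1L], mean_activity = s$mean,
                 sem = s$sem, n = s$n, stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
    utils::write.csv(summ, out("reporter_summary.csv"), row.names = FALSE)
    stages$reporter <- "run"
    tables$reporter <- summ
  } else {
    stages$reporter <- "skipped"
  }

  # -- decay ------------------------------------------------------------
  if (!is.null(config$chx)) {
    chx <- utils::read.csv(config$chx, stringsAsFactors = FALSE)
    decay <- do.call(rbind, lapply(split(chx, chx$condition), function(g) {
      g <- g[order(g$time_h), , drop = FALSE]
      fit <- fit_first_order_decay(
        decay_series(g$time_h, g$level_pct, condition = g$condition[1L]))
      data.frame(condition = g$condition[1L], k_per_h = fit$k,
                 half_life_h = fit$half_life_h, decaying = fit$decaying,
                 stringsAsFactors = FALSE)
    }))
    rownames(decay) <- NULL
    utils::write.csv(decay, out("decay.csv"), row.names = FALSE)
    stages$decay <- "run"
    tables$decay <- decay
  } else {
    stages$decay <- "skipped"
  }

  # -- recruitment ------------------------------------------------------
  if (!is.null(config$recruitment)) {
    counts <- utils::read.csv(config$recruitment, stringsAsFactors = FALSE)
    summ <- recruitment_summary(counts)
    utils::write.csv(summ, out("recruitment_summary.csv"), row.names = FALSE)
    stages$recruitment <- "run"
    tables$recruitment <- summ
  } else {
    stages$recruitment <- "skipped"
  }

  report <- list(
    version = as.character(utils::packageVersion("axinpool")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    stages = stages,
    tables = tables,
    qc = qc)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null",
                       pretty = TRUE, force = TRUE)
  invisible(report)
}
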