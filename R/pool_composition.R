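# Pool-composition engine: converts the bridged AXIN1:AXIN2 ratio into the
# percentage split of the combined AXIN1+AXIN2 pool in reference cells, then
# propagates condition-specific fold changes into per-condition pool tables
# (the pie-chart quantities).
#
# Rounding convention ("table" mode): fold changes and percentages are
# rounded to one decimal, half away from zero, BEFORE propagation — e.g.
# 21.9 x 6.2 with 6.2 = round(615.4/100), not 21.9 x 6.154. This is the only
# convention that reproduces the printed pool table cell-for-cell; an
# "exact" mode carries full precision and rounds only on output.

#' Split the combined pool by the AXIN1:AXIN2 ratio
#'
#' For a ratio r of AXIN1 to AXIN2 amounts, the combined pool of 100%
#' contains 100/(1+r) percent AXIN2 and 100*r/(1+r) percent AXIN1.
#'
#' @param ratio_a1_to_a2 positive AXIN1:AXIN2 amount ratio.
#' @param digits decimals for reporting (default 1); use `Inf` for
#'   unrounded fractions.
#' @return named numeric `c(pct_axin1, pct_axin2)` summing to ~100.
#' @examples
#' pool_fractions(3.56)  # 78.1, 21.9
#' @export
pool_fractions <- function(ratio_a1_to_a2, digits = 1) {
  if (!is.finite(ratio_a1_to_a2) || ratio_a1_to_a2 <= 0) {
    stop_ap("ratio must be a positive number")
  }
  a2 <- 100 / (1 + ratio_a1_to_a2)
  a1 <- 100 * ratio_a1_to_a2 / (1 + ratio_a1_to_a2)
  if (is.finite(digits)) {
    a1 <- round_half_up(a1, digits); a2 <- round_half_up(a2, digits)
  }
  c(pct_axin1 = a1, pct_axin2 = a2)
}

#' Fold change of a condition relative to the reference
#'
#' Per-replicate percent levels (reference = 100) are averaged and divided
#' by the reference percent; in `table` rounding the fold is rounded to one
#' decimal before any propagation.
#'
#' @param percent_levels numeric vector of per-replicate percent levels.
#' @param wt_percent reference percent level (default 100).
#' @param analyte,condition labels carried along for reporting.
#' @param rounding `"table"` (one-decimal half-up, the reproduction
#'   convention) or `"exact"`.
#' @return object of class `fold_change` with `value`, `analyte`,
#'   `condition`, `source_percents`.
#' @examples
#' fold_vs_wt(c(161.9, 214.9))  # 1.9
#' @export
fold_vs_wt <- function(percent_levels, wt_percent = 100,
                       analyte = NA_character_, condition = NA_character_,
                       rounding = c("table", "exact")) {
  rounding <- match.arg(rounding)
  if (length(percent_levels) < 1L || any(!is.finite(percent_levels))) {
    stop_ap("fold_vs_wt() needs at least one finite percent level")
  }
  if (!is.finite(wt_percent) || wt_percent <= 0) {
    stop_ap("reference percent must be > 0")
  }
  value <- mean(percent_levels) / wt_percent
  if (rounding == "table") value <- round_half_up(value, 1)
  structure(list(analyte = analyte, condition = condition, value = value,
                 source_percents = as.numeric(percent_levels)),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("fold change %s/%s: %.4g (from %s)\n",
              x$analyte, x$condition, x$value,
              paste(format(x$source_percents), collapse = ", ")))
  invisible(x)
}

#' Scale a base pool percentage by a fold change
#'
#' @param base_pct reference-pool percentage of the component (>= 0).
#' @param fold a [fold_vs_wt()] object or bare positive number.
#' @param rounding `"table"` rounds the product to one decimal.
#' @return scaled percentage.
#' @examples
#' scaled_component(78.1, 1.9)  # 148.4
#' @export
scaled_component <- function(base_pct, fold, rounding = c("table", "exact")) {
  rounding <- match.arg(rounding)
  if (!is.finite(base_pct) || base_pct < 0) stop_ap("base_pct must be >= 0")
  f <- if (inherits(fold, "fold_change")) fold$value else as.numeric(fold)
  if (!is.finite(f) || f < 0) stop_ap("fold must be >= 0")
  out <- base_pct * f
  if (rounding == "table") out <- round_half_up(out, 1)
  out
}

#' Build the per-condition pool table
#'
#' One row per condition: AXIN1 and AXIN2 as percent of the reference
#' combined pool, plus their total. The reference condition is fixed at
#' the split implied by `ratio`; every other condition needs an AXIN1 fold
#' and either an AXIN2 fold or `axin2_absent = TRUE` (knockout lines, where
#' the component is structurally absent rather than measured at fold 0 —
#' keeping missing-fold validation alive for genuinely unspecified
#' conditions).
#'
#' @param ratio AXIN1:AXIN2 amount ratio in the reference condition, as a
#'   positive number or a `ratio_estimate` (its mean is used).
#' @param folds list of [fold_vs_wt()] objects (or a data frame with
#'   columns `condition`, `analyte`, `fold`); analytes `"AXIN1"`/`"AXIN2"`.
#' @param conditions data frame with columns `condition` and logical
#'   `axin2_absent`, in output order. The first row or the row named by
#'   `reference` is the reference condition.
#' @param reference name of the reference condition (default: first row).
#' @param rounding `"table"` (reproduction convention) or `"exact"`.
#' @return data frame of class `pool_table`: `condition`, `pct_axin1`,
#'   `pct_axin2`, `total`, `fold_axin1_vs_wt`, `fold_axin2_vs_wt`.
#' @export
build_pool_table <- function(ratio, folds, conditions,
                             reference = conditions$condition[1L],
                             rounding = c("table", "exact")) {
  rounding <- match.arg(rounding)
  if (inherits(ratio, "ratio_estimate")) ratio <- ratio$mean
  assert_cols(conditions, c("condition", "axin2_absent"), "condition spec")
  if (!reference %in% conditions$condition) {
    stop_ap("reference condition '%s' is not in the condition spec", reference)
  }
  fold_df <- normalize_folds(folds, rounding)
  base <- pool_fractions(ratio,
                         digits = if (rounding == "table") 1 else Inf)
  lookup <- function(cond, analyte) {
    hit <- fold_df$fold[fold_df$condition == cond & fold_df$analyte == analyte]
    if (length(hit) == 0L) return(NULL)
    if (length(hit) > 1L) {
      stop_ap("multiple %s folds declared for condition '%s'", analyte, cond)
    }
    hit
  }
  rows <- lapply(seq_len(nrow(conditions)), function(i) {
    cond <- conditions$condition[i]
    absent2 <- isTRUE(conditions$axin2_absent[i])
    if (cond == reference) {
      return(data.frame(condition = cond,
                        pct_axin1 = base[["pct_axin1"]],
                        pct_axin2 = base[["pct_axin2"]],
                        total = base[["pct_axin1"]] + base[["pct_axin2"]],
                        fold_axin1_vs_wt = NA_real_,
                        fold_axin2_vs_wt = NA_real_,
                        stringsAsFactors = FALSE))
    }
    f1 <- lookup(cond, "AXIN1")
    if (is.null(f1)) stop_ap("no AXIN1 fold declared for condition '%s'", cond)
    p1 <- scaled_component(base[["pct_axin1"]], f1, rounding)
    if (absent2) {
      f2 <- NA_real_; p2 <- 0
    } else {
      f2 <- lookup(cond, "AXIN2")
      if (is.null(f2)) stop_ap("no AXIN2 fold declared for condition '%s'", cond)
      p2 <- scaled_component(base[["pct_axin2"]], f2, rounding)
    }
    data.frame(condition = cond, pct_axin1 = p1, pct_axin2 = p2,
               total = p1 + p2, fold_axin1_vs_wt = f1,
               fold_axin2_vs_wt = if (absent2) NA_real_ else f2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("pool_table", class(out))
  out
}

# Accepts a list of fold_change objects or a data frame (condition, analyte,
# fold) and returns a plain data frame; table-mode rounding is applied to
# bare numeric folds for consistency with fold_vs_wt().
normalize_folds <- function(folds, rounding) {
  if (is.data.frame(folds)) {
    assert_cols(folds, c("condition", "analyte", "fold"), "fold table")
    df <- folds[, c("condition", "analyte", "fold")]
  } else {
    if (!length(folds)) stop_ap("no fold changes supplied")
    df <- do.call(rbind, lapply(folds, function(f) {
      stopifnot(inherits(f, "fold_change"))
      data.frame(condition = f$condition, analyte = f$analyte,
                 fold = f$value, stringsAsFactors = FALSE)
    }))
  }
  if (any(!is.finite(df$fold) | df$fold < 0)) {
    stop_ap("fold changes must be finite and >= 0")
  }
  if (rounding == "table") df$fold <- round_half_up(df$fold, 1)
  df
}

#' Write a pool table to CSV and chart-ready JSON
#'
#' The JSON mirrors the pie-chart inputs: per condition the component
#' percentages (slice values), the total (chart size) and the folds that
#' produced them.
#'
#' @param entries a [build_pool_table()] result.
#' @param csv_path,json_path output paths; either may be `NULL` to skip.
#' @return `entries`, invisibly.
#' @export
export_pools <- function(entries, csv_path = NULL, json_path = NULL) {
  if (nrow(entries) < 1L) stop_ap("pool table is empty")
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(entries), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    chart <- lapply(seq_len(nrow(entries)), function(i) {
      e <- entries[i, ]
      list(condition = e$condition,
           components = list(AXIN1 = e$pct_axin1, AXIN2 = e$pct_axin2),
           total = e$total,
           folds = list(AXIN1 = e$fold_axin1_vs_wt,
                        AXIN2 = e$fold_axin2_vs_wt))
    })
    jsonlite::write_json(chart, json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null", pretty = TRUE)
  }
  invisible(entries)
}

#' Read a pool table back from CSV
#'
#' @param csv_path path written by [export_pools()].
#' @return data frame with the pool-table columns.
#' @export
read_pools <- function(csv_path) {
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  assert_cols(df, c("condition", "pct_axin1", "pct_axin2", "total"),
              "pool CSV")
  df
}

#' Read a fold-input table (source percent levels per condition/analyte)
#'
#' Schema: one row per replicate-mean percent level, columns `condition`,
#' `analyte`, `percent`. Multiple rows for one (condition, analyte) are
#' averaged by [fold_vs_wt()].
#'
#' @param csv_path CSV path.
#' @param rounding passed to [fold_vs_wt()].
#' @return list of `fold_change` objects.
#' @export
read_fold_inputs <- function(csv_path, rounding = c("table", "exact")) {
  rounding <- match.arg(rounding)
  df <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  assert_cols(df, c("condition", "analyte", "percent"), "fold-input CSV")
  keys <- unique(df[, c("condition", "analyte")])
  lapply(seq_len(nrow(keys)), function(i) {
    sel <- df$condition == keys$condition[i] & df$analyte == keys$analyte[i]
    fold_vs_wt(df$percent[sel], analyte = keys$analyte[i],
               condition = keys$condition[i], rounding = rounding)
  })
}
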