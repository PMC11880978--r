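# Auxiliary assay quantifications: TOP/FOP dual-reporter normalization,
# cycloheximide-chase decay kinetics, and recruitment-fraction statistics.

#' Beta-catenin-dependent transcription from a TOP/FOP reporter pair
#'
#' Each luciferase readout is first normalized to its same-well
#' beta-galactosidase activity (transfection control); the TOP/FOP ratio of
#' the normalized activities reports beta-catenin-dependent transcription.
#' FOP is matched per replicate (same day, parallel wells).
#'
#' @param top_luc,top_bgal TOP-well luciferase and beta-galactosidase.
#' @param fop_luc,fop_bgal matched FOP-well readouts.
#' @return normalized TOP/FOP activity, (top_luc/top_bgal)/(fop_luc/fop_bgal).
#' @examples
#' top_fop_activity(100, 1, 50, 1)  # 2
#' @export
top_fop_activity <- function(top_luc, top_bgal, fop_luc, fop_bgal) {
  vals <- c(top_luc, top_bgal, fop_luc, fop_bgal)
  if (any(!is.finite(vals)) || top_luc < 0 || fop_luc < 0) {
    stop_ap("reporter readouts must be finite and luciferase >= 0")
  }
  if (top_bgal <= 0 || fop_bgal <= 0) {
    stop_ap("beta-galactosidase readouts must be > 0")
  }
  if (fop_luc == 0) {
    stop_ap("FOP luciferase is zero; the TOP/FOP ratio is undefined")
  }
  (top_luc / top_bgal) / (fop_luc / fop_bgal)
}

#' Summarize TOP/FOP activities for a replicate table
#'
#' @param reporter data frame with columns `replicate_id`, `condition`,
#'   `top_luc`, `top_bgal`, `fop_luc`, `fop_bgal`.
#' @return data frame with per-replicate `activity` per condition.
#' @export
reporter_activities <- function(reporter) {
  assert_cols(reporter, c("replicate_id", "condition", "top_luc", "top_bgal",
                          "fop_luc", "fop_bgal"), "reporter table")
  reporter$activity <- mapply(top_fop_activity, reporter$top_luc,
                              reporter$top_bgal, reporter$fop_luc,
                              reporter$fop_bgal)
  reporter[, c("replicate_id", "condition", "activity")]
}

#' Construct a cycloheximide decay series
#'
#' Loading-normalized protein levels as percent of the pre-treatment level,
#' measured at increasing times after blocking translation. The series must
#' start at t = 0 with level 100 (the normalization anchor).
#'
#' @param timepoints hours since translation block, strictly increasing,
#'   starting at 0.
#' @param levels percent of the t = 0 level; `levels[1]` must be 100.
#' @param condition label carried along.
#' @return object of class `decay_series`.
#' @export
decay_series <- function(timepoints, levels, condition = NA_character_) {
  timepoints <- as.numeric(timepoints); levels <- as.numeric(levels)
  if (length(timepoints) != length(levels)) {
    stop_ap("timepoints and levels must have equal length")
  }
  if (any(timepoints < 0) || any(diff(timepoints) <= 0)) {
    stop_ap("timepoints must be non-negative and strictly increasing")
  }
  if (timepoints[1L] != 0 || abs(levels[1L] - 100) > 1e-9) {
    stop_ap("a decay series starts at t = 0 with level 100")
  }
  if (any(levels < 0)) stop_ap("levels must be >= 0")
  structure(list(condition = condition, timepoints = timepoints,
                 levels = levels), class = "decay_series")
}

#' Fit first-order decay to a cycloheximide chase
#'
#' Ordinary least squares of log(level) on time with a free intercept;
#' the decay rate is k = -slope (per hour) and the half-life ln(2)/k.
#' With the two or three timepoints a chase affords, log-linear OLS is the
#' model the data can support — no extra parameters, deterministic fit.
#' Series that do not decay (k <= 0) are flagged and report an infinite
#' half-life.
#'
#' @param series a [decay_series()] (or list with `timepoints`, `levels`).
#' @return object of class `decay_fit`: `k` (per hour), `half_life_h`,
#'   `decaying` (logical), and `fraction_at(t)` giving exp(-k t).
#' @examples
#' fit_first_order_decay(decay_series(c(0, 8), c(100, 50)))$half_life_h  # 8
#' @export
fit_first_order_decay <- function(series) {
  t <- as.numeric(series$timepoints)
  y <- as.numeric(series$levels)
  if (any(y <= 0)) {
    stop_ap("all levels must be > 0 to fit log-linear decay (zero level at t = %g h)",
            t[which(y <= 0)[1L]])
  }
  if (length(t) < 2L) stop_ap("need at least two timepoints to fit decay")
  fit <- stats::lm(log(y) ~ t)
  k <- -unname(stats::coef(fit)[2L])
  # slopes below numerical noise are flat series, not slow decay
  decaying <- is.finite(k) && k > sqrt(.Machine$double.eps)
  structure(list(
    k = k,
    half_life_h = if (decaying) log(2) / k else Inf,
    decaying = decaying,
    fraction_at = function(tt) exp(-k * tt)
  ), class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  if (x$decaying) {
    cat(sprintf("first-order decay: k = %.4g / h, half-life %.3g h\n",
                x$k, x$half_life_h))
  } else {
    cat(sprintf("non-decaying series (k = %.4g / h)\n", x$k))
  }
  invisible(x)
}

#' Summarize recruitment fractions across experiments
#'
#' For condensate-recruitment scoring, the independent experiment — not the
#' cell — is the replication unit: each experiment contributes one
#' percentage 100 * n_recruited / n_total, and the summary is the mean +/-
#' SEM of those percentages.
#'
#' @param counts data frame with columns `experiment_id`, `setup`,
#'   `n_recruited`, `n_total` (one row per experiment).
#' @return data frame with one row per setup: `setup`, `mean_pct`,
#'   `sem_pct`, `n_experiments`, `n_cells`.
#' @export
recruitment_summary <- function(counts) {
  assert_cols(counts, c("experiment_id", "setup", "n_recruited", "n_total"),
              "recruitment counts")
  if (nrow(counts) < 1L) stop_ap("no recruitment counts supplied")
  if (any(counts$n_total < 1L)) stop_ap("n_total must be >= 1")
  if (any(counts$n_recruited < 0L | counts$n_recruited > counts$n_total)) {
    stop_ap("n_recruited must lie in [0, n_total]")
  }
  counts$pct <- 100 * counts$n_recruited / counts$n_total
  out <- do.call(rbind, lapply(split(counts, counts$setup), function(g) {
    s <- summarize_replicates(g$pct)
    data.frame(setup = g$setup[1L], mean_pct = s$mean, sem_pct = s$sem,
               n_experiments = s$n, n_cells = sum(g$n_total),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Compare recruitment between two setups
#'
#' Unpaired two-tailed Student's t-test on the per-experiment percentages.
#'
#' @param counts recruitment-count data frame (see [recruitment_summary()]).
#' @param setup_a,setup_b the two setups to compare.
#' @return a `significance_call` (see [student_t_test()]).
#' @export
recruitment_test <- function(counts, setup_a, setup_b) {
  counts$pct <- 100 * counts$n_recruited / counts$n_total
  a <- counts$pct[counts$setup == setup_a]
  b <- counts$pct[counts$setup == setup_b]
  if (!length(a) || !length(b)) {
    stop_ap("setup '%s' or '%s' not found in recruitment counts",
            setup_a, setup_b)
  }
  student_t_test(a, b, paired = FALSE)
}
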