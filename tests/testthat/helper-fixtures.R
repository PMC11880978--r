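# Shared builders for synthetic test inputs.

# A noise-free pairwise comparison whose two dilution responses have the
# given slopes (slope = affinity x abundance), over the standard series.
comp_with_slopes <- function(slope_a, slope_b, antibody = "ab",
                             analyte_a = "A", analyte_b = "B",
                             dilutions = c(0.1, 0.5, 1.0)) {
  lanes <- function(s) data.frame(dilution = dilutions,
                                  intensity = s * dilutions)
  pairwise_comparison(antibody, analyte_a, analyte_b,
                      lanes(slope_a), lanes(slope_b))
}

# A noise-free bridge experiment with known endogenous amounts, arbitrary
# antibody affinities and arbitrary GFP-construct amounts. The chained
# ratio must equal endo_a1 / endo_a2 regardless of affinities/constructs.
noise_free_bridge <- function(endo_a1, endo_a2, gfp1 = 7, gfp2 = 13,
                              aff = c(a1 = 5, gfp = 0.2, a2 = 11),
                              experiment_id = "exp") {
  bridge_experiment(
    experiment_id,
    comp_with_slopes(aff[["a1"]] * endo_a1, aff[["a1"]] * gfp1,
                     "anti-AXIN1", "AXIN1", "GFP-AXIN1"),
    comp_with_slopes(aff[["gfp"]] * gfp1, aff[["gfp"]] * gfp2,
                     "anti-GFP", "GFP-AXIN1", "GFP-AXIN2"),
    comp_with_slopes(aff[["a2"]] * gfp2, aff[["a2"]] * endo_a2,
                     "anti-AXIN2", "GFP-AXIN2", "AXIN2"))
}

# Independent textbook oracle for the two-tailed pooled-variance Student's
# t-test p-value (kept free of stats::t.test on purpose).
pooled_t_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  tstat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tstat), df = n1 + n2 - 2)
}

# Independent textbook oracle for the paired two-tailed t p-value.
paired_t_p <- function(a, b) {
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(length(d)))
  2 * pt(-abs(tstat), df = length(d) - 1)
}

# Write a complete set of pipeline input CSVs to `dir`; returns the paths.
write_pipeline_inputs <- function(dir, seed = 1L, noise_sigma = 0) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  tr <- bridge_truth(3.56, noise_sigma = noise_sigma,
                     lane_loading_cv = if (noise_sigma == 0) 0 else 0.1,
                     seed = seed)
  tabs <- bridge_study_tables(simulate_bridge_study(3.56, 6, tr))
  write.csv(tabs$bands, p("bands.csv"), row.names = FALSE)
  write.csv(tabs$design, p("bridge_design.csv"), row.names = FALSE)
  fx <- table1_fixture()
  file.copy(fx$folds, p("folds.csv"))
  file.copy(fx$conditions, p("conditions.csv"))
  write.csv(simulate_reporter(c(WT = 1, `AXIN2-/-` = 1.5), sigma = 0,
                              seed = seed),
            p("reporter.csv"), row.names = FALSE)
  chase <- simulate_chx(log(2) / 8, c(0, 4, 8), sigma = 0, seed = seed)
  write.csv(data.frame(condition = "WT", time_h = chase$timepoints,
                       level_pct = chase$levels),
            p("chx.csv"), row.names = FALSE)
  write.csv(simulate_recruitment(0.9, 88, 4, seed = seed, setup = "WT"),
            p("recruitment.csv"), row.names = FALSE)
  list(bands = p("bands.csv"), bridge_design = p("bridge_design.csv"),
       folds = p("folds.csv"), conditions = p("conditions.csv"),
       reporter = p("reporter.csv"), chx = p("chx.csv"),
       recruitment = p("recruitment.csv"))
}

# Paths to the packaged published-table fixture.
table1_fixture <- function() {
  list(folds = system.file("extdata", "table1_folds.csv",
                           package = "axinpool"),
       conditions = system.file("extdata", "table1_conditions.csv",
                                package = "axinpool"))
}

# The published pool table (condition, AXIN2 %, AXIN1 %, total), used to
# check full reproduction.
published_pool_table <- function() {
  data.frame(
    condition = c("SW480", "AXIN2-/-", "siAXIN2", "+/+ #1 ut",
                  "+/+ #1 G007-LK", "+/+ #2 ut", "+/+ #2 G007-LK",
                  "AXIN2-/- #1 ut", "AXIN2-/- #1 G007-LK",
                  "AXIN2-/- #2 ut", "AXIN2-/- #2 G007-LK"),
    pct_axin2 = c(21.9, 0, 6.6, 21.9, 135.8, 30.7, 295.7, 0, 0, 0, 0),
    pct_axin1 = c(78.1, 148.4, 125.0, 78.1, 148.4, 54.7, 140.6, 140.6,
                  156.2, 179.6, 171.8),
    total = c(100, 148.4, 131.6, 100, 284.2, 85.4, 436.3, 140.6, 156.2,
              179.6, 171.8),
    stringsAsFactors = FALSE)
}
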