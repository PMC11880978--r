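test_that("loading-control normalization divides intensity by loading band", {
  rec <- band_records("e1", "b1", 1:3, "WT", "AXIN1", "anti-AXIN1", 1,
                      intensity = c(200, 0, 161.9),
                      loading_intensity = c(100, 50, 100))
  lev <- normalize_to_loading(rec)
  expect_equal(lev$value, c(2.0, 0.0, 1.619))
  expect_equal(lev$condition, rep("WT", 3))
})

test_that("normalization refuses missing or zero loading controls, naming the lane", {
  rec <- band_records("e1", "blotX", 4, "WT", "AXIN1", "ab", 1, 10, NA)
  expect_error(normalize_to_loading(rec), "blotX.*lane 4")
})

test_that("normalization is invariant to rescaling a whole lane", {
  set.seed(42)
  for (i in 1:10) {
    int <- runif(1, 1, 500); load <- runif(1, 1, 200); c0 <- runif(1, 0.1, 50)
    a <- normalize_to_loading(
      band_records("e", "b", 1, "WT", "A", "ab", 1, int, load))
    b <- normalize_to_loading(
      band_records("e", "b", 1, "WT", "A", "ab", 1, c0 * int, c0 * load))
    expect_equal(a$value, b$value)
  }
})

test_that("band-record invariants are enforced", {
  expect_error(band_records("e", "b", 1, "WT", "A", "ab", 1.5, 10, 5),
               "dilution")
  expect_error(band_records("e", "b", 1, "WT", "A", "ab", 1, -1, 5),
               "intensit")
  expect_error(band_records("e", "b", c(1, 1), "WT", "A", "ab", 1,
                            c(1, 2), c(5, 5)),
               "duplicate")
})

test_that("relative levels set the reference to exactly 100 per replicate", {
  lev <- data.frame(condition = rep(c("ref", "cond"), 2),
                    analyte = "A",
                    replicate_id = rep(c("r1", "r2"), each = 2),
                    value = c(2.0, 3.0, 2.0, 2.0))
  rel <- relative_to_reference(lev, "ref")
  expect_identical(rel$percent_of_reference[rel$condition == "ref"],
                   c(100, 100))
  expect_equal(rel$percent_of_reference[rel$condition == "cond"],
               c(150, 100))
})

test_that("relative_to_reference is idempotent when the reference is reused", {
  set.seed(7)
  lev <- data.frame(condition = rep(c("ref", "a", "b"), 3),
                    analyte = "A",
                    replicate_id = rep(c("r1", "r2", "r3"), each = 3),
                    value = runif(9, 0.5, 5))
  r1 <- relative_to_reference(lev, "ref")
  again <- r1
  names(again)[names(again) == "percent_of_reference"] <- "value"
  r2 <- relative_to_reference(again, "ref")
  expect_equal(r2$percent_of_reference, r1$percent_of_reference)
})

test_that("a missing reference names the offending replicate", {
  lev <- data.frame(condition = c("ref", "cond", "cond"),
                    analyte = "A",
                    replicate_id = c("r1", "r1", "r2"),
                    value = c(1, 2, 3))
  expect_error(relative_to_reference(lev, "ref"), "r2")
})

test_that("replicate summaries use the n-1 SEM and define SEM 0 for n = 1", {
  s <- summarize_replicates(c(2, 2, 2, 2))
  expect_equal(c(s$mean, s$sem, s$n), c(2, 0, 4))
  s <- summarize_replicates(c(1, 3))
  expect_equal(c(s$mean, s$sem), c(2, 1))   # sd = sqrt(2), sem = 1
  s <- summarize_replicates(161.9)
  expect_equal(c(s$mean, s$sem, s$n), c(161.9, 0, 1))
  for (k in 1:5) {
    expect_equal(summarize_replicates(rep(3.7, k))$sem, 0)
  }
  expect_error(summarize_replicates(numeric(0)), "at least one")
})

test_that("significance stars follow the publication thresholds at the boundaries", {
  expect_identical(significance_stars(0.0009), "***")
  expect_identical(significance_stars(0.001), "**")
  expect_identical(significance_stars(0.009), "**")
  expect_identical(significance_stars(0.01), "*")
  expect_identical(significance_stars(0.049), "*")
  expect_identical(significance_stars(0.05), "ns")
  expect_identical(significance_stars(0.9), "ns")
})

test_that("t-test handles degenerate, separated and symmetric inputs", {
  r <- student_t_test(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(r$p_value, 1.0)
  expect_identical(r$stars, "ns")

  set.seed(11)
  r <- student_t_test(c(0, 0, 0, 0), 10 + rnorm(4, 0, 1e-6), paired = FALSE)
  expect_lt(r$p_value, 0.001)
  expect_identical(r$stars, "***")

  a <- rnorm(5); b <- rnorm(5, 1)
  expect_equal(student_t_test(a, b)$p_value, student_t_test(b, a)$p_value)

  expect_error(student_t_test(1, c(1, 2)), "at least two")
  expect_error(student_t_test(c(1, 2, 3), c(1, 2), paired = TRUE), "equal")
})

test_that("t-test p-values match the textbook formulas to 1e-10", {
  set.seed(123)
  for (i in 1:20) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    a <- rnorm(n1, mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    b <- rnorm(n2, mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    expect_equal(student_t_test(a, b)$p_value, pooled_t_p(a, b),
                 tolerance = 1e-10)
    ap <- rnorm(n1); bp <- rnorm(n1)
    expect_equal(student_t_test(ap, bp, paired = TRUE)$p_value,
                 paired_t_p(ap, bp), tolerance = 1e-10)
  }
})

test_that("Welch mode is available for unpaired tests", {
  set.seed(5)
  a <- rnorm(6, 0, 0.2); b <- rnorm(12, 1, 3)
  pw <- student_t_test(a, b, welch = TRUE)$p_value
  expect_equal(pw, t.test(a, b)$p.value)
  expect_false(isTRUE(all.equal(pw, student_t_test(a, b)$p_value)))
})
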