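test_that("half-up rounding matches the printed-table convention", {
  expect_equal(round_half_up(0.05), 0.1)
  expect_equal(round_half_up(21.9 * 13.5), 295.7)  # binary rep sits below the tie
  expect_equal(round_half_up(1.25, 1), 1.3)
  expect_equal(round_half_up(-0.05), -0.1)
  expect_equal(round_half_up(2.04), 2.0)
})

test_that("pool fractions split 100% by the AXIN1:AXIN2 ratio", {
  expect_equal(unname(pool_fractions(3.56)), c(78.1, 21.9))
  expect_equal(unname(pool_fractions(1.0)), c(50, 50))
  expect_equal(unname(pool_fractions(9.0)), c(90, 10))
  expect_error(pool_fractions(0), "positive")
  expect_error(pool_fractions(-2), "positive")
})

test_that("reported pool fractions sum to 100 within one rounding step", {
  set.seed(31)
  for (r in exp(runif(50, log(0.1), log(10)))) {
    fr <- pool_fractions(r)
    expect_lte(abs(sum(fr) - 100), 0.1)
    # fractions -> ratio -> fractions is the identity
    expect_equal(pool_fractions(fr[["pct_axin1"]] / fr[["pct_axin2"]]), fr)
  }
})

test_that("fold changes average replicate percents and round once", {
  expect_equal(fold_vs_wt(c(161.9, 214.9))$value, 1.9)
  expect_equal(fold_vs_wt(100.0)$value, 1.0)
  expect_equal(fold_vs_wt(615.4)$value, 6.2)
  expect_equal(fold_vs_wt(615.4, rounding = "exact")$value, 6.154)
  expect_error(fold_vs_wt(150, wt_percent = 0), "> 0")
})

test_that("scaled components reproduce the printed products", {
  expect_equal(scaled_component(78.1, 1.9), 148.4)
  expect_equal(scaled_component(21.9, 0.3), 6.6)
  set.seed(8)
  for (x in runif(10, 0, 300)) {
    expect_equal(scaled_component(x, 1.0),
                 round_half_up(x, 1))  # identity fold
  }
})

test_that("the full published pool table is reproduced cell-for-cell", {
  fx <- table1_fixture()
  folds <- read_fold_inputs(fx$folds)
  conds <- read.csv(fx$conditions, stringsAsFactors = FALSE)
  pt <- build_pool_table(3.56, folds, conds, reference = "SW480")
  pub <- published_pool_table()
  expect_equal(pt$condition, pub$condition)
  expect_equal(pt$pct_axin1, pub$pct_axin1)
  expect_equal(pt$pct_axin2, pub$pct_axin2)
  expect_equal(pt$total, pub$total)
})

test_that("knockout rows carry a structurally absent AXIN2 component", {
  conds <- data.frame(condition = c("WT", "KO"), axin2_absent = c(FALSE, TRUE))
  folds <- data.frame(condition = "KO", analyte = "AXIN1", fold = 1.9)
  pt <- build_pool_table(3.56, folds, conds)
  expect_equal(pt$pct_axin2[2], 0)
  expect_equal(pt$pct_axin1[2], 148.4)
  expect_equal(pt$total[2], 148.4)
  expect_true(is.na(pt$fold_axin2_vs_wt[2]))
})

test_that("a genuinely missing fold errors naming the condition", {
  conds <- data.frame(condition = c("WT", "treated"),
                      axin2_absent = c(FALSE, FALSE))
  folds <- data.frame(condition = "treated", analyte = "AXIN1", fold = 1.5)
  expect_error(build_pool_table(3.56, folds, conds), "AXIN2.*treated")
  expect_error(build_pool_table(3.56, folds[0, ], conds), "AXIN1.*treated")
})

test_that("all-unity folds reproduce the reference entry everywhere", {
  conds <- data.frame(condition = c("WT", "c1", "c2"),
                      axin2_absent = FALSE)
  folds <- expand.grid(condition = c("c1", "c2"),
                       analyte = c("AXIN1", "AXIN2"),
                       stringsAsFactors = FALSE)
  folds$fold <- 1.0
  pt <- build_pool_table(3.56, folds, conds)
  expect_true(all(pt$pct_axin1 == 78.1))
  expect_true(all(pt$pct_axin2 == 21.9))
  expect_true(all(pt$total == 100))
})

test_that("totals are componentwise sums and folds act monotonically", {
  conds <- data.frame(condition = c("WT", "x"), axin2_absent = FALSE)
  set.seed(13)
  for (i in 1:20) {
    f1 <- round_half_up(runif(1, 0.1, 14), 1)
    f2 <- round_half_up(runif(1, 0.1, 14), 1)
    folds <- data.frame(condition = "x", analyte = c("AXIN1", "AXIN2"),
                        fold = c(f1, f2))
    pt <- build_pool_table(3.56, folds, conds)
    expect_equal(pt$total, pt$pct_axin1 + pt$pct_axin2)
    bigger <- folds; bigger$fold[1] <- f1 + 0.5
    pt2 <- build_pool_table(3.56, bigger, conds)
    expect_gt(pt2$pct_axin1[2], pt$pct_axin1[2])
    expect_gt(pt2$total[2], pt$total[2])
  }
})

test_that("exact mode carries full precision through the propagation", {
  conds <- data.frame(condition = c("WT", "x"), axin2_absent = c(FALSE, TRUE))
  folds <- data.frame(condition = "x", analyte = "AXIN1", fold = 1.88)
  pt <- build_pool_table(3.56, folds, conds, rounding = "exact")
  expect_equal(pt$pct_axin1[2], 100 * 3.56 / 4.56 * 1.88, tolerance = 1e-12)
  # table mode rounds the fold to 1.9 first
  ptt <- build_pool_table(3.56, folds, conds, rounding = "table")
  expect_equal(ptt$pct_axin1[2], 148.4)
})

test_that("pool export round-trips through CSV and emits chart JSON", {
  fx <- table1_fixture()
  pt <- build_pool_table(3.56, read_fold_inputs(fx$folds),
                         read.csv(fx$conditions), reference = "SW480")
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  export_pools(pt, csv, js)
  back <- read_pools(csv)
  expect_equal(nrow(back), 11L)  # one row per published condition
  expect_equal(back$total, pt$total)
  expect_equal(back$pct_axin1, pt$pct_axin1)
  chart <- jsonlite::read_json(js)
  expect_length(chart, 11L)
  expect_equal(chart[[2]]$components$AXIN1, 148.4)
  unlink(c(csv, js))
})
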