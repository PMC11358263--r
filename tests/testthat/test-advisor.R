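toy_window <- function() {
  s <- make_series(1:5, 3, 3, c(NA, 9, 9, 9, 9))
  build_windows(s, 3, train_pk()$features)[[3]]  # targets day 5
}

test_that("dose sweep with toy predictors solves the target inequality on the grid", {
  w <- toy_window()
  half <- function(win) 0.5 * win$dynamic[nrow(win$dynamic), "dose_am"]
  sug <- suggest_doses(half, w)
  expect_equal(sug, seq(16, 20, by = 0.5))
  flat <- function(win) 5
  expect_length(suggest_doses(flat, w), 0)
})

test_that("PK-family suggestions re-predict inside the target and are contiguous", {
  set.seed(71)
  m <- train_pk()
  co <- simulate_cohort(generator_config(12, seed = 111, missing_rate_labs = 0))
  w <- cohort_windows(co, 3, m$features)
  checked <- 0L
  for (win in sample(w, 40)) {
    sug <- suggest_doses(m, win)
    if (length(sug) == 0L) next
    checked <- checked + 1L
    re <- vapply(sug, function(d) {
      v <- win
      v$dynamic[nrow(v$dynamic), c("dose_am", "dose_pm")] <- d
      predict_next(m, v)
    }, numeric(1))
    expect_true(all(re >= 8 & re <= 10))
    ## monotone-in-dose predictor: suggestions form a contiguous grid run
    expect_equal(sug, seq(min(sug), max(sug), by = 0.5))
  }
  expect_gt(checked, 5)
})

test_that("case classification uses range semantics and target inclusivity", {
  set5to7 <- seq(5, 7, 0.5)
  expect_equal(classify_case(4.0, set5to7, 6.2), list(row = "under", col = "under"))
  expect_equal(classify_case(6.0, set5to7, 9.0), list(row = "within", col = "within"))
  expect_equal(classify_case(8.0, set5to7, 11.0), list(row = "over", col = "over"))
  ## inclusive bounds on both the dose range and the target range
  expect_equal(classify_case(5.0, set5to7, 8.0)$row, "within")
  expect_equal(classify_case(5.0, set5to7, 8.0)$col, "within")
  expect_equal(classify_case(7.0, set5to7, 10.0), list(row = "within", col = "within"))
  expect_null(classify_case(5, numeric(0), 9))
})

test_that("contingency table counts, percentages and exclusion bookkeeping", {
  cases <- list(list(row = "under", col = "under"), NULL,
                list(row = "within", col = "within"))
  tab <- build_contingency(cases)
  expect_equal(sum(unclass(tab)), 2)
  expect_equal(attr(tab, "n_excluded"), 1)
  expect_equal(unclass(tab)["dose_under", "conc_under"], 1L)

  one <- build_contingency(list(list(row = "over", col = "over")))
  expect_equal(sum(unclass(one) == 0), 8)

  ## percentages sum to ~100 after integer rounding
  set.seed(14)
  rc <- c("under", "within", "over")
  rnd <- lapply(1:200, function(i) list(row = sample(rc, 1), col = sample(rc, 1)))
  tab2 <- build_contingency(rnd)
  expect_lte(abs(sum(attr(tab2, "percent")) - 100), 2)
})

test_that("chi-square test: independence, naive oracle, zero margins", {
  flat <- matrix(10, 2, 2)
  res <- chi_square_test(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(3)
  for (i in 1:20) {
    m <- matrix(rpois(9, 30) + 1, 3, 3)
    res <- chi_square_test(m)
    expect_equal(res$statistic, naive_chisq(m), tolerance = 1e-10)
    expect_equal(res$df, 4)
  }
  withzero <- rbind(c(10, 5), c(0, 0), c(3, 8))
  expect_warning(res0 <- chi_square_test(withzero), "zero-margin")
  expect_equal(res0$df, 1)
})

test_that("outcome flags: exceedance, IPV, and the creatinine AKI criteria", {
  calm <- make_series(1:5, 3, 3, c(NA, 8.5, 8.5, 8.5, 8.5))
  f <- outcome_flags(calm)
  expect_false(f$exceeded_target)
  expect_false(f$high_ipv)

  volatile <- make_series(1:4, 3, 3, c(NA, 5, 9, 13))
  f2 <- outcome_flags(volatile)
  expect_true(f2$high_ipv)     # SD of {5,9,13} = 4 > 2
  expect_true(f2$exceeded_target)

  ## creatinine 1.0 -> 1.4 within 48 h: absolute-rise criterion fires
  aki1 <- make_series(1:3, 3, 3, c(NA, 9, 9), creatinine = c(1.0, 1.4, 1.2))
  expect_true(outcome_flags(aki1)$aki)
  ## slow ratio rise to >= 1.5x baseline inside 7 days
  aki2 <- make_series(1:8, 3, 3, 9,
                      creatinine = c(1.0, 1.1, 1.2, 1.3, 1.4, 1.5, 1.55, 1.6))
  expect_true(outcome_flags(aki2)$aki)
  stable <- make_series(1:5, 3, 3, 9, creatinine = c(1.0, 1.1, 1.0, 1.1, 1.0))
  expect_false(outcome_flags(stable)$aki)
  ## all creatinine missing: undetermined, not FALSE
  nocr <- make_series(1:5, 3, 3, 9, creatinine = NA_real_)
  expect_true(is.na(outcome_flags(nocr)$aki))
  ## fewer than 2 troughs: IPV undetermined
  onetr <- make_series(1:2, 3, 3, c(NA, 9))
  expect_true(is.na(outcome_flags(onetr)$high_ipv))
})

test_that("flag-outcome association: extremes and orientation invariance", {
  expo <- rep(c(TRUE, FALSE), each = 20)
  res <- outcome_association(expo, expo)
  expect_lt(res$p_value, 0.001)

  set.seed(909)
  e2 <- runif(1000) < 0.5
  o2 <- runif(1000) < 0.3
  res_null <- outcome_association(e2, o2)
  expect_gt(res_null$p_value, 0.001)
  ## swapping rows and columns leaves the statistic unchanged
  res_sw <- outcome_association(o2, e2)
  expect_equal(res_sw$statistic, res_null$statistic, tolerance = 1e-12)
})

test_that("stay comparison routes by normality and handles degenerate groups", {
  same <- rep(5, 10)
  res <- stay_comparison(same, same)
  expect_gt(res$p_value, 0.9)

  res2 <- stay_comparison(1:10, 11:20)
  expect_lt(res2$p_value, 0.01)

  set.seed(33)
  normal_a <- rnorm(40, 8, 2); normal_b <- rnorm(40, 8.5, 2)
  expect_equal(stay_comparison(normal_a, normal_b)$test, "welch")
  heavy <- exp(rnorm(40, 1, 1.5))
  expect_equal(stay_comparison(heavy, normal_b)$test, "mann-whitney")
  expect_error(stay_comparison(1, 1:5), ">= 2")
})
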