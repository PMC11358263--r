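## Shared fixtures and independent oracles, built in code.

## small noise-free cohort: deterministic troughs equal the PK closed form
noise_free_config <- function(n = 3, seed = 11, horizon = 10) {
  generator_config(n, horizon_days = horizon, seed = seed,
                   iiv_cv = 0, residual_cv = 0, missing_rate_labs = 0)
}

small_cohort <- function(n = 12, seed = 21, ...) {
  simulate_cohort(generator_config(n, seed = seed, ...))
}

## hand-built series with full control over every cell
make_series <- function(days, dose_am, dose_pm, trough,
                        ast = 100, albumin = 3.2, hematocrit = 32,
                        creatinine = 1.0, weight = 65, id = "p1") {
  H <- length(days)
  rep_len2 <- function(x) rep_len(x, H)
  structure(list(
    patient_id = id, age = 55, sex = 1L, height_cm = 165,
    iiv = c(cl = 1, v = 1),
    daily = data.frame(day = days, dose_am = rep_len2(dose_am),
                       dose_pm = rep_len2(dose_pm), trough = rep_len2(trough),
                       weight = rep_len2(weight), ast = rep_len2(ast),
                       alt = rep_len2(80), tbil = rep_len2(2),
                       inr = rep_len2(1.3), albumin = rep_len2(albumin),
                       creatinine = rep_len2(creatinine),
                       hematocrit = rep_len2(hematocrit))),
    class = "patient_series")
}

## naive sort-based error-metric oracle, independent of summarize_errors
naive_metrics <- function(pred, obs) {
  med <- function(x) {
    s <- sort(x); n <- length(s)
    if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
  }
  pe <- (pred - obs) / obs * 100
  list(rmse = sqrt(sum((pred - obs)^2) / length(pred)),
       mae = med(abs(pred - obs)),
       mdpe = med(pe),
       mdape = med(abs(pe)))
}

## naive Pearson chi-square from first principles
naive_chisq <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

## counts from the published 3x3 dose-vs-concentration analysis:
## rows dose over/within/under suggestion, cols conc under/within/over target
table3_counts <- function() {
  matrix(c(3, 36, 31,
           69, 116, 73,
           690, 80, 34),
         nrow = 3, byrow = TRUE,
         dimnames = list(dose = c("dose_over", "dose_within", "dose_under"),
                         concentration = c("conc_under", "conc_within", "conc_over")))
}

## brute-force window counter: targets are days >= 2 with a measured trough
naive_window_count <- function(series) {
  d <- series$daily
  sum(d$day >= 2 & !is.na(d$trough) & d$trough > 0)
}
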