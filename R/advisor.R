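#' Dose sweep grid and trough target range
#'
#' @param min_mg,max_mg,step_mg grid bounds and granularity (mg); inclusive
#'   at both ends.
#' @return `dose_grid`: the numeric vector of candidate doses.
#' @export
dose_grid <- function(min_mg = 0.5, max_mg = 20, step_mg = 0.5) {
  abort_if(min_mg > max_mg, "min must be <= max")
  abort_if(step_mg <= 0, "step must be > 0")
  structure(seq(min_mg, max_mg, by = step_mg), class = "dose_grid")
}

#' @param low,high target trough bounds (ng/mL), inclusive at both ends.
#' @rdname dose_grid
#' @export
target_range <- function(low = 8, high = 10) {
  abort_if(low >= high, "low must be < high")
  structure(c(low = low, high = high), class = "target_range")
}

in_target <- function(x, target) x >= target[["low"]] & x <= target[["high"]]

#' Sweep candidate doses and keep those predicted to hit the target
#'
#' Each grid dose is substituted for both same-day administrations on the
#' most recent input day of the window (the dose whose effect the next-day
#' trough reflects), the window is re-encoded, and the predictor re-run.
#' Doses whose predicted next-day trough lies in the (inclusive) target
#' range are the suggested set, which may be empty.
#'
#' @param pred a `tacro_predictor`, or a plain function taking a re-encoded
#'   `window_sample` and returning a predicted trough (handy for toy tests).
#' @param window the context `window_sample`.
#' @param grid a [dose_grid()].
#' @param target a [target_range()].
#' @param per_day if `TRUE`, the swept value is the *daily* dose split
#'   equally over the two administrations; default sweeps the
#'   per-administration amount.
#' @return numeric vector of suggested doses (subset of the grid; possibly
#'   empty).
#' @export
suggest_doses <- function(pred, window, grid = dose_grid(),
                          target = target_range(), per_day = FALSE) {
  predict1 <- if (inherits(pred, "tacro_predictor")) {
    function(w) predict_next(pred, w)
  } else {
    abort_if(!is.function(pred), "pred must be a predictor or function")
    pred
  }
  last <- nrow(window$dynamic)
  conc <- vapply(as.numeric(grid), function(d) {
    w <- window
    per_admin <- if (per_day) d / 2 else d
    w$dynamic[last, "dose_am"] <- per_admin
    w$dynamic[last, "dose_pm"] <- per_admin
    predict1(w)
  }, numeric(1))
  as.numeric(grid)[in_target(conc, target)]
}

#' Classify one case into the 3x3 dose-by-concentration table
#'
#' Row: the administered dose relative to the suggested set — `"over"` above
#' `max(set)`, `"under"` below `min(set)`, `"within"` inside the closed range
#' `[min(set), max(set)]` (range semantics are robust to gaps in the grid).
#' Column: the observed concentration against the inclusive target range.
#' An empty suggested set makes the row undefined: the case is excluded
#' (`NULL`), to be counted by [build_contingency()].
#'
#' @param administered administered dose (same scale as the suggested set).
#' @param suggested numeric vector from [suggest_doses()].
#' @param observed observed trough (ng/mL).
#' @param target a [target_range()].
#' @return list(row =, col =) with levels under/within/over, or `NULL`.
#' @export
classify_case <- function(administered, suggested, observed,
                          target = target_range()) {
  if (length(suggested) == 0L) return(NULL)
  row <- if (administered > max(suggested)) "over"
         else if (administered < min(suggested)) "under"
         else "within"
  col <- if (observed < target[["low"]]) "under"
         else if (observed > target[["high"]]) "over"
         else "within"
  list(row = row, col = col)
}

#' Assemble the 3x3 contingency table of classified cases
#'
#' Rows: administered dose over / within / under the suggested set. Columns:
#' observed concentration under / within / over the target. The percentage
#' view divides each cell by the classified total and rounds to the nearest
#' integer. Excluded (empty-suggestion) cases are counted in attribute
#' `"n_excluded"`.
#'
#' @param cases list of [classify_case()] results (`NULL`s allowed).
#' @return an object of class `contingency_table`: 3x3 integer matrix with
#'   attributes `percent` and `n_excluded`.
#' @export
build_contingency <- function(cases) {
  keep <- !vapply(cases, is.null, logical(1))
  abort_if(!any(keep), "no classifiable cases")
  rows <- factor(vapply(cases[keep], `[[`, character(1), "row"),
                 levels = c("over", "within", "under"))
  cols <- factor(vapply(cases[keep], `[[`, character(1), "col"),
                 levels = c("under", "within", "over"))
  tab <- table(dose = rows, concentration = cols)
  m <- matrix(as.integer(tab), 3, 3,
              dimnames = list(dose = c("dose_over", "dose_within", "dose_under"),
                              concentration = c("conc_under", "conc_within", "conc_over")))
  structure(m, class = c("contingency_table", "matrix"),
            percent = round(100 * m / sum(m)),
            n_excluded = sum(!keep))
}

#' @export
print.contingency_table <- function(x, ...) {
  m <- unclass(x)
  attributes(m)[c("percent", "n_excluded")] <- NULL
  print(m)
  cat("percent of", sum(m), "classified cases:\n")
  print(attr(x, "percent"))
  invisible(x)
}

#' Pearson chi-square test of independence on a count table
#'
#' Pearson statistic with expected counts from the margins, df =
#' (r-1)(c-1), upper-tail p, no continuity correction. Rows or columns with
#' a zero margin are dropped with a warning before testing.
#'
#' @param counts an r x c matrix of non-negative counts (a
#'   `contingency_table` works).
#' @return list(statistic =, df =, p_value =).
#' @export
chi_square_test <- function(counts) {
  m <- unclass(as.matrix(counts))
  attributes(m)["percent"] <- NULL
  abort_if(sum(m) <= 0, "table total must be > 0")
  rz <- rowSums(m) == 0
  cz <- colSums(m) == 0
  if (any(rz) || any(cz)) {
    warning("dropping zero-margin rows/columns from the chi-square table",
            call. = FALSE)
    m <- m[!rz, !cz, drop = FALSE]
  }
  abort_if(nrow(m) < 2 || ncol(m) < 2, "table degenerate after dropping zero margins")
  ct <- stats::chisq.test(m, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = unname(ct$p.value))
}

#' Per-patient clinical outcome flags
#'
#' * `exceeded_target`: any measured trough above the target upper bound
#'   during the horizon.
#' * `high_ipv`: high intra-patient variability — sample SD (n-1) of the
#'   measured troughs above 2 ng/mL (needs >= 2 troughs, else `NA`).
#' * `aki`: acute kidney injury — serum creatinine rise >= 0.3 mg/dL between
#'   any two measurements at most 2 days apart, or any value >= 1.5 x the
#'   baseline (first recorded value) within 7 days of baseline. All
#'   creatinine missing gives `NA` (undetermined, not FALSE).
#'
#' @param series a `patient_series`.
#' @param target a [target_range()].
#' @param ipv_sd_threshold SD threshold for the IPV flag (ng/mL).
#' @return list of logical flags (`NA` where undetermined).
#' @export
outcome_flags <- function(series, target = target_range(),
                          ipv_sd_threshold = 2) {
  tr <- series$daily$trough
  tr <- tr[!is.na(tr)]
  exceeded <- if (length(tr)) any(tr > target[["high"]]) else NA
  high_ipv <- if (length(tr) >= 2) stats::sd(tr) > ipv_sd_threshold else NA

  cr <- series$daily$creatinine
  day <- series$daily$day
  ok <- !is.na(cr)
  aki <- if (!any(ok)) {
    NA
  } else {
    d <- day[ok]; v <- cr[ok]
    rise48 <- FALSE
    for (i in seq_along(d)) {
      later <- which(d > d[i] & d - d[i] <= 2)
      if (any(v[later] - v[i] >= 0.3)) { rise48 <- TRUE; break }
    }
    baseline <- v[1]
    ratio7 <- any(v[d <= d[1] + 7] / baseline >= 1.5)
    rise48 || ratio7
  }
  list(exceeded_target = exceeded, high_ipv = high_ipv, aki = aki)
}

#' Association between a binary exposure flag and a binary outcome
#'
#' Cross-tabulates the two indicators and applies [chi_square_test()].
#' Degenerate margins are reported (test result `NA`) rather than raised.
#'
#' @param exposure,outcome logical vectors of equal length (`NA`s dropped
#'   pairwise).
#' @return list(table =, statistic =, df =, p_value =).
#' @export
outcome_association <- function(exposure, outcome) {
  stopifnot(length(exposure) == length(outcome))
  ok <- !is.na(exposure) & !is.na(outcome)
  tab <- table(exposure = factor(exposure[ok], levels = c(FALSE, TRUE)),
               outcome = factor(outcome[ok], levels = c(FALSE, TRUE)))
  m <- matrix(as.integer(tab), 2, 2, dimnames = dimnames(tab))
  res <- tryCatch(suppressWarnings(chi_square_test(m)),
                  error = function(e) list(statistic = NA_real_, df = NA_real_,
                                           p_value = NA_real_))
  c(list(table = m), res)
}

#' Compare a continuous outcome (e.g. ICU stay) between two groups
#'
#' Normality routing per group by Shapiro-Wilk at 0.05 (constant or tiny
#' samples count as non-normal): both normal-looking gives a Welch t-test,
#' otherwise a Mann-Whitney U test (normal approximation with tie
#' correction, so two identical constant groups give p = 1).
#'
#' @param a,b numeric vectors, each with >= 2 values.
#' @return list(mean_a, mean_b, sd_a, sd_b, test = "welch"|"mann-whitney",
#'   p_value).
#' @export
stay_comparison <- function(a, b) {
  abort_if(length(a) < 2 || length(b) < 2, "each group needs >= 2 values")
  looks_normal <- function(x) {
    if (length(x) < 3 || length(unique(x)) < 3) return(FALSE)
    stats::shapiro.test(x)$p.value > 0.05
  }
  use_t <- looks_normal(a) && looks_normal(b)
  p <- if (stats::var(c(a, b)) == 0) {
    1  # every value identical: no evidence of any difference
  } else if (use_t) {
    stats::t.test(a, b)$p.value
  } else {
    suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)$p.value)
  }
  list(mean_a = mean(a), mean_b = mean(b), sd_a = stats::sd(a),
       sd_b = stats::sd(b), test = if (use_t) "welch" else "mann-whitney",
       p_value = p)
}
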