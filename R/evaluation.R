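#' Performance error of one prediction
#'
#' PE = (pred - obs) / obs * 100, so over-prediction is positive. Defined
#' only for positive observed concentrations.
#'
#' @param pred predicted concentration (ng/mL).
#' @param obs observed concentration (ng/mL); > 0.
#' @return performance error in percent (vectorised).
#' @export
performance_error <- function(pred, obs) {
  abort_if(any(obs <= 0), "performance error requires obs > 0")
  (pred - obs) / obs * 100
}

#' Summarise prediction errors the PK-validation way
#'
#' RMSE is the root mean squared raw error (ng/mL); MAE is the *median*
#' absolute error (ng/mL) — the usual PK-validation reading, not the mean;
#' MDPE and MDAPE are the median signed and median absolute performance
#' errors (%). Pairs with non-positive observations are excluded and
#' counted. Medians of even-sized samples use midpoint interpolation.
#'
#' @param pred,obs numeric vectors of predicted and observed troughs (ng/mL).
#' @return an object of class `error_summary` with fields `rmse`, `mae`,
#'   `mdpe`, `mdape`, `n`, `n_excluded`.
#' @export
#' @examples
#' summarize_errors(c(11, 9, 13), c(10, 10, 10))  # mdpe 10, mdape 10
summarize_errors <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  ok <- is.finite(obs) & obs > 0 & is.finite(pred)
  n_excluded <- sum(!ok)
  pred <- pred[ok]; obs <- obs[ok]
  abort_if(length(pred) == 0L, "no valid prediction pairs")
  pe <- performance_error(pred, obs)
  structure(list(rmse = sqrt(mean((pred - obs)^2)),
                 mae = stats::median(abs(pred - obs)),
                 mdpe = stats::median(pe),
                 mdape = stats::median(abs(pe)),
                 n = length(pred), n_excluded = n_excluded),
            class = "error_summary")
}

#' @export
print.error_summary <- function(x, ...) {
  cat(sprintf("RMSE %.2f ng/mL | MAE %.2f ng/mL | MDPE %+.1f%% | MDAPE %.1f%% (n = %d)\n",
              x$rmse, x$mae, x$mdpe, x$mdape, x$n))
  invisible(x)
}

#' Clinical acceptability gate
#'
#' A predictor is flagged acceptable when its bias and precision fall inside
#' the conventional population-PK external-validation bounds: MDPE within
#' +/-20 % and MDAPE <= 30 %.
#'
#' @param summary an [summarize_errors()] result.
#' @return logical.
#' @export
is_clinically_acceptable <- function(summary) {
  abs(summary$mdpe) <= 20 && summary$mdape <= 30
}

#' Multi-seed resampling validation
#'
#' For each of `n_seeds` seeds: a patient-level 80/20 split, training of
#' every requested family on the training windows, evaluation on the test
#' windows, and an [summarize_errors()] row. The PK family is evaluated
#' without training. A family that fails on a seed is recorded as NA and the
#' run continues.
#'
#' @param cohort complete-covariate cohort.
#' @param families character vector from `c("lstm","gbrt","linear","pk")`.
#' @param n_seeds number of resampling repetitions.
#' @param test_fraction held-out patient fraction.
#' @param features a [feature_set()] (the PK family always uses its own).
#' @param hp a [hyper_params()].
#' @param seed0 base seed; repetition `i` uses `seed0 + i`.
#' @return a `validation_report`: list with `per_seed` (data.frame seed x
#'   family x metrics) and `summary` (mean and SD per family per metric).
#' @export
multi_seed_validation <- function(cohort, families = c("lstm", "gbrt", "linear", "pk"),
                                  n_seeds = 10L, test_fraction = 0.2,
                                  features = feature_set(), hp = hyper_params(),
                                  seed0 = 100L) {
  rows <- list()
  for (i in seq_len(n_seeds)) {
    s <- seed0 + i
    sp <- split_by_patient(cohort, test_fraction, seed = s)
    for (fam in families) {
      fs <- if (fam == "pk") train_pk(n_days = hp$n_days)$features else features
      res <- tryCatch({
        wtr <- cohort_windows(sp$train, n_days = hp$n_days, features = fs)
        wte <- cohort_windows(sp$test, n_days = hp$n_days, features = fs)
        mod <- train_family(fam, wtr, hp, seed = s)
        obs <- vapply(wte, function(w) w$target, numeric(1))
        summarize_errors(predict_windows(mod, wte), obs)
      }, error = function(e) {
        warning(sprintf("family %s failed on seed %d: %s", fam, s,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
      rows[[length(rows) + 1L]] <- data.frame(
        seed = s, family = fam,
        rmse = res$rmse %||% NA_real_, mae = res$mae %||% NA_real_,
        mdpe = res$mdpe %||% NA_real_, mdape = res$mdape %||% NA_real_,
        n = res$n %||% NA_integer_)
    }
  }
  per_seed <- do.call(rbind, rows)
  metrics <- c("rmse", "mae", "mdpe", "mdape")
  agg <- do.call(rbind, lapply(split(per_seed, per_seed$family), function(df) {
    out <- data.frame(family = df$family[1])
    for (m in metrics) {
      out[[paste0(m, "_mean")]] <- mean(df[[m]], na.rm = TRUE)
      out[[paste0(m, "_sd")]] <- stats::sd(df[[m]], na.rm = TRUE)
    }
    out
  }))
  rownames(agg) <- NULL
  structure(list(per_seed = per_seed, summary = agg),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Resampling validation (mean (SD) across seeds):\n")
  print(x$summary, digits = 3)
  invisible(x)
}

#' Compare model families on a per-seed metric
#'
#' One-way ANOVA across families with the per-seed metric values as
#' replicates, followed by pairwise Welch t-tests with Bonferroni
#' correction (raw p multiplied by the number of pairs, capped at 1).
#'
#' @param report a [multi_seed_validation()] result.
#' @param metric one of `"rmse"`, `"mae"`, `"mdpe"`, `"mdape"`.
#' @return list with `anova_p`, `anova_F`, and `pairwise` (data.frame of
#'   family pairs, raw and adjusted p).
#' @export
compare_models <- function(report, metric = "mdape") {
  df <- report$per_seed[is.finite(report$per_seed[[metric]]), ]
  fams <- unique(df$family)
  abort_if(length(fams) < 2, "need at least 2 families")
  abort_if(length(unique(df$seed)) < 2, "need at least 2 seeds")
  if (stats::var(df[[metric]]) < 1e-24) {
    return(list(anova_F = 0, anova_p = 1,
                pairwise = data.frame(), note = "zero variance everywhere"))
  }
  df$family <- factor(df$family)
  fit <- stats::aov(stats::reformulate("family", response = metric), data = df)
  an <- summary(fit)[[1]]
  pairs <- utils::combn(as.character(levels(df$family)), 2)
  n_pairs <- ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(n_pairs), function(j) {
    a <- df[[metric]][df$family == pairs[1, j]]
    b <- df[[metric]][df$family == pairs[2, j]]
    p_raw <- tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
    data.frame(family_a = pairs[1, j], family_b = pairs[2, j],
               p_raw = p_raw, p_bonferroni = min(1, p_raw * n_pairs))
  }))
  list(anova_F = an[["F value"]][1], anova_p = an[["Pr(>F)"]][1], pairwise = pw)
}
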