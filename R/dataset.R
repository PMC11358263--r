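#' Feature set for the dynamic input block
#'
#' Doses (morning and evening) are always inputs. The measured trough can be
#' toggled off for the no-concentration sensitivity variant. Dynamic
#' covariates are any subset of weight and the seven daily labs; the default
#' is the selected combination weight + AST + creatinine.
#'
#' @param covariates character subset of
#'   `c("weight","ast","alt","tbil","inr","albumin","creatinine","hematocrit")`.
#' @param include_trough include the measured trough as an input feature.
#' @return an object of class `feature_set`.
#' @export
feature_set <- function(covariates = c("weight", "ast", "creatinine"),
                        include_trough = TRUE) {
  universe <- c("weight", lab_columns())
  bad <- setdiff(covariates, universe)
  abort_if(length(bad) > 0, "unknown dynamic covariates: ",
           paste(bad, collapse = ", "))
  covariates <- universe[universe %in% covariates]  # canonical order
  structure(list(covariates = covariates, include_trough = include_trough),
            class = "feature_set")
}

feature_columns <- function(features) {
  c("dose_am", "dose_pm", if (features$include_trough) "trough",
    features$covariates)
}

n_features <- function(features) length(feature_columns(features))

feature_set_label <- function(features) {
  paste(c("doses", if (features$include_trough) "trough", features$covariates),
        collapse = "+")
}

#' Zero substitution before the first dose, with window padding
#'
#' Doses and troughs on days before the first administered dose are set to 0;
#' days before post-operative day 1 that a window may reach into are
#' materialised as all-zero rows (static covariates are untouched). This is
#' the standard encoding for "no drug on board yet".
#'
#' @param series a `patient_series`.
#' @param pad_days number of all-zero days to prepend before day 1.
#' @return the series with modified/padded `daily`.
#' @export
zero_substitute <- function(series, pad_days = 0L) {
  d <- series$daily
  first_dose_day <- {
    has <- which((!is.na(d$dose_am) & d$dose_am > 0) |
                 (!is.na(d$dose_pm) & d$dose_pm > 0))
    if (length(has)) d$day[min(has)] else Inf
  }
  pre <- d$day < first_dose_day
  d$dose_am[pre] <- 0
  d$dose_pm[pre] <- 0
  d$trough[pre] <- 0
  d$dose_am[is.na(d$dose_am)] <- 0
  d$dose_pm[is.na(d$dose_pm)] <- 0
  if (pad_days > 0L) {
    pad <- d[rep(1L, pad_days), , drop = FALSE]
    pad[] <- 0
    pad$day <- seq(min(d$day) - pad_days, min(d$day) - 1L)
    d <- rbind(pad, d)
    rownames(d) <- NULL
  }
  series$daily <- d
  series
}

#' Build supervised next-day-trough windows from one series
#'
#' One sample per day `t >= 2` with a measured (positive) trough: the target
#' is day `t`'s morning trough and the dynamic input block covers the
#' `n_days` preceding days (`t - n_days` ... `t - 1`) after
#' [zero_substitute()]; early windows reach into zero-padded days. Day 1 has
#' no dosing history and is never a target. Troughs that were simply not
#' measured on an *input* day are encoded 0 (indistinguishable, by design,
#' from "no drug yet"); lab covariates must already be complete — run
#' [impute_missing()] first.
#'
#' @param series a `patient_series`.
#' @param n_days input window length (days); >= 1.
#' @param features a [feature_set()].
#' @return list of `window_sample` objects: `dynamic` (n_days x F matrix,
#'   rows oldest-first), `static` (named vector age/sex/height), `target`
#'   (ng/mL), `patient_id`, `target_day`.
#' @export
build_windows <- function(series, n_days = 3L, features = feature_set()) {
  abort_if(n_days < 1, "n_days must be >= 1")
  d0 <- series$daily
  if (nrow(d0) < 2L) return(list())
  cols <- feature_columns(features)
  labs_used <- intersect(c("weight", lab_columns()), cols)
  if (length(labs_used)) {
    incomplete <- vapply(labs_used, function(cl) anyNA(d0[[cl]]), logical(1))
    abort_if(any(incomplete),
             "missing covariate values in: ",
             paste(labs_used[incomplete], collapse = ", "),
             " - impute before building windows")
  }
  zs <- zero_substitute(series, pad_days = n_days)
  d <- zs$daily
  d$trough[is.na(d$trough)] <- 0
  static <- c(age = series$age, sex = as.numeric(series$sex),
              height = series$height_cm)
  targets <- d0$day[d0$day >= 2 & !is.na(d0$trough) & d0$trough > 0]
  lapply(targets, function(t_day) {
    rows <- match((t_day - n_days):(t_day - 1L), d$day)
    dyn <- as.matrix(d[rows, cols, drop = FALSE])
    rownames(dyn) <- NULL
    structure(list(dynamic = dyn, static = static,
                   target = d0$trough[d0$day == t_day],
                   patient_id = series$patient_id, target_day = t_day),
              class = "window_sample")
  })
}

#' Build windows for a whole cohort
#' @inheritParams build_windows
#' @param cohort list of `patient_series`.
#' @return flat list of `window_sample`s.
#' @export
cohort_windows <- function(cohort, n_days = 3L, features = feature_set()) {
  do.call(c, lapply(cohort, build_windows, n_days = n_days, features = features))
}

#' Patient-level train/test split
#'
#' Whole patients (and thus all their windows) land on one side. The test
#' set size is `floor(test_fraction * N)`, which reproduces a 355/88 split
#' of 443 patients at 0.2.
#'
#' @param cohort list of `patient_series`.
#' @param test_fraction fraction of patients in the test set; in (0, 1).
#' @param seed RNG seed for the assignment.
#' @return list with elements `train` and `test` (each a `tacro_cohort`).
#' @export
split_by_patient <- function(cohort, test_fraction = 0.2, seed = 1) {
  abort_if(test_fraction <= 0 || test_fraction >= 1,
           "test_fraction must be in (0, 1)")
  n <- length(cohort)
  abort_if(n < 2, "need at least 2 patients to split")
  n_test <- max(1L, floor(test_fraction * n))
  set.seed(seed)
  idx_test <- sort(sample.int(n, n_test))
  list(train = structure(cohort[-idx_test], class = "tacro_cohort"),
       test = structure(cohort[idx_test], class = "tacro_cohort"))
}

## ---- flattening windows to matrices -----------------------------------

## design matrix for flat learners: dynamic block row-major oldest-first,
## then static block; column names carry day lag for interpretability
windows_to_matrix <- function(windows) {
  abort_if(length(windows) == 0L, "no windows")
  n_days <- nrow(windows[[1]]$dynamic)
  cols <- colnames(windows[[1]]$dynamic)
  dyn_names <- unlist(lapply(seq_len(n_days), function(d)
    paste0(cols, "_lag", n_days - d + 1)))
  X <- t(vapply(windows, function(w) c(t(w$dynamic), w$static),
                numeric(n_days * length(cols) + 3L)))
  colnames(X) <- c(dyn_names, names(windows[[1]]$static))
  y <- vapply(windows, function(w) w$target, numeric(1))
  list(X = X, y = y,
       patient_id = vapply(windows, function(w) as.character(w$patient_id), character(1)),
       target_day = vapply(windows, function(w) w$target_day, numeric(1)))
}

## arrays for the sequence model: list of T matrices (N x F), static N x 3
windows_to_arrays <- function(windows) {
  abort_if(length(windows) == 0L, "no windows")
  n_days <- nrow(windows[[1]]$dynamic)
  Xt <- lapply(seq_len(n_days), function(t)
    t(vapply(windows, function(w) w$dynamic[t, ], numeric(ncol(windows[[1]]$dynamic)))))
  S <- t(vapply(windows, function(w) w$static, numeric(3)))
  y <- vapply(windows, function(w) w$target, numeric(1))
  list(Xt = Xt, S = S, y = y)
}

## ---- standardization ---------------------------------------------------

#' Fit a train-set z-score scaler over windows
#'
#' Dynamic features are standardized with statistics pooled over all input
#' days of the training windows; static features with per-feature statistics.
#' Constant features (SD 0) are passed through unscaled. Targets stay on the
#' ng/mL scale.
#'
#' @param train_windows list of `window_sample`s.
#' @return a `window_scaler` record.
#' @export
fit_scaler <- function(train_windows) {
  abort_if(length(train_windows) == 0L, "train windows must be non-empty")
  dyn <- do.call(rbind, lapply(train_windows, function(w) w$dynamic))
  S <- do.call(rbind, lapply(train_windows, function(w) w$static))
  colnames(S) <- names(train_windows[[1]]$static)
  stat <- function(M) {
    mu <- colMeans(M)
    sd <- apply(M, 2, stats::sd)
    const <- !is.finite(sd) | sd < 1e-12
    mu[const] <- 0
    sd[const] <- 1
    list(mean = mu, sd = sd)
  }
  structure(list(dynamic = stat(dyn), static = stat(S)),
            class = "window_scaler")
}

#' Apply a scaler to windows
#' @param scaler a [fit_scaler()] record.
#' @param windows list of `window_sample`s.
#' @return windows with standardized blocks.
#' @export
apply_scaler <- function(scaler, windows) {
  lapply(windows, function(w) {
    w$dynamic <- sweep(sweep(w$dynamic, 2, scaler$dynamic$mean), 2,
                       scaler$dynamic$sd, "/")
    w$static <- (w$static - scaler$static$mean) / scaler$static$sd
    w
  })
}

## ---- multiple imputation ----------------------------------------------

#' Multiple imputation of daily lab covariates by chained equations
#'
#' Produces `m` completed copies of the cohort. Each copy: missing lab cells
#' are initialised at the observed column means, then a few sweeps of
#' chained-equation regression run over the lab columns — each incomplete
#' column is regressed (ordinary least squares) on the other labs plus the
#' day index over originally-observed rows, and its missing cells are drawn
#' from the predictive distribution (fit + residual-SD noise). Imputed labs
#' are clamped strictly positive. Doses and troughs are never imputed: a day
#' without a measured trough simply yields no training target.
#'
#' @param cohort list of `patient_series`.
#' @param m number of completed copies; >= 1.
#' @param seed RNG seed; fixed seed gives identical output.
#' @param sweeps chained-equation sweeps per copy.
#' @return list of `m` completed cohorts.
#' @export
impute_missing <- function(cohort, m = 5L, seed = 1, sweeps = 3L) {
  abort_if(m < 1, "m must be >= 1")
  labs <- c("weight", lab_columns())
  long <- do.call(rbind, lapply(cohort, function(s) s$daily[, c("day", labs)]))
  miss <- is.na(long[, labs, drop = FALSE])
  all_missing <- colSums(!miss) == 0
  abort_if(any(all_missing), "covariate(s) missing for the entire cohort: ",
           paste(labs[all_missing], collapse = ", "))
  set.seed(seed)
  out <- vector("list", m)
  for (k in seq_len(m)) {
    filled <- long
    for (cl in labs) {
      filled[[cl]][is.na(filled[[cl]])] <- mean(long[[cl]], na.rm = TRUE)
    }
    incomplete <- labs[colSums(miss) > 0]
    for (s in seq_len(sweeps)) {
      for (cl in incomplete) {
        obs <- !miss[, cl]
        rhs <- setdiff(labs, cl)
        df <- filled[, c(cl, rhs, "day")]
        fit <- stats::lm(stats::reformulate(c(rhs, "day"), response = cl),
                         data = df[obs, , drop = FALSE])
        pred <- stats::predict(fit, newdata = df[!obs, , drop = FALSE])
        sigma <- summary(fit)$sigma
        if (!is.finite(sigma)) sigma <- 0
        draw <- pred + stats::rnorm(sum(!obs), 0, sigma)
        lo <- 0.05 * stats::median(long[[cl]], na.rm = TRUE)
        filled[[cl]][!obs] <- pmax(draw, lo)
      }
    }
    ## write the completed values back into per-patient series
    completed <- cohort
    offset <- 0L
    for (i in seq_along(completed)) {
      nr <- nrow(completed[[i]]$daily)
      rows <- offset + seq_len(nr)
      for (cl in labs) completed[[i]]$daily[[cl]] <- filled[[cl]][rows]
      offset <- offset + nr
    }
    out[[k]] <- structure(completed, class = "tacro_cohort")
  }
  out
}
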