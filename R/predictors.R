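#' Hyperparameters for the sequence model and trainers
#'
#' The defaults reproduce the selected combination: 3 input days, 16
#' recurrent nodes, 32 dense nodes. The search grids are 2-7 input days,
#' \{8, 16, 32, 64, 128, 256\} recurrent nodes and \{8, 16, 32, 64, 128\}
#' dense nodes.
#'
#' @param n_days input window length in days.
#' @param recurrent_nodes LSTM hidden size.
#' @param dense_nodes dense-layer width.
#' @param epochs maximum training epochs.
#' @param learning_rate Adam step size.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction internal validation fraction for early stopping.
#' @param gbrt list of GBRT settings (`n_estimators`, `max_depth`,
#'   `learning_rate`).
#' @return an object of class `hyper_params`.
#' @export
hyper_params <- function(n_days = 3L, recurrent_nodes = 16L, dense_nodes = 32L,
                         epochs = 200L, learning_rate = 0.02, patience = 20L,
                         val_fraction = 0.1,
                         gbrt = list(n_estimators = 200L, max_depth = 3L,
                                     learning_rate = 0.1)) {
  abort_if(n_days < 1 || recurrent_nodes < 1 || dense_nodes < 1,
           "counts must be positive")
  structure(list(n_days = as.integer(n_days),
                 recurrent_nodes = as.integer(recurrent_nodes),
                 dense_nodes = as.integer(dense_nodes),
                 epochs = as.integer(epochs), learning_rate = learning_rate,
                 patience = as.integer(patience), val_fraction = val_fraction,
                 gbrt = gbrt),
            class = "hyper_params")
}

new_predictor <- function(family, fit, features, scaler, hp, extra = list()) {
  structure(c(list(family = family, fit = fit, features = features,
                   scaler = scaler, hp = hp), extra),
            class = "tacro_predictor")
}

#' @export
print.tacro_predictor <- function(x, ...) {
  cat(sprintf("<tacro_predictor: %s | features %s | n_days %d>\n",
              x$family, feature_set_label(x$features),
              x$hp$n_days %||% NA_integer_))
  invisible(x)
}

#' Train the recurrent sequence model
#'
#' An LSTM layer reads the `n_days` x F dynamic block day by day; its final
#' hidden state is concatenated with the static covariates (age, sex,
#' height) and passed through one ReLU dense layer to a linear output
#' predicting the next-day trough. Trained by full-batch Adam on squared
#' error with early stopping; fully deterministic under a fixed seed.
#'
#' @param train_windows list of `window_sample`s (unscaled; scaling is fitted
#'   internally on these windows).
#' @param hp a [hyper_params()].
#' @param seed RNG seed controlling initialisation and the validation split.
#' @return a `tacro_predictor` of family `"lstm"`.
#' @export
train_sequence_model <- function(train_windows, hp = hyper_params(), seed = 1) {
  abort_if(length(train_windows) < 1, "need at least one training window")
  scaler <- fit_scaler(train_windows)
  arr <- windows_to_arrays(apply_scaler(scaler, train_windows))
  fit <- lstm_fit(arr$Xt, arr$S, arr$y,
                  hidden = hp$recurrent_nodes, dense = hp$dense_nodes,
                  epochs = hp$epochs, lr = hp$learning_rate,
                  patience = hp$patience, val_fraction = hp$val_fraction,
                  seed = seed)
  new_predictor("lstm", fit, train_windows[[1]]$features %||%
                  infer_features(train_windows[[1]]), scaler, hp)
}

## feature_set implied by a window's dynamic column names
infer_features <- function(window) {
  cols <- colnames(window$dynamic)
  feature_set(covariates = intersect(c("weight", lab_columns()), cols),
              include_trough = "trough" %in% cols)
}

#' Train the gradient-boosted regression tree model
#'
#' xgboost on the flattened (n_days * F + 3 static) feature vector,
#' squared-error objective, single thread for reproducibility.
#'
#' @inheritParams train_sequence_model
#' @return a `tacro_predictor` of family `"gbrt"`.
#' @export
train_gbrt <- function(train_windows, hp = hyper_params(), seed = 1) {
  abort_if(length(train_windows) < 1, "need at least one training window")
  scaler <- fit_scaler(train_windows)
  mat <- windows_to_matrix(apply_scaler(scaler, train_windows))
  set.seed(seed)
  g <- hp$gbrt
  dtrain <- xgboost::xgb.DMatrix(mat$X, label = mat$y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", max_depth = g$max_depth,
                  eta = g$learning_rate, nthread = 1,
                  seed = seed %% .Machine$integer.max),
    data = dtrain, nrounds = g$n_estimators, verbose = 0
  )
  new_predictor("gbrt", xgboost::xgb.save.raw(booster),
                infer_features(train_windows[[1]]), scaler, hp,
                extra = list(feature_names = colnames(mat$X)))
}

#' Train the linear regression model
#'
#' Ordinary least squares on the flattened features; if the standardized
#' design matrix is rank deficient, a small ridge penalty (lambda = 1e-6)
#' stabilises the solution and zero-variance columns get coefficient 0.
#'
#' @inheritParams train_sequence_model
#' @return a `tacro_predictor` of family `"linear"`.
#' @export
train_linear <- function(train_windows, hp = hyper_params(), seed = 1) {
  abort_if(length(train_windows) < 1, "need at least one training window")
  scaler <- fit_scaler(train_windows)
  mat <- windows_to_matrix(apply_scaler(scaler, train_windows))
  X <- cbind(`(Intercept)` = 1, mat$X)
  qrX <- qr(X)
  coefs <- if (qrX$rank == ncol(X)) {
    qr.coef(qrX, mat$y)
  } else {
    lambda <- 1e-6
    XtX <- crossprod(X) + diag(lambda, ncol(X))
    drop(solve(XtX, crossprod(X, mat$y)))
  }
  coefs[!is.finite(coefs)] <- 0
  new_predictor("linear", coefs, infer_features(train_windows[[1]]), scaler, hp,
                extra = list(feature_names = colnames(mat$X)))
}

#' The population-PK comparator as a predictor
#'
#' No fitting: predictions reconstruct the dose events encoded in the window
#' (09:00/21:00 administrations on each input day), resolve the piecewise
#' parameters from the window's AST/albumin/hematocrit on each dosing day,
#' and evaluate the closed-form superposition at the target day's trough
#' instant. Requires the feature set to carry `ast`, `albumin` and
#' `hematocrit`. Doses earlier than the window are invisible to it, exactly
#' as they are to the learned models.
#'
#' @param n_days input window length the predictor expects.
#' @param ka absorption rate constant (1/h).
#' @param mode parameter resolution, see [concentration_at()].
#' @return a `tacro_predictor` of family `"pk"`.
#' @export
train_pk <- function(n_days = 3L, ka = 4.5, mode = "per_dose") {
  feats <- feature_set(covariates = c("weight", "ast", "albumin", "hematocrit"),
                       include_trough = TRUE)
  hp <- hyper_params(n_days = n_days)
  new_predictor("pk", list(ka = ka, mode = mode), feats, NULL, hp)
}

#' Predict the next-day trough from one window
#'
#' Raw predictions below 0.1 ng/mL are floored at 0.1 (concentrations are
#' positive; 0.1 is below assay quantitation anyway).
#'
#' @param pred a `tacro_predictor`.
#' @param window a `window_sample` with the dynamic columns the predictor
#'   was trained on.
#' @return predicted trough, ng/mL.
#' @export
predict_next <- function(pred, window) {
  predict_windows(pred, list(window))[1]
}

#' Vectorised prediction over a list of windows
#' @inheritParams predict_next
#' @param windows list of `window_sample`s.
#' @return numeric vector of predicted troughs (ng/mL), floored at 0.1.
#' @export
predict_windows <- function(pred, windows) {
  abort_if(length(windows) == 0L, "no windows to predict")
  want <- feature_columns(pred$features)
  have <- colnames(windows[[1]]$dynamic)
  abort_if(!identical(have, want),
           "window features (", paste(have, collapse = ","),
           ") do not match the predictor's (", paste(want, collapse = ","), ")")
  raw <- switch(pred$family,
    lstm = {
      arr <- windows_to_arrays(apply_scaler(pred$scaler, windows))
      lstm_forward(pred$fit, arr$Xt, arr$S)
    },
    gbrt = {
      mat <- windows_to_matrix(apply_scaler(pred$scaler, windows))
      booster <- xgboost::xgb.load.raw(pred$fit)
      stats::predict(booster, xgboost::xgb.DMatrix(mat$X, nthread = 1))
    },
    linear = {
      mat <- windows_to_matrix(apply_scaler(pred$scaler, windows))
      as.vector(cbind(1, mat$X) %*% pred$fit)
    },
    pk = vapply(windows, predict_window_pk, numeric(1),
                ka = pred$fit$ka, mode = pred$fit$mode),
    stop("unknown predictor family: ", pred$family)
  )
  pmax(as.numeric(raw), 0.1)
}

## PK prediction from a single (unscaled) window
predict_window_pk <- function(window, ka, mode) {
  dyn <- window$dynamic
  n_days <- nrow(dyn)
  days <- (window$target_day - n_days):(window$target_day - 1L)
  tm <- c((days - 1) * 24 + 9, (days - 1) * 24 + 21)
  amt <- c(dyn[, "dose_am"], dyn[, "dose_pm"])
  keep <- amt > 0
  doses <- data.frame(time = tm[keep], amount = amt[keep])
  doses <- doses[order(doses$time), , drop = FALSE]
  if (nrow(doses) == 0L) return(0)
  ctx <- data.frame(day = c(days, window$target_day),
                    ast = c(dyn[, "ast"], dyn[n_days, "ast"]),
                    albumin = c(dyn[, "albumin"], dyn[n_days, "albumin"]),
                    hematocrit = c(dyn[, "hematocrit"], dyn[n_days, "hematocrit"]))
  t_sample <- (window$target_day - 1) * 24 + 9 - 1 / 60
  concentration_at(doses, ctx, t_sample, ka = ka, mode = mode)
}

#' Save / load a trained predictor
#'
#' The archive is a single RDS holding the weights (raw bytes for the GBRT
#' booster), feature set, scaler and hyperparameters; a reloaded predictor
#' gives bit-identical predictions.
#'
#' @param pred a `tacro_predictor`.
#' @param path file path.
#' @return `save_predictor` returns `path` invisibly; `load_predictor` the
#'   predictor.
#' @export
save_predictor <- function(pred, path) {
  stopifnot(inherits(pred, "tacro_predictor"))
  saveRDS(unclass(pred), path)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  structure(readRDS(path), class = "tacro_predictor")
}

## dispatch a family tag to its trainer on a cohort's windows
train_family <- function(family, train_windows, hp, seed) {
  switch(family,
         lstm = train_sequence_model(train_windows, hp, seed),
         gbrt = train_gbrt(train_windows, hp, seed),
         linear = train_linear(train_windows, hp, seed),
         pk = train_pk(n_days = hp$n_days),
         stop("unknown model family: ", family))
}

#' Five-fold cross-validated feature selection
#'
#' Patient-level k-fold CV RMSE for each candidate feature set; the winner
#' has the lowest mean RMSE, with ties (within 1e-8 ng/mL) broken by fewer
#' variables, then lexicographic label order.
#'
#' @param cohort training cohort (complete covariates).
#' @param candidates named list of [feature_set()]s.
#' @param k number of folds.
#' @param family model family used for scoring (default `"linear"`, the
#'   cheapest honest scorer; any family tag works).
#' @param hp a [hyper_params()].
#' @param seed RNG seed for fold assignment and training.
#' @return the winning `feature_set`, with the per-candidate CV table in
#'   attribute `"cv_table"`.
#' @export
cv_feature_selection <- function(cohort, candidates, k = 5L, family = "linear",
                                 hp = hyper_params(), seed = 1) {
  abort_if(length(cohort) < k, "need at least k patients")
  abort_if(length(candidates) == 0L, "no candidate feature sets")
  if (is.null(names(candidates)))
    names(candidates) <- vapply(candidates, feature_set_label, character(1))
  set.seed(seed)
  folds <- sample(rep_len(seq_len(k), length(cohort)))
  score <- vapply(candidates, function(fs) {
    fold_rmse <- vapply(seq_len(k), function(f) {
      tr <- cohort[folds != f]
      te <- cohort[folds == f]
      wtr <- cohort_windows(tr, n_days = hp$n_days, features = fs)
      wte <- cohort_windows(te, n_days = hp$n_days, features = fs)
      if (length(wtr) == 0L || length(wte) == 0L) return(NA_real_)
      mod <- train_family(family, wtr, hp, seed)
      obs <- vapply(wte, function(w) w$target, numeric(1))
      sqrt(mean((predict_windows(mod, wte) - obs)^2))
    }, numeric(1))
    mean(fold_rmse, na.rm = TRUE)
  }, numeric(1))
  sizes <- vapply(candidates, function(fs) n_features(fs), integer(1))
  ord <- order(round(score / 1e-8), sizes, names(candidates))
  best <- candidates[[ord[1]]]
  attr(best, "cv_table") <- data.frame(candidate = names(candidates),
                                       cv_rmse = score, n_features = sizes,
                                       row.names = NULL)
  best
}

#' Grid search over hyperparameters on a held-out validation fold
#'
#' Patient-level 80/20 train/validation split inside the training cohort;
#' every grid row is trained and scored by validation RMSE; the arg-min row
#' wins. The full grid-to-error table is attached as attribute
#' `"grid_table"`.
#'
#' @param cohort training cohort.
#' @param grid data.frame of hyperparameter combinations; recognised columns
#'   are `n_days`, `recurrent_nodes`, `dense_nodes`, `epochs`.
#' @param family model family tag.
#' @param features a [feature_set()].
#' @param base_hp baseline [hyper_params()] supplying unspecified settings.
#' @param seed RNG seed (split + training).
#' @return the winning `hyper_params` with attribute `"grid_table"`.
#' @export
grid_search <- function(cohort, grid, family = "lstm",
                        features = feature_set(), base_hp = hyper_params(),
                        seed = 1) {
  abort_if(nrow(grid) == 0L, "empty hyperparameter grid")
  sp <- split_by_patient(cohort, test_fraction = 0.2, seed = seed)
  rmse <- vapply(seq_len(nrow(grid)), function(i) {
    hp <- base_hp
    for (nm in intersect(names(grid), c("n_days", "recurrent_nodes",
                                        "dense_nodes", "epochs"))) {
      hp[[nm]] <- as.integer(grid[[nm]][i])
    }
    wtr <- cohort_windows(sp$train, n_days = hp$n_days, features = features)
    wva <- cohort_windows(sp$test, n_days = hp$n_days, features = features)
    mod <- train_family(family, wtr, hp, seed)
    obs <- vapply(wva, function(w) w$target, numeric(1))
    sqrt(mean((predict_windows(mod, wva) - obs)^2))
  }, numeric(1))
  i_best <- which.min(rmse)
  hp <- base_hp
  for (nm in intersect(names(grid), c("n_days", "recurrent_nodes",
                                      "dense_nodes", "epochs"))) {
    hp[[nm]] <- as.integer(grid[[nm]][i_best])
  }
  attr(hp, "grid_table") <- cbind(grid, val_rmse = rmse)
  hp
}

#' Sensitivity variant: train without concentration inputs
#'
#' Same pipeline with the measured-trough feature removed from the feature
#' set (doses are retained).
#'
#' @param cohort training cohort.
#' @param family model family tag.
#' @param features the with-concentration [feature_set()] to strip.
#' @param hp a [hyper_params()].
#' @param seed RNG seed.
#' @return a `tacro_predictor` trained without the trough feature.
#' @export
no_concentration_variant <- function(cohort, family = "lstm",
                                     features = feature_set(),
                                     hp = hyper_params(), seed = 1) {
  fs <- feature_set(covariates = features$covariates, include_trough = FALSE)
  w <- cohort_windows(cohort, n_days = hp$n_days, features = fs)
  train_family(family, w, hp, seed)
}
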