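#' Clinician-style proportional dosing policy
#'
#' Empirical tacrolimus titration starts from a weight-based daily dose
#' (typically 0.1-0.15 mg/kg/day) and adjusts it by the target-to-current
#' trough concentration ratio, within a practical dose grid.
#'
#' @param initial_daily_mg_per_kg starting daily dose rate (mg/kg/day).
#' @param target_mid mid-point of the trough target range (ng/mL).
#' @param dose_step_mg dose rounding granularity (mg).
#' @param min_dose_mg,max_dose_mg bounds on the total daily dose (mg).
#' @return an object of class `dosing_policy`.
#' @export
dosing_policy <- function(initial_daily_mg_per_kg = 0.1, target_mid = 9,
                          dose_step_mg = 0.5, min_dose_mg = 0.5,
                          max_dose_mg = 20) {
  abort_if(initial_daily_mg_per_kg <= 0, "initial dose rate must be > 0")
  abort_if(min_dose_mg > max_dose_mg, "min_dose_mg must be <= max_dose_mg")
  abort_if(dose_step_mg <= 0, "dose_step_mg must be > 0")
  structure(list(initial_daily_mg_per_kg = initial_daily_mg_per_kg,
                 target_mid = target_mid, dose_step_mg = dose_step_mg,
                 min_dose_mg = min_dose_mg, max_dose_mg = max_dose_mg),
            class = "dosing_policy")
}

#' One titration step: proportional dose update from an observed trough
#'
#' `next = current * target / trough`, clipped to the policy bounds and
#' rounded to the dose grid. A non-positive (or missing) trough carries no
#' titration information, so the current dose is held.
#'
#' @param current_daily_dose current total daily dose (mg).
#' @param trough observed morning trough (ng/mL).
#' @param policy a [dosing_policy()].
#' @return next total daily dose (mg), a multiple of `dose_step_mg`.
#' @export
#' @examples
#' titration_step(6, 4.5, dosing_policy())  # doubles to 12
titration_step <- function(current_daily_dose, trough, policy = dosing_policy()) {
  if (!is.finite(trough) || trough <= 0) return(current_daily_dose)
  raw <- current_daily_dose * policy$target_mid / trough
  clamp(round_step(clamp(raw, policy$min_dose_mg, policy$max_dose_mg),
                   policy$dose_step_mg),
        policy$min_dose_mg, policy$max_dose_mg)
}

#' Phenomenological daily lab trajectory model
#'
#' Each lab gets an initial-value distribution and one of three dynamics:
#' `"decay"` (exponential relaxation toward a healthy baseline with
#' multiplicative noise — the post-transplant washout of AST/ALT/bilirubin/INR),
#' `"rise"` (slow relaxation upward — albumin recovering with graft synthetic
#' function) and `"meanrevert"` (an AR(1) walk around a set point —
#' creatinine, hematocrit). These are statistical stand-ins, not organ
#' physiology; they exist so that the covariates carry the qualitative
#' signal (AST falling through the 500 U/L clearance threshold, albumin and
#' hematocrit crossing their day-4 thresholds) the predictors are meant to
#' exploit.
#'
#' @param labs optional list overriding per-lab settings; see source for the
#'   fields of each entry (`init_median`, `init_cv`, `type`, `rate`,
#'   `baseline`/`setpoint`, `noise_cv`/`noise_sd`).
#' @return an object of class `covariate_model`.
#' @export
covariate_model <- function(labs = list()) {
  defaults <- list(
    ast        = list(init_median = 350, init_cv = 0.70, type = "decay",
                      rate = 0.30, baseline = 35, noise_cv = 0.15),
    alt        = list(init_median = 300, init_cv = 0.70, type = "decay",
                      rate = 0.20, baseline = 30, noise_cv = 0.15),
    tbil       = list(init_median = 5.0, init_cv = 0.60, type = "decay",
                      rate = 0.12, baseline = 0.9, noise_cv = 0.15),
    inr        = list(init_median = 1.8, init_cv = 0.25, type = "decay",
                      rate = 0.25, baseline = 1.05, noise_cv = 0.05),
    albumin    = list(init_median = 2.9, init_cv = 0.12, type = "rise",
                      rate = 0.10, baseline = 3.6, noise_sd = 0.12),
    creatinine = list(init_median = 1.0, init_cv = 0.35, type = "meanrevert",
                      rate = 0.25, setpoint = 1.1, noise_sd = 0.08),
    hematocrit = list(init_median = 30, init_cv = 0.12, type = "meanrevert",
                      rate = 0.30, setpoint = 32, noise_sd = 1.0)
  )
  for (nm in names(labs)) {
    abort_if(!nm %in% names(defaults), sprintf("unknown lab '%s'", nm))
    defaults[[nm]] <- utils::modifyList(defaults[[nm]], labs[[nm]])
  }
  structure(defaults, class = "covariate_model")
}

## simulate one lab trajectory over `horizon` days
simulate_lab <- function(spec, horizon) {
  x <- numeric(horizon)
  x[1] <- stats::rlnorm(1, log(spec$init_median), sdlog_from_cv(spec$init_cv))
  for (d in seq_len(horizon - 1L)) {
    x[d + 1] <- switch(spec$type,
      decay = {
        mu <- spec$baseline + (x[d] - spec$baseline) * exp(-spec$rate)
        mu * exp(stats::rnorm(1, 0, sdlog_from_cv(spec$noise_cv)))
      },
      rise = {
        mu <- spec$baseline + (x[d] - spec$baseline) * exp(-spec$rate)
        mu + stats::rnorm(1, 0, spec$noise_sd)
      },
      meanrevert = {
        x[d] + spec$rate * (spec$setpoint - x[d]) + stats::rnorm(1, 0, spec$noise_sd)
      },
      stop("unknown trajectory type"))
  }
  pmax(x, 1e-3)
}

#' Configuration of the synthetic post-transplant cohort generator
#'
#' Demographic defaults follow the derivation cohort's summary statistics
#' (age 55.6 (11.4) yr, height 165.1 (8.0) cm, weight 64.5 (14.7) kg,
#' 306/443 male). Inter-individual variability is a lognormal multiplier on
#' CL/F and V/F, residual error a proportional lognormal on observed troughs.
#'
#' @param n_patients number of patients; >= 1.
#' @param horizon_days follow-up length in post-operative days; >= 2.
#' @param seed integer RNG seed for [simulate_cohort()].
#' @param age_mean,age_sd,height_mean,height_sd,weight_mean,weight_sd
#'   demographic normal parameters.
#' @param male_fraction probability a patient is male.
#' @param iiv_cv fractional CV of the lognormal inter-individual multipliers
#'   on CL/F and V/F; >= 0.
#' @param residual_cv fractional proportional error on observed troughs; >= 0.
#' @param missing_rate_labs probability a lab value is masked missing on a
#'   given day; in [0, 1).
#' @param ka absorption rate constant (1/h) used by the simulating PK engine.
#' @param policy a [dosing_policy()].
#' @param covariates a [covariate_model()].
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_patients, horizon_days = 14, seed = 1,
                             age_mean = 55.6, age_sd = 11.4,
                             height_mean = 165.1, height_sd = 8.0,
                             weight_mean = 64.5, weight_sd = 14.7,
                             male_fraction = 306 / 443,
                             iiv_cv = 0.3, residual_cv = 0.15,
                             missing_rate_labs = 0.1,
                             ka = 4.5,
                             policy = dosing_policy(),
                             covariates = covariate_model()) {
  abort_if(!is.finite(n_patients) || n_patients < 1, "n_patients must be >= 1")
  abort_if(horizon_days < 2, "horizon_days must be >= 2")
  abort_if(iiv_cv < 0 || residual_cv < 0, "CVs must be >= 0")
  abort_if(missing_rate_labs < 0 || missing_rate_labs >= 1,
           "missing_rate_labs must be in [0, 1)")
  stopifnot(inherits(policy, "dosing_policy"), inherits(covariates, "covariate_model"))
  structure(list(n_patients = as.integer(n_patients),
                 horizon_days = as.integer(horizon_days), seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd,
                 height_mean = height_mean, height_sd = height_sd,
                 weight_mean = weight_mean, weight_sd = weight_sd,
                 male_fraction = male_fraction,
                 iiv_cv = iiv_cv, residual_cv = residual_cv,
                 missing_rate_labs = missing_rate_labs, ka = ka,
                 policy = policy, covariates = covariates),
            class = "generator_config")
}

## split a daily dose into morning/evening administrations on the step grid;
## the evening administration absorbs the remainder
split_daily_dose <- function(daily, step) {
  am <- step * floor(daily / (2 * step))
  c(am = am, pm = daily - am)
}

#' Simulate one post-transplant patient
#'
#' Twice-daily oral dosing starts on post-operative day 1 (09:00 and 21:00).
#' Each morning the trough is computed by the PK engine from the full prior
#' dose history at one minute before the morning dose, perturbed by
#' proportional residual error; the attending's next total daily dose is the
#' proportional [titration_step()] from that observed trough. Labs follow the
#' [covariate_model()] trajectories — and they steer the simulating PK
#' parameters through [piecewise_params()], so AST/albumin/hematocrit are
#' genuinely informative covariates. Lab values are masked missing at the
#' configured rate; doses and troughs are never masked (the day-1 trough,
#' drawn before any drug is on board, is recorded as not measured).
#'
#' Callers are responsible for RNG state; [simulate_cohort()] seeds it.
#'
#' @param config a [generator_config()].
#' @param patient_id identifier stored in the series.
#' @return an object of class `patient_series`: list with `patient_id`,
#'   `age`, `sex` (0 female / 1 male), `height_cm`, `iiv`, and `daily`, a
#'   data.frame with columns day, dose_am, dose_pm, trough, weight, ast, alt,
#'   tbil, inr, albumin, creatinine, hematocrit.
#' @export
simulate_patient <- function(config, patient_id = 1L) {
  H <- config$horizon_days
  pol <- config$policy

  age <- clamp(stats::rnorm(1, config$age_mean, config$age_sd), 18, 85)
  sex <- as.integer(stats::runif(1) < config$male_fraction)
  height <- clamp(stats::rnorm(1, config$height_mean, config$height_sd), 140, 195)
  weight <- clamp(stats::rnorm(1, config$weight_mean, config$weight_sd), 35, 130)
  iiv <- c(cl = rlnorm_mult(1, config$iiv_cv), v = rlnorm_mult(1, config$iiv_cv))

  labs <- vapply(config$covariates, simulate_lab, numeric(H), horizon = H)
  labs <- as.data.frame(labs)  # columns ast, alt, tbil, inr, albumin, creatinine, hematocrit
  labs$hematocrit <- clamp(labs$hematocrit, 5, 65)
  ctx <- data.frame(day = seq_len(H), ast = labs$ast, albumin = labs$albumin,
                    hematocrit = labs$hematocrit)

  daily <- numeric(H)
  dose_am <- numeric(H)
  dose_pm <- numeric(H)
  trough <- rep(NA_real_, H)
  dose_events <- data.frame(time = numeric(0), amount = numeric(0))
  sdl <- sdlog_from_cv(config$residual_cv)

  for (d in seq_len(H)) {
    ## morning trough from all doses so far
    t_sample <- (d - 1) * 24 + 9 - 1 / 60
    true_c <- concentration_at(dose_events, ctx, t_sample, ka = config$ka,
                               iiv = iiv, mode = "per_dose")
    abort_if(!is.finite(true_c),
             sprintf("non-finite simulated concentration (patient %s, day %d)",
                     patient_id, d))
    if (d > 1L) {
      trough[d] <- if (config$residual_cv > 0) {
        true_c * exp(stats::rnorm(1, 0, sdl))
      } else true_c
    }
    ## dose decision for today
    daily[d] <- if (d == 1L) {
      clamp(round_step(pol$initial_daily_mg_per_kg * weight, pol$dose_step_mg),
            pol$min_dose_mg, pol$max_dose_mg)
    } else {
      titration_step(daily[d - 1L], trough[d], pol)
    }
    sp <- split_daily_dose(daily[d], pol$dose_step_mg)
    dose_am[d] <- sp[["am"]]
    dose_pm[d] <- sp[["pm"]]
    new_ev <- data.frame(time = (d - 1) * 24 + c(9, 21),
                         amount = c(dose_am[d], dose_pm[d]))
    new_ev <- new_ev[new_ev$amount > 0, , drop = FALSE]
    dose_events <- rbind(dose_events, new_ev)
  }

  daily_df <- data.frame(day = seq_len(H), dose_am = dose_am, dose_pm = dose_pm,
                         trough = trough, weight = rep(weight, H),
                         ast = labs$ast, alt = labs$alt, tbil = labs$tbil,
                         inr = labs$inr, albumin = labs$albumin,
                         creatinine = labs$creatinine,
                         hematocrit = labs$hematocrit)
  ## MCAR lab masking
  if (config$missing_rate_labs > 0) {
    for (col in lab_columns()) {
      mask <- stats::runif(H) < config$missing_rate_labs
      daily_df[[col]][mask] <- NA_real_
    }
  }
  structure(list(patient_id = patient_id, age = age, sex = sex,
                 height_cm = height, iiv = iiv, daily = daily_df),
            class = "patient_series")
}

lab_columns <- function() c("ast", "alt", "tbil", "inr", "albumin",
                            "creatinine", "hematocrit")
dynamic_columns <- function() c("dose_am", "dose_pm", "trough", "weight",
                                lab_columns())

#' Simulate a cohort
#'
#' @param config a [generator_config()]; its `seed` fully determines the
#'   cohort — identical configs reproduce it bit-for-bit.
#' @return a list of `patient_series` with class `tacro_cohort` and the
#'   config stored as an attribute.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  cohort <- lapply(seq_len(config$n_patients),
                   function(i) simulate_patient(config, patient_id = i))
  structure(cohort, class = "tacro_cohort", config = config)
}

#' @export
print.patient_series <- function(x, ...) {
  cat(sprintf("<patient_series %s: age %.0f, %s, %.0f cm, %d days>\n",
              x$patient_id, x$age, if (x$sex == 1) "male" else "female",
              x$height_cm, nrow(x$daily)))
  invisible(x)
}

#' @export
print.tacro_cohort <- function(x, ...) {
  cat(sprintf("<tacro_cohort: %d patients x %d days>\n", length(x),
              if (length(x)) nrow(x[[1]]$daily) else 0L))
  invisible(x)
}
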