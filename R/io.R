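#' Write / read a cohort as long-format CSV
#'
#' Two files are written into `dir`: `daily.csv`, one row per patient-day
#' with columns patient_id, day, dose_am_mg, dose_pm_mg, trough_ng_ml, ast,
#' alt, tbil, inr, albumin, creatinine, hematocrit, weight_kg; and
#' `static.csv` with patient_id, age, sex, height_cm. Empty cells are
#' missing values. The round trip is lossless.
#'
#' @param cohort list of `patient_series`.
#' @param dir output directory (created if needed).
#' @return `write_cohort_csv` returns `dir` invisibly; `read_cohort_csv` the
#'   cohort.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(cohort) == 0L) {
    daily <- data.frame(patient_id = character(0), day = integer(0),
                        dose_am_mg = numeric(0), dose_pm_mg = numeric(0),
                        trough_ng_ml = numeric(0), ast = numeric(0),
                        alt = numeric(0), tbil = numeric(0), inr = numeric(0),
                        albumin = numeric(0), creatinine = numeric(0),
                        hematocrit = numeric(0), weight_kg = numeric(0))
    static <- data.frame(patient_id = character(0), age = numeric(0),
                         sex = integer(0), height_cm = numeric(0))
    utils::write.csv(daily, file.path(dir, "daily.csv"), row.names = FALSE, na = "")
    utils::write.csv(static, file.path(dir, "static.csv"), row.names = FALSE, na = "")
    return(invisible(dir))
  }
  daily <- do.call(rbind, lapply(cohort, function(s) {
    d <- s$daily
    data.frame(patient_id = s$patient_id, day = d$day,
               dose_am_mg = d$dose_am, dose_pm_mg = d$dose_pm,
               trough_ng_ml = d$trough, ast = d$ast, alt = d$alt,
               tbil = d$tbil, inr = d$inr, albumin = d$albumin,
               creatinine = d$creatinine, hematocrit = d$hematocrit,
               weight_kg = d$weight)
  }))
  static <- do.call(rbind, lapply(cohort, function(s)
    data.frame(patient_id = s$patient_id, age = s$age, sex = s$sex,
               height_cm = s$height_cm)))
  utils::write.csv(daily, file.path(dir, "daily.csv"), row.names = FALSE, na = "")
  utils::write.csv(static, file.path(dir, "static.csv"), row.names = FALSE, na = "")
  invisible(dir)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(dir) {
  daily_path <- file.path(dir, "daily.csv")
  static_path <- file.path(dir, "static.csv")
  abort_if(!file.exists(daily_path) || !file.exists(static_path),
           "expected daily.csv and static.csv in ", dir)
  daily <- utils::read.csv(daily_path)
  static <- utils::read.csv(static_path)
  if (nrow(daily) == 0L) {
    warning("empty cohort file", call. = FALSE)
    return(structure(list(), class = "tacro_cohort"))
  }
  required <- c("patient_id", "day", "dose_am_mg", "dose_pm_mg", "trough_ng_ml",
                "ast", "alt", "tbil", "inr", "albumin", "creatinine",
                "hematocrit", "weight_kg")
  missing_cols <- setdiff(required, names(daily))
  abort_if(length(missing_cols) > 0, "daily.csv lacks columns: ",
           paste(missing_cols, collapse = ", "))
  bad_dose <- which(daily$dose_am_mg < 0 | daily$dose_pm_mg < 0)
  abort_if(length(bad_dose) > 0,
           sprintf("negative dose in daily.csv at data line %d", bad_dose[1] + 1L))
  bad_trough <- which(!is.na(daily$trough_ng_ml) & daily$trough_ng_ml < 0)
  abort_if(length(bad_trough) > 0,
           sprintf("negative trough in daily.csv at data line %d", bad_trough[1] + 1L))
  cohort <- lapply(unique(daily$patient_id), function(pid) {
    d <- daily[daily$patient_id == pid, , drop = FALSE]
    d <- d[order(d$day), , drop = FALSE]
    abort_if(anyDuplicated(d$day) > 0,
             sprintf("duplicated day for patient %s", pid))
    st <- static[static$patient_id == pid, , drop = FALSE]
    abort_if(nrow(st) != 1L, sprintf("patient %s missing from static.csv", pid))
    structure(list(patient_id = pid, age = st$age, sex = st$sex,
                   height_cm = st$height_cm, iiv = c(cl = NA_real_, v = NA_real_),
                   daily = data.frame(day = d$day, dose_am = d$dose_am_mg,
                                      dose_pm = d$dose_pm_mg,
                                      trough = d$trough_ng_ml,
                                      weight = d$weight_kg, ast = d$ast,
                                      alt = d$alt, tbil = d$tbil, inr = d$inr,
                                      albumin = d$albumin,
                                      creatinine = d$creatinine,
                                      hematocrit = d$hematocrit)),
              class = "patient_series")
  })
  structure(cohort, class = "tacro_cohort")
}

## ---- eICU-shaped extraction -------------------------------------------

eicu_lab_map <- function() {
  c(ast = "^ast", alt = "^alt", tbil = "total bilirubin",
    inr = "^(pt - )?inr", albumin = "^albumin", creatinine = "^creatinine",
    hematocrit = "^hct|hematocrit")
}

#' Extract patient series from eICU-shaped relational tables
#'
#' Reproduces the external-validation extraction logic on tables shaped like
#' the eICU-CRD `patient`, `admissiondx`, `lab` and `medication` tables
#' (minute offsets from unit admission, stay-id joins). Kept are stays whose
#' admission diagnosis contains "liver transplant" (case-insensitive) with
#' age >= 15. Tacrolimus troughs are matched in the lab table by a
#' configurable case-insensitive pattern (default `"tacro|fk506"`); doses
#' come from medication rows matching the same drug pattern, excluding
#' sublingual and intravenous routes. A calendar day is a 1440-minute window
#' from offset 0; a dose row covers every day overlapped by its start/stop
#' offsets (morning administration if it starts before minute 720 of the
#' day, evening otherwise). Lab values land on the day of their result
#' offset. Days with neither a dose nor any data are dropped, as are
#' dose-only rows with missing amounts.
#'
#' @param tables named list of data.frames: `patient` (patientunitstayid,
#'   age, gender, admissionheight, admissionweight), `admissiondx`
#'   (patientunitstayid, admitdxname), `lab` (patientunitstayid, labname,
#'   labresult, labresultoffset), `medication` (patientunitstayid, drugname,
#'   dosage, routeadmin, drugstartoffset, drugstopoffset).
#' @param drug_pattern case-insensitive regex identifying tacrolimus rows.
#' @param max_days horizon cap in days.
#' @return a `tacro_cohort`.
#' @export
extract_eicu_series <- function(tables, drug_pattern = "tacro|fk506",
                                max_days = 14L) {
  req <- list(patient = c("patientunitstayid", "age", "gender",
                          "admissionheight", "admissionweight"),
              admissiondx = c("patientunitstayid", "admitdxname"),
              lab = c("patientunitstayid", "labname", "labresult",
                      "labresultoffset"),
              medication = c("patientunitstayid", "drugname", "dosage",
                             "routeadmin", "drugstartoffset", "drugstopoffset"))
  for (nm in names(req)) {
    abort_if(is.null(tables[[nm]]), "missing table: ", nm)
    lack <- setdiff(req[[nm]], names(tables[[nm]]))
    abort_if(length(lack) > 0,
             sprintf("table '%s' lacks columns: %s", nm,
                     paste(lack, collapse = ", ")))
  }
  pat <- tables$patient
  dx <- tables$admissiondx
  lt_ids <- unique(dx$patientunitstayid[grepl("liver transplant",
                                              dx$admitdxname, ignore.case = TRUE)])
  age_num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", as.character(pat$age))))
  keep_ids <- intersect(lt_ids, pat$patientunitstayid[!is.na(age_num) & age_num >= 15])

  lab <- tables$lab[tables$lab$patientunitstayid %in% keep_ids, , drop = FALSE]
  med <- tables$medication[tables$medication$patientunitstayid %in% keep_ids, , drop = FALSE]
  med <- med[grepl(drug_pattern, med$drugname, ignore.case = TRUE), , drop = FALSE]
  med <- med[!grepl("subling|intraven|\\biv\\b", med$routeadmin,
                    ignore.case = TRUE), , drop = FALSE]
  med$dose_mg <- suppressWarnings(as.numeric(gsub("[^0-9.]", "",
                                                  as.character(med$dosage))))
  med <- med[!is.na(med$dose_mg) & med$dose_mg > 0, , drop = FALSE]

  lmap <- eicu_lab_map()
  cohort <- lapply(keep_ids, function(id) {
    prow <- pat[pat$patientunitstayid == id, , drop = FALSE][1, ]
    daily <- data.frame(day = seq_len(max_days), dose_am = 0, dose_pm = 0,
                        trough = NA_real_,
                        weight = suppressWarnings(as.numeric(prow$admissionweight)),
                        ast = NA_real_, alt = NA_real_, tbil = NA_real_,
                        inr = NA_real_, albumin = NA_real_,
                        creatinine = NA_real_, hematocrit = NA_real_)
    ml <- lab[lab$patientunitstayid == id, , drop = FALSE]
    ml$day <- floor(ml$labresultoffset / 1440) + 1L
    ml <- ml[ml$day >= 1 & ml$day <= max_days & !is.na(ml$labresult), , drop = FALSE]
    for (i in seq_len(nrow(ml))) {
      nmlab <- as.character(ml$labname[i])
      d <- ml$day[i]
      if (grepl(drug_pattern, nmlab, ignore.case = TRUE)) {
        daily$trough[d] <- ml$labresult[i]
      } else {
        for (col in names(lmap)) {
          if (grepl(lmap[[col]], nmlab, ignore.case = TRUE)) {
            daily[[col]][d] <- ml$labresult[i]
            break
          }
        }
      }
    }
    mm <- med[med$patientunitstayid == id, , drop = FALSE]
    for (i in seq_len(nrow(mm))) {
      d0 <- floor(mm$drugstartoffset[i] / 1440) + 1L
      d1 <- floor(max(mm$drugstartoffset[i], mm$drugstopoffset[i] - 1) / 1440) + 1L
      for (d in max(1L, d0):min(max_days, d1)) {
        within_day <- mm$drugstartoffset[i] - (d - 1L) * 1440
        morning <- d > d0 || within_day < 720
        if (morning && daily$dose_am[d] == 0) {
          daily$dose_am[d] <- mm$dose_mg[i]
        } else {
          daily$dose_pm[d] <- mm$dose_mg[i]
        }
      }
    }
    has_data <- rowSums(!is.na(daily[, c("trough", lab_columns())])) > 0 |
      daily$dose_am > 0 | daily$dose_pm > 0
    if (!any(has_data)) return(NULL)
    daily <- daily[seq_len(max(which(has_data))), , drop = FALSE]
    sex <- as.integer(grepl("^m", as.character(prow$gender), ignore.case = TRUE))
    structure(list(patient_id = id,
                   age = suppressWarnings(as.numeric(gsub("[^0-9.]", "",
                                                          as.character(prow$age)))),
                   sex = sex,
                   height_cm = suppressWarnings(as.numeric(prow$admissionheight)),
                   iiv = c(cl = NA_real_, v = NA_real_), daily = daily),
              class = "patient_series")
  })
  cohort <- cohort[!vapply(cohort, is.null, logical(1))]
  structure(cohort, class = "tacro_cohort")
}

#' Export a cohort to eICU-shaped tables (synthetic stand-in)
#'
#' Writes a synthetic cohort into the four-table relational layout that
#' [extract_eicu_series()] reads, for round-trip testing and fixture
#' generation. Morning administrations are encoded at offset 540 min of
#' their day, evening at 1260; labs and troughs at the morning offset.
#'
#' @param cohort list of `patient_series`.
#' @return named list of the four data.frames.
#' @export
export_eicu_tables <- function(cohort) {
  patient <- do.call(rbind, lapply(cohort, function(s)
    data.frame(patientunitstayid = s$patient_id, age = s$age,
               gender = if (s$sex == 1) "Male" else "Female",
               admissionheight = s$height_cm,
               admissionweight = s$daily$weight[1])))
  admissiondx <- do.call(rbind, lapply(cohort, function(s)
    data.frame(patientunitstayid = s$patient_id,
               admitdxname = "Liver transplantation")))
  lab_rows <- list()
  med_rows <- list()
  lab_names <- c(ast = "AST (SGOT)", alt = "ALT (SGPT)",
                 tbil = "total bilirubin", inr = "PT - INR",
                 albumin = "albumin", creatinine = "creatinine",
                 hematocrit = "Hct")
  for (s in cohort) {
    d <- s$daily
    for (r in seq_len(nrow(d))) {
      off <- (d$day[r] - 1L) * 1440 + 540
      if (!is.na(d$trough[r])) {
        lab_rows[[length(lab_rows) + 1L]] <- data.frame(
          patientunitstayid = s$patient_id, labname = "Tacrolimus-FK506",
          labresult = d$trough[r], labresultoffset = off)
      }
      for (col in names(lab_names)) {
        if (!is.na(d[[col]][r])) {
          lab_rows[[length(lab_rows) + 1L]] <- data.frame(
            patientunitstayid = s$patient_id, labname = lab_names[[col]],
            labresult = d[[col]][r], labresultoffset = off)
        }
      }
      if (d$dose_am[r] > 0) {
        med_rows[[length(med_rows) + 1L]] <- data.frame(
          patientunitstayid = s$patient_id, drugname = "TACROLIMUS",
          dosage = sprintf("%g mg", d$dose_am[r]), routeadmin = "PO",
          drugstartoffset = (d$day[r] - 1L) * 1440 + 540,
          drugstopoffset = (d$day[r] - 1L) * 1440 + 570)
      }
      if (d$dose_pm[r] > 0) {
        med_rows[[length(med_rows) + 1L]] <- data.frame(
          patientunitstayid = s$patient_id, drugname = "TACROLIMUS",
          dosage = sprintf("%g mg", d$dose_pm[r]), routeadmin = "PO",
          drugstartoffset = (d$day[r] - 1L) * 1440 + 1260,
          drugstopoffset = (d$day[r] - 1L) * 1440 + 1290)
      }
    }
  }
  list(patient = patient, admissiondx = admissiondx,
       lab = do.call(rbind, lab_rows), medication = do.call(rbind, med_rows))
}
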