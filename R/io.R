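# collect row-level problems and fail with line numbers (line 1 = header)
fail_rows <- function(problems, path) {
  if (length(problems) == 0) return(invisible(NULL))
  stop_domain("invalid rows in '", path, "':\n  ",
              paste(problems, collapse = "\n  "))
}

#' Read a patient covariate table
#'
#' CSV with header and columns `patient_id`, `age` (years), `height` (cm),
#' `weight` (kg), `diplotype` (e.g. `"*1/*4"`); an optional `activity`
#' column overrides the diplotype-derived score. Malformed rows are
#' reported with their file line numbers; duplicate ids are an error.
#'
#' @param path CSV file path.
#' @return data frame of typed patient records (with a `bmi` column added).
#' @export
read_patients <- function(path) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "height", "weight", "diplotype")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop_domain("missing columns in '", path, "': ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) {
    df$bmi <- numeric(0)
    return(df)
  }
  df$patient_id <- as.character(df$patient_id)
  dup <- duplicated(df$patient_id)
  if (any(dup)) {
    stop_domain("duplicate patient_id in '", path, "': ",
                paste(unique(df$patient_id[dup]), collapse = ", "))
  }
  problems <- character(0)
  line <- seq_len(nrow(df)) + 1L
  for (col in c("age", "height", "weight")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) | v <= 0
    if (any(bad)) {
      problems <- c(problems, sprintf("line %d: %s must be a positive number (got '%s')",
                                      line[bad], col, df[[col]][bad]))
    }
    df[[col]] <- v
  }
  if ("activity" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$activity))
    bad <- !is.na(df$activity) & (is.na(v) | v < 0)
    if (any(bad)) {
      problems <- c(problems, sprintf("line %d: activity must be a number >= 0",
                                      line[bad]))
    }
    df$activity <- v
  }
  fail_rows(problems, path)
  # diplotype syntax is validated here; allele-table membership at scoring time
  parse_diplotype(df$diplotype)
  df$bmi <- df$weight / (df$height / 100)^2
  df
}

#' Read an endoxifen observation table
#'
#' CSV with header and columns `patient_id`, `day` (days since treatment
#' start), `dose_mg`, and either `concentration_nM` or
#' `concentration_ng_ml` (converted to nM on read using the configured
#' molar mass). All concentrations are held in nM internally.
#'
#' @param path CSV file path.
#' @param mw molar mass (g/mol) for ng/mL input.
#' @return data frame with columns `patient_id`, `day`, `concentration`
#'   (nM), `dose`.
#' @export
read_observations <- function(path, mw = 373.5) {
  if (!file.exists(path)) stop_domain("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  conc_col <- intersect(c("concentration_nM", "concentration_ng_ml"), names(df))
  need <- c("patient_id", "day", "dose_mg")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0 || length(conc_col) == 0) {
    stop_domain("missing columns in '", path, "': ",
                paste(c(miss, if (length(conc_col) == 0)
                  "concentration_nM (or concentration_ng_ml)"), collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(data.frame(patient_id = character(0), day = numeric(0),
                      concentration = numeric(0), dose = numeric(0)))
  }
  conc_col <- conc_col[1]
  problems <- character(0)
  line <- seq_len(nrow(df)) + 1L
  day <- suppressWarnings(as.numeric(df$day))
  bad <- is.na(day) | day < 0
  if (any(bad)) problems <- c(problems,
    sprintf("line %d: day must be a number >= 0", line[bad]))
  conc <- suppressWarnings(as.numeric(df[[conc_col]]))
  bad <- is.na(conc) | conc < 0
  if (any(bad)) problems <- c(problems,
    sprintf("line %d: concentration must be a number >= 0", line[bad]))
  dose <- suppressWarnings(as.numeric(df$dose_mg))
  bad <- is.na(dose) | dose <= 0
  if (any(bad)) problems <- c(problems,
    sprintf("line %d: dose_mg must be a positive number", line[bad]))
  fail_rows(problems, path)
  if (conc_col == "concentration_ng_ml") conc <- ngml_to_nm(conc, mw)
  data.frame(patient_id = as.character(df$patient_id), day = day,
             concentration = conc, dose = dose, stringsAsFactors = FALSE)
}

#' Run the full MIPD workflow on patient and observation tables
#'
#' For every patient: derive the CYP2D6 activity score, predict the
#' steady-state endoxifen concentration at 20 mg, recommend an a-priori
#' dose; if timed samples exist, compute the empirical-Bayes update and the
#' updated recommendation (advisory when only early, uninformative samples
#' exist); and, when a steady-state sample (day >= `steady_state_day`) is
#' present, classify target attainment. Dose changes between the a-priori
#' and updated recommendation are logged as messages. The pipeline is a
#' pure function of its inputs and configuration.
#'
#' @param patients data frame from [read_patients()].
#' @param observations optional data frame from [read_observations()].
#' @param config configuration list, see [load_config()].
#' @return object of class `mipd_report`: `patients` (per-patient results),
#'   `by_category` and `by_bin` sub-therapeutic tables over patients with a
#'   steady-state sample, and the `config` echo (including any seed).
#' @export
run_pipeline <- function(patients, observations = NULL,
                         config = default_config()) {
  model <- model_from_config(config)
  table <- alleles_from_config(config)
  thr <- config$thresholds
  if (!is.null(observations) && nrow(observations) > 0) {
    unknown <- setdiff(unique(observations$patient_id), patients$patient_id)
    if (length(unknown) > 0) {
      stop_domain("observations reference unknown patient ids: ",
                  paste(unknown, collapse = ", "))
    }
  }
  activity <- if ("activity" %in% names(patients) &&
                 any(!is.na(patients$activity))) {
    ifelse(is.na(patients$activity),
           activity_score(patients$diplotype, table), patients$activity)
  } else {
    activity_score(patients$diplotype, table)
  }
  css20 <- predict_css(model, dose = 20, activity = activity,
                       age = patients$age, bmi = patients$bmi,
                       height = patients$height)
  rec <- recommend_dose(css20, threshold = thr$target_nM,
                        margin = thr$margin,
                        upper_threshold = thr$upper_nM)
  out <- data.frame(
    patient_id = patients$patient_id,
    activity = activity,
    bin = assign_bin(activity),
    css20_pred = css20,
    category = rec$category,
    administered_dose = rec$administered_dose,
    css20_updated = NA_real_,
    category_updated = factor(NA, levels = dose_categories()),
    informative = NA,
    steady_state_conc = NA_real_,
    attained = NA,
    stringsAsFactors = FALSE
  )
  if (!is.null(observations) && nrow(observations) > 0) {
    for (i in seq_len(nrow(out))) {
      obs_i <- observations[observations$patient_id == out$patient_id[i] &
                              observations$day > 0 &
                              observations$concentration > 0, , drop = FALSE]
      if (nrow(obs_i) > 0) {
        obs_i <- data.frame(time = obs_i$day,
                            concentration = obs_i$concentration,
                            dose = obs_i$dose)
        ebe <- estimate_eta(model, obs_i, activity = activity[i],
                            age = patients$age[i], bmi = patients$bmi[i],
                            height = patients$height[i],
                            informative_cutoff = thr$informative_cutoff_days)
        upd <- update_recommendation(ebe, threshold = thr$target_nM,
                                     margin = thr$margin)
        out$css20_updated[i] <- ebe$css20_updated
        out$category_updated[i] <- upd$category
        out$informative[i] <- ebe$informative
        if (ebe$informative && upd$category != out$category[i]) {
          message(sprintf("dose change for %s: %s -> %s", out$patient_id[i],
                          out$category[i], upd$category))
        }
      }
      ss <- observations[observations$patient_id == out$patient_id[i] &
                           observations$day >= thr$steady_state_day, ,
                         drop = FALSE]
      if (nrow(ss) > 0) {
        last <- ss[which.max(ss$day), ]
        out$steady_state_conc[i] <- last$concentration
        out$attained[i] <- classify_attainment(last$concentration,
                                               thr$target_nM)
      }
    }
  }
  has_ss <- !is.na(out$attained)
  structure(list(
    patients = out,
    by_category = if (any(has_ss))
      attainment_table(out$steady_state_conc[has_ss], out$category[has_ss],
                       thr$target_nM) else NULL,
    by_bin = if (any(has_ss))
      attainment_table(out$steady_state_conc[has_ss], out$bin[has_ss],
                       thr$target_nM) else NULL,
    n = nrow(out),
    n_steady_state = sum(has_ss),
    threshold = thr$target_nM,
    seed = config$simulation$seed
  ), class = "mipd_report")
}

#' @export
print.mipd_report <- function(x, ...) {
  cat(sprintf("MIPD report: %d patients (%d with a steady-state sample)\n",
              x$n, x$n_steady_state))
  print(utils::head(x$patients, 10), row.names = FALSE)
  if (x$n > 10) cat("  ...\n")
  invisible(x)
}

#' Write a pipeline report to JSON
#'
#' Stable key ordering, `NA` rendered as null, numbers unrounded.
#'
#' @param report an `mipd_report` (or any list).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE, dataframe = "rows")
  invisible(path)
}
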