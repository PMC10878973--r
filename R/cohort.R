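# Longitudinal visit tables, DR state classification, and derivation of
# interval-censored survival records.
#
# Grades follow the International Clinical Diabetic Retinopathy Disease
# Severity Scale (ICDRDSS): 0 none, 1 mild NPDR, 2 moderate NPDR,
# 3 severe NPDR, 4 PDR. DME is carried as a separate boolean.

#' Baseline metadata covariate names
#'
#' The twelve baseline covariates used by the metadata model: age, sex,
#' smoking status, duration of diabetes, baseline DR grade, body-mass index,
#' HbA1c, systolic and diastolic blood pressure, triglycerides, LDL and HDL
#' cholesterol. `sex` and `smoker` are binary; all others are continuous
#' (baseline DR grade is treated as a numeric severity score).
#'
#' @return Character vector of length 12.
#' @export
covariate_fields <- function() {
  c("age", "sex", "smoker", "duration_dm", "baseline_dr_grade",
    "bmi", "hba1c", "sbp", "dbp", "tg", "ldl", "hdl")
}

binary_covariates <- function() c("sex", "smoker")

#' Construct a single eye exam
#'
#' @param time Years since baseline, non-negative.
#' @param dr_grade ICDRDSS grade, integer 0-4.
#' @param dme Logical, diabetic macular edema present.
#' @return A `dr_visit` list.
#' @export
visit <- function(time, dr_grade, dme = FALSE) {
  check_number(time, "time", lower = 0)
  check_grade(dr_grade)
  abort_if(!is.logical(dme) || length(dme) != 1L || is.na(dme),
           "`dme` must be TRUE or FALSE")
  structure(list(time = as.numeric(time), dr_grade = as.integer(dr_grade),
                 dme = dme), class = "dr_visit")
}

check_grade <- function(grade) {
  abort_if(!is.numeric(grade) || any(is.na(grade)) ||
             any(grade != as.integer(grade)) ||
             any(grade < 0) || any(grade > 4),
           "`dr_grade` must be an integer in 0..4")
  invisible(grade)
}

#' Classify an eye's DR state
#'
#' Maps an ICDRDSS grade plus DME flag to the study's three nested disease
#' states: any DR (grade >= 1), referable DR (moderate NPDR or worse, and/or
#' DME), and vision-threatening DR (severe NPDR, PDR and/or DME).
#'
#' @param grade ICDRDSS grade(s), integer 0-4 (vectorized).
#' @param dme Logical DME flag(s), recycled against `grade`.
#' @return A data.frame with logical columns `has_dr`, `referable`, `vtdr`.
#' @examples
#' classify_state(2, FALSE)  # referable, not vision-threatening
#' classify_state(1, TRUE)   # DME alone confers VTDR
#' @export
classify_state <- function(grade, dme = FALSE) {
  check_grade(grade)
  n <- max(length(grade), length(dme))
  grade <- rep_len(as.integer(grade), n)
  dme <- rep_len(as.logical(dme), n)
  data.frame(has_dr = grade >= 1L,
             referable = grade >= 2L | dme,
             vtdr = grade >= 3L | dme)
}

#' Progression endpoint definitions
#'
#' @param kind One of `"any"` (first deterioration of DR grade or new onset of
#'   DME), `"incident_dr"`, `"incident_referable"`, `"incident_vtdr"`
#'   (first attainment of the corresponding state).
#' @return An `endpoint_definition` object.
#' @export
endpoint_definition <- function(kind = c("any", "incident_dr",
                                         "incident_referable",
                                         "incident_vtdr")) {
  kind <- match.arg(kind)
  structure(list(kind = kind), class = "endpoint_definition")
}

as_endpoint <- function(x) {
  if (inherits(x, "endpoint_definition")) x else endpoint_definition(x)
}

as_visit <- function(x) {
  if (inherits(x, "dr_visit")) return(x)
  abort_if(is.null(x$dr_grade), "a visit needs a `dr_grade`")
  visit(x$time %||% 0, x$dr_grade, isTRUE(as.logical(x$dme)))
}

#' Has an eye progressed between two exams?
#'
#' Progression under the `"any"` endpoint is the first deterioration of DR
#' grade or new onset of DME relative to baseline. The incident endpoints
#' test whether the later exam has reached the corresponding state,
#' regardless of the baseline grade.
#'
#' @param baseline,later Visits (see [visit()]); `later` must be after
#'   `baseline`.
#' @param definition An [endpoint_definition()] or its kind string.
#' @return Logical scalar.
#' @export
has_progressed <- function(baseline, later, definition = "any") {
  baseline <- as_visit(baseline); later <- as_visit(later)
  definition <- as_endpoint(definition)
  abort_if(later$time <= baseline$time,
           "`later` visit must be after `baseline`")
  st <- classify_state(later$dr_grade, later$dme)
  switch(definition$kind,
         any = later$dr_grade > baseline$dr_grade ||
           (later$dme && !baseline$dme),
         incident_dr = st$has_dr,
         incident_referable = st$referable,
         incident_vtdr = st$vtdr)
}

#' Is a baseline exam eligible for an endpoint?
#'
#' Incident endpoints require the baseline to be free of the target state.
#' Under `"any"`, only an eye already at PDR with DME is ineligible (no
#' further deterioration is possible).
#'
#' @inheritParams has_progressed
#' @return Logical scalar.
#' @export
is_eligible <- function(baseline, definition = "any") {
  baseline <- as_visit(baseline)
  definition <- as_endpoint(definition)
  st <- classify_state(baseline$dr_grade, baseline$dme)
  switch(definition$kind,
         any = !(baseline$dr_grade == 4L && baseline$dme),
         incident_dr = !st$has_dr,
         incident_referable = !st$referable,
         incident_vtdr = !st$vtdr)
}

#' Build a visit series for one eye
#'
#' @param participant_id Participant identifier (string).
#' @param eye `"OD"` or `"OS"`.
#' @param visits A data.frame with columns `time`, `dr_grade`, `dme`,
#'   strictly increasing in `time`, first row at time 0 (the baseline exam).
#' @param covariates Named list or vector holding the 12 baseline covariates
#'   (see [covariate_fields()]); missing values are allowed.
#' @return A `visit_series` object.
#' @export
visit_series <- function(participant_id, eye, visits, covariates) {
  abort_if(!eye %in% c("OD", "OS"), "`eye` must be \"OD\" or \"OS\"")
  abort_if(!is.data.frame(visits) ||
             !all(c("time", "dr_grade", "dme") %in% names(visits)),
           "`visits` needs columns time, dr_grade, dme")
  abort_if(nrow(visits) < 1L, "`visits` must not be empty")
  abort_if(any(diff(visits$time) <= 0),
           "visit times must be strictly increasing")
  abort_if(visits$time[1L] != 0,
           "a baseline visit at time 0 is required")
  check_grade(visits$dr_grade)
  cov <- as.list(covariates)
  missing_fields <- setdiff(covariate_fields(), names(cov))
  abort_if(length(missing_fields) > 0,
           paste("missing covariates:", paste(missing_fields, collapse = ", ")))
  cov <- cov[covariate_fields()]
  structure(list(participant_id = as.character(participant_id), eye = eye,
                 visits = visits[c("time", "dr_grade", "dme")],
                 covariates = cov),
            class = "visit_series")
}

#' Derive one interval-censored survival record from a visit series
#'
#' Scans the exams in order for the first visit at which the endpoint's
#' progression predicate holds. If found, the record is an event (`event = 1`)
#' with `t` the time of the last exam before progression and `t_prime` the
#' exam at which it was observed; otherwise the eye is right-censored at its
#' last exam (`t = t_prime`, `event = 0`).
#'
#' @param series A [visit_series()].
#' @param definition Endpoint (see [endpoint_definition()]).
#' @param feature_map Optional function mapping the covariate list to a
#'   numeric feature vector (e.g. an encoder from [fit_feature_encoder()]).
#' @return A one-row data.frame with columns `participant_id`, `eye`, `t`,
#'   `t_prime`, `event` (plus encoded feature columns when `feature_map` is
#'   supplied), or `NULL` when the baseline is ineligible for the endpoint.
#' @export
derive_survival_record <- function(series, definition = "any",
                                   feature_map = NULL) {
  abort_if(!inherits(series, "visit_series"), "`series` must be a visit_series")
  definition <- as_endpoint(definition)
  v <- series$visits
  abort_if(nrow(v) < 2L,
           sprintf("series %s/%s has a single visit: no follow-up to derive from",
                   series$participant_id, series$eye))
  baseline <- visit(v$time[1L], v$dr_grade[1L], as.logical(v$dme[1L]))
  if (!is_eligible(baseline, definition)) return(NULL)
  k <- NA_integer_
  for (i in seq_len(nrow(v))[-1L]) {
    if (has_progressed(baseline, visit(v$time[i], v$dr_grade[i],
                                       as.logical(v$dme[i])), definition)) {
      k <- i
      break
    }
  }
  if (is.na(k)) {
    t <- t_prime <- v$time[nrow(v)]
    e <- 0L
  } else {
    t <- v$time[k - 1L]
    t_prime <- v$time[k]
    e <- 1L
  }
  rec <- data.frame(participant_id = series$participant_id, eye = series$eye,
                    t = as.double(t), t_prime = as.double(t_prime), event = e,
                    stringsAsFactors = FALSE)
  if (!is.null(feature_map)) {
    x <- feature_map(series$covariates)
    feat <- as.data.frame(as.list(as.numeric(x)))
    names(feat) <- paste0("f", seq_along(x) - 1L)
    rec <- cbind(rec, feat)
  }
  rec
}

#' Split a visits table into per-eye series
#'
#' @param visits A visits data.frame as returned by [read_visits_csv()] or
#'   [simulate_cohort()].
#' @return List of [visit_series()] objects, ordered by participant and eye.
#' @export
visit_series_list <- function(visits) {
  abort_if(!is.data.frame(visits), "`visits` must be a data.frame")
  key <- interaction(visits$participant_id, visits$eye, drop = TRUE, sep = "/")
  idx <- split(seq_len(nrow(visits)), key)
  out <- lapply(idx, function(i) {
    rows <- visits[i, , drop = FALSE]
    rows <- rows[order(rows$exam_time_years), , drop = FALSE]
    visit_series(rows$participant_id[1L], rows$eye[1L],
                 data.frame(time = rows$exam_time_years,
                            dr_grade = rows$dr_grade,
                            dme = as.logical(rows$dme)),
                 as.list(rows[1L, covariate_fields()]))
  })
  ord <- order(vapply(out, function(s) s$participant_id, ""),
               vapply(out, function(s) s$eye, ""))
  unname(out[ord])
}

#' Derive survival records for a whole cohort
#'
#' Applies [derive_survival_record()] to every eye in a visits table,
#' dropping baseline-ineligible eyes.
#'
#' @inheritParams visit_series_list
#' @param definition Endpoint (see [endpoint_definition()]).
#' @param encoder Optional `feature_encoder` from [fit_feature_encoder()];
#'   when supplied the records carry encoded feature columns `f0..f{d-1}`.
#' @return A data.frame of survival records, one row per eligible eye.
#' @export
derive_records <- function(visits, definition = "any", encoder = NULL) {
  series <- visit_series_list(visits)
  fm <- if (!is.null(encoder)) {
    function(cov) encode_covariates(encoder, as.data.frame(cov))[1L, ]
  }
  recs <- lapply(series, derive_survival_record, definition = definition,
                 feature_map = fm)
  recs <- recs[!vapply(recs, is.null, TRUE)]
  abort_if(length(recs) == 0, "no eligible eyes for this endpoint")
  do.call(rbind, recs)
}

# ---- feature encoding -------------------------------------------------------

#' Fit a covariate encoder on a training split
#'
#' Continuous covariates are median-imputed and z-scored; binary covariates
#' (`sex`, `smoker`) are mode-imputed and mapped to 0/1. All statistics come
#' from the supplied (training) data only, so the encoder can be applied to
#' held-out data without leakage.
#'
#' @param covariates Data.frame containing the columns of
#'   [covariate_fields()] (extra columns ignored).
#' @return A `feature_encoder` object.
#' @export
fit_feature_encoder <- function(covariates) {
  fields <- covariate_fields()
  abort_if(!all(fields %in% names(covariates)),
           paste("missing covariates:",
                 paste(setdiff(fields, names(covariates)), collapse = ", ")))
  bin <- binary_covariates()
  stats <- lapply(fields, function(f) {
    x <- covariates[[f]]
    if (f %in% bin) {
      x <- as.numeric(x)
      tab <- table(x[!is.na(x)])
      mode_val <- if (length(tab)) as.numeric(names(tab)[which.max(tab)]) else 0
      list(type = "binary", impute = mode_val)
    } else {
      x <- as.numeric(x)
      med <- stats::median(x, na.rm = TRUE)
      filled <- ifelse(is.na(x), med, x)
      s <- stats::sd(filled)
      list(type = "continuous", impute = med, mean = mean(filled),
           sd = if (is.na(s) || s < 1e-12) 1 else s)
    }
  })
  names(stats) <- fields
  structure(list(fields = fields, stats = stats), class = "feature_encoder")
}

#' Encode covariates to the model feature matrix
#'
#' @param encoder A `feature_encoder` from [fit_feature_encoder()].
#' @param covariates Data.frame with the covariate columns.
#' @return Numeric matrix, one row per input row, columns `f0..f{d-1}`.
#' @export
encode_covariates <- function(encoder, covariates) {
  abort_if(!inherits(encoder, "feature_encoder"),
           "`encoder` must come from fit_feature_encoder()")
  cols <- lapply(encoder$fields, function(f) {
    st <- encoder$stats[[f]]
    x <- as.numeric(covariates[[f]])
    x[is.na(x)] <- st$impute
    if (st$type == "binary") as.numeric(x != 0) else (x - st$mean) / st$sd
  })
  m <- do.call(cbind, cols)
  colnames(m) <- paste0("f", seq_along(encoder$fields) - 1L)
  m
}

#' Extract the feature matrix from a records data.frame
#'
#' @param records Records with feature columns `f0..f{d-1}`.
#' @return Numeric matrix.
#' @export
record_features <- function(records) {
  fcols <- grep("^f[0-9]+$", names(records), value = TRUE)
  abort_if(length(fcols) == 0, "records carry no feature columns f0..f{d-1}")
  fcols <- fcols[order(as.integer(sub("^f", "", fcols)))]
  as.matrix(records[fcols])
}

# ---- CSV schemas ------------------------------------------------------------

visits_required_cols <- function() {
  c("participant_id", "eye", "exam_time_years", "dr_grade", "dme",
    covariate_fields())
}

#' Read a longitudinal visits table
#'
#' The file must carry a header with columns `participant_id`, `eye`,
#' `exam_time_years`, `dr_grade`, `dme`, then the twelve covariate columns
#' (see [covariate_fields()]). Unknown columns are preserved in the returned
#' data.frame but ignored downstream. Malformed rows are reported with their
#' file line numbers.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A validated visits data.frame.
#' @export
read_visits_csv <- function(path) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(visits_required_cols(), names(df))
  abort_if(length(missing) > 0,
           sprintf("%s: missing required column(s): %s", path,
                   paste(missing, collapse = ", ")))
  if (nrow(df) == 0) return(df)
  df$dme <- as.logical(df$dme)
  bad <- which(!is.finite(df$exam_time_years) | df$exam_time_years < 0 |
                 is.na(df$dr_grade) | df$dr_grade %% 1 != 0 |
                 df$dr_grade < 0 | df$dr_grade > 4 | is.na(df$dme))
  abort_if(length(bad) > 0,
           sprintf("%s: malformed row(s) at file line(s) %s", path,
                   paste(bad + 1L, collapse = ", ")))
  df$dr_grade <- as.integer(df$dr_grade)
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Write a visits table
#' @param visits Visits data.frame.
#' @param path Output path.
#' @export
write_visits_csv <- function(visits, path) {
  out <- visits
  for (col in c("exam_time_years", covariate_fields())) {
    if (is.numeric(out[[col]]) && col != "dr_grade") {
      out[[col]] <- format_double(out[[col]])
    }
  }
  out$dme <- as.logical(visits$dme)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write survival records
#'
#' Columns: `participant_id`, `eye`, `t`, `t_prime`, `event`, then feature
#' columns `f0..f{d-1}`. Doubles are written with 17 significant digits so a
#' write/read round-trip is lossless.
#'
#' @param records Records data.frame.
#' @param path Output path.
#' @export
write_records_csv <- function(records, path) {
  out <- records
  for (col in names(out)) {
    if (is.double(out[[col]])) out[[col]] <- format_double(out[[col]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read survival records
#' @param path Path to a records CSV written by [write_records_csv()].
#' @return Records data.frame.
#' @export
read_records_csv <- function(path) {
  abort_if(!file.exists(path), sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("participant_id", "eye", "t", "t_prime", "event")
  missing <- setdiff(required, names(df))
  abort_if(length(missing) > 0,
           sprintf("%s: missing required column(s): %s", path,
                   paste(missing, collapse = ", ")))
  if (nrow(df) == 0) return(df)
  bad <- which(!is.finite(df$t) | !is.finite(df$t_prime) |
                 df$t < 0 | df$t > df$t_prime |
                 !df$event %in% c(0L, 1L) |
                 (df$event == 0L & df$t != df$t_prime) |
                 (df$event == 1L & df$t >= df$t_prime))
  abort_if(length(bad) > 0,
           sprintf("%s: malformed row(s) at file line(s) %s", path,
                   paste(bad + 1L, collapse = ", ")))
  df$participant_id <- as.character(df$participant_id)
  df$event <- as.integer(df$event)
  for (col in grep("^f[0-9]+$", names(df), value = TRUE)) {
    df[[col]] <- as.double(df[[col]])
  }
  df$t <- as.double(df$t)
  df$t_prime <- as.double(df$t_prime)
  df
}
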