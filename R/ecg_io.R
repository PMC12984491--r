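#' Construct a 12-lead ECG record
#'
#' Container for a single resting ECG: the 12 named lead series in mV, the
#' sampling rate, and optional machine-report metadata.  If only the 8
#' linearly independent leads (I, II, V1--V6) are supplied the augmented
#' limb leads are derived by Einthoven/Goldberger algebra.
#'
#' @param leads named list (or matrix with column names) of numeric lead
#'   series in mV; names must cover the 8 independent leads and may include
#'   the derived ones.
#' @param fs sampling rate in Hz (positive).
#' @param record_id,patient_id identifiers.
#' @param report_text optional machine-report text.
#' @param machine_numeric optional named numeric vector of machine
#'   measurements (e.g. machine QRS duration, axis).
#' @param machine_flags optional named logical vector of machine Boolean
#'   flags (e.g. left-ventricular-hypertrophy).
#' @param label optional phenotype label.
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(leads, fs, record_id = "record", patient_id = record_id,
                       report_text = NULL, machine_numeric = NULL,
                       machine_flags = NULL, label = NA_character_) {
  if (is.matrix(leads) || is.data.frame(leads)) {
    leads <- as.list(as.data.frame(leads))
  }
  stopifnot(is.list(leads), !is.null(names(leads)))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("sampling rate must be a positive scalar")
  }
  indep <- vcg_independent_leads()
  missing_leads <- setdiff(indep, names(leads))
  if (length(missing_leads)) {
    stop("lead ", paste(missing_leads, collapse = ", "), " absent")
  }
  lens <- vapply(leads[indep], length, integer(1))
  if (length(unique(lens)) != 1L) stop("lead series have unequal lengths")
  if (!all(vapply(leads[indep], function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite amplitude values")
  }
  derived <- setdiff(vcg_lead_names(), indep)
  if (!all(derived %in% names(leads))) {
    aug <- derive_augmented_leads(leads[["I"]], leads[["II"]])
    leads[derived] <- aug[derived]
  }
  leads <- leads[vcg_lead_names()]
  structure(
    list(record_id = record_id, patient_id = patient_id,
         sampling_rate = fs, leads = leads, report_text = report_text,
         machine_numeric = machine_numeric, machine_flags = machine_flags,
         label = label),
    class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- length(x$leads[[1L]])
  cat(sprintf("<ecg_record %s> %d leads, %.1f s @ %g Hz, label=%s\n",
              x$record_id, length(x$leads), n / x$sampling_rate,
              x$sampling_rate,
              if (is.na(x$label)) "?" else x$label))
  invisible(x)
}

#' Derive the augmented limb leads
#'
#' Standard limb-lead algebra: III = II - I, aVR = -(I+II)/2,
#' aVL = I - II/2, aVF = II - I/2.
#'
#' @param leadI,leadII numeric series in mV, equal length.
#' @return named list with components `III`, `aVR`, `aVL`, `aVF`.
#' @export
derive_augmented_leads <- function(leadI, leadII) {
  if (length(leadI) != length(leadII)) {
    stop("lead I and lead II have different lengths")
  }
  list(III = leadII - leadI,
       aVR = -(leadI + leadII) / 2,
       aVL = leadI - leadII / 2,
       aVF = leadII - leadI / 2)
}

#' Default report-text exclusion rules
#'
#' Ordered list of (rule name, phrase list) pairs covering the rhythm and
#' conduction abnormalities removed from the study cohort: paced rhythms,
#' artifact, bundle branch blocks, fascicular/posterior blocks,
#' intraventricular conduction defects, premature ventricular contractions,
#' atrial fibrillation and atrial flutter.  Fully user-configurable.
#'
#' @return named list of character vectors.
#' @export
default_exclusion_rules <- function() {
  list(
    paced    = c("paced rhythm", "pacemaker", "ventricular pacing",
                 "atrial pacing", "av sequential pacing"),
    artifact = c("artifact", "poor data quality", "technically limited",
                 "baseline wander precludes"),
    bbb      = c("bundle branch block", "bundle-branch block", "lbbb", "rbbb"),
    fascicular_block = c("fascicular block", "hemiblock", "posterior block"),
    ivcd     = c("intraventricular conduction defect",
                 "intraventricular conduction delay",
                 "nonspecific conduction delay"),
    pvc      = c("premature ventricular contraction",
                 "premature ventricular complex", "ventricular ectopy",
                 "frequent pvcs"),
    afib     = c("atrial fibrillation", "a-fib", "afib"),
    aflutter = c("atrial flutter")
  )
}

#' Decide keep/exclude from machine-report text
#'
#' Case-insensitive substring matching with a negation guard: a phrase whose
#' match is preceded by "no " or "without " within `negation_window`
#' characters does not count.  A record is excluded iff at least one rule
#' matches; all matched rule names are reported.
#'
#' @param report_text report string (may be `NA`/empty).
#' @param rules named list of phrase vectors; see
#'   [default_exclusion_rules()].
#' @param strict if `TRUE` an empty report excludes the record (reason
#'   `"no report"`); if `FALSE` it is kept with a warning.
#' @param negation_window characters to scan backwards for a negation cue.
#' @return list with `decision` (`"keep"`/`"exclude"`) and `matched`
#'   (character vector of rule names).
#' @export
exclusion_filter <- function(report_text, rules = default_exclusion_rules(),
                             strict = TRUE, negation_window = 30L) {
  stopifnot(length(rules) >= 1L)
  if (is.null(report_text) || is.na(report_text) ||
      !nzchar(trimws(report_text))) {
    if (strict) {
      return(list(decision = "exclude", matched = "no report"))
    }
    warning("empty report kept in lenient mode")
    return(list(decision = "keep", matched = character(0)))
  }
  text <- tolower(report_text)
  matched <- character(0)
  for (rule in names(rules)) {
    for (phrase in tolower(rules[[rule]])) {
      hits <- gregexpr(phrase, text, fixed = TRUE)[[1L]]
      if (hits[1L] == -1L) next
      for (pos in hits) {
        ctx <- substr(text, max(1L, pos - negation_window), pos - 1L)
        if (grepl("(no |without |negative for )[[:alnum:] ,-]*$", ctx)) next
        matched <- c(matched, rule)
        break
      }
      if (rule %in% matched) break
    }
  }
  list(decision = if (length(matched)) "exclude" else "keep",
       matched = unique(matched))
}

#' Select one ECG per patient
#'
#' Lexicographic priority: clean record first, then definitive phenotype
#' label, then earliest timestamp, then record id ascending (full
#' determinism).
#'
#' @param candidates data.frame with columns `record_id`, `is_clean`
#'   (logical), `label_definitive` (logical), `timestamp`
#'   (numeric or sortable).
#' @return the selected `record_id`.
#' @export
select_primary_ecg <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    stop("no candidate ECGs")
  }
  ord <- order(!candidates$is_clean, !candidates$label_definitive,
               candidates$timestamp, candidates$record_id)
  candidates$record_id[ord[1L]]
}

#' Read a 12-lead record from disk
#'
#' Two dialects: `"csv"` -- first column `time_s` then 12 lead columns
#' named exactly I, II, III, aVR, aVL, aVF, V1..V6 holding mV values; and
#' `"wfdb"` -- a WFDB header/.dat pair (see [read_wfdb()]).  Records not at
#' `target_fs` are resampled (`on_rate = "resample"`) or rejected.
#'
#' @param path file path; for WFDB either the `.hea` file or the record
#'   base name.
#' @param dialect `"wfdb"` or `"csv"` (default guessed from the extension).
#' @param target_fs pipeline sampling rate, Hz.
#' @param on_rate `"resample"` or `"reject"` for non-`target_fs` input.
#' @param ... passed to [ecg_record()] (e.g. `label`, `report_text`).
#' @return an [ecg_record()].
#' @export
read_record <- function(path, dialect = c("auto", "csv", "wfdb"),
                        target_fs = 500, on_rate = c("resample", "reject"),
                        ...) {
  dialect <- match.arg(dialect)
  on_rate <- match.arg(on_rate)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "wfdb"
  }
  if (dialect == "csv") {
    if (!file.exists(path)) stop("unreadable file: ", path)
    tab <- utils::read.csv(path, check.names = FALSE)
    if (!"time_s" %in% names(tab)) stop("CSV dialect requires a time_s column")
    for (lead in vcg_independent_leads()) {
      if (!lead %in% names(tab)) stop("lead ", lead, " absent")
    }
    dt <- diff(tab$time_s[1:2])
    fs <- 1 / dt
    leads <- as.list(tab[intersect(vcg_lead_names(), names(tab))])
    rec_id <- sub("\\.csv$", "", basename(path), ignore.case = TRUE)
  } else {
    w <- read_wfdb(path)
    fs <- w$fs
    leads <- w$leads
    rec_id <- w$record_id
  }
  if (abs(fs - target_fs) > 1e-6) {
    if (on_rate == "reject") {
      stop(sprintf("sampling rate %.6g Hz != required %g Hz", fs, target_fs))
    }
    leads <- lapply(leads, resample_series, fs_in = fs, fs_out = target_fs)
    fs <- target_fs
  }
  dots <- list(...)
  if (is.null(dots$record_id)) dots$record_id <- rec_id
  do.call(ecg_record, c(list(leads = leads, fs = fs), dots))
}

#' Read a cohort manifest
#'
#' CSV with columns `record_id`, `patient_id`, `path`, `label`,
#' `report_text`, plus optional `machine_*` columns (numeric measurements
#' and Boolean flags passed through to the feature vector).
#'
#' @param path manifest CSV path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, check.names = FALSE,
                         colClasses = c(record_id = "character"))
  need <- c("record_id", "patient_id", "path", "label")
  miss <- setdiff(need, names(man))
  if (length(miss)) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  }
  man
}
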