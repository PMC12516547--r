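# Cohort data model and CSV plumbing: every downstream stage consumes the
# validated structure built here.

DIAGNOSIS_LEVELS <- c("CN", "MCI", "AD")

# Case-insensitive synonym map for diagnosis strings found in the wild.
.diagnosis_synonyms <- c(
  "cn" = "CN", "nl" = "CN", "normal" = "CN",
  "mci" = "MCI",
  "ad" = "AD", "dementia" = "AD"
)

#' Normalize diagnosis strings to the CN/MCI/AD coding
#'
#' Strings are matched case-insensitively against a documented synonym map
#' ("NL"/"Normal" -> CN, "Dementia" -> AD).  Anything unrecognized maps to
#' `NA`, which the cohort validator treats as a rejected row.
#'
#' @param x character vector of raw diagnosis labels.
#' @return character vector over `{"CN","MCI","AD"}` with `NA` for
#'   unrecognized codes.
#' @export
normalize_diagnosis <- function(x) {
  out <- .diagnosis_synonyms[tolower(trimws(as.character(x)))]
  unname(out)
}

#' Construct a validated cohort object
#'
#' A cohort bundles one subject table and one visit table.  Validation
#' enforces the structural contract: every visit's subject exists, per-subject
#' visit days are strictly increasing and start at day 0, diagnosis codes are
#' in `{CN, MCI, AD}`, MMSE lies in 0..30 and ADAS is non-negative when
#' present, baseline age is at least 55, and volumes are positive when
#' present.
#'
#' @param subjects data.frame with columns `subject_id`, `age_baseline`,
#'   `fdg_raw`, `centiloid`, `hippocampus_vol`, `brain_vol`, `enroll_day`.
#' @param visits data.frame with columns `subject_id`, `day`, `diagnosis`,
#'   `mmse`, `adas`.
#' @return an object of class `"cohort"`: a list with elements `subjects`
#'   and `visits` (visits sorted by subject then day).
#' @export
cohort <- function(subjects, visits) {
  subj_cols <- c("subject_id", "age_baseline", "fdg_raw", "centiloid",
                 "hippocampus_vol", "brain_vol", "enroll_day")
  visit_cols <- c("subject_id", "day", "diagnosis", "mmse", "adas")
  miss_s <- setdiff(subj_cols, names(subjects))
  miss_v <- setdiff(visit_cols, names(visits))
  if (length(miss_s) || length(miss_v)) {
    stop("schema error: missing column(s): ",
         paste(c(miss_s, miss_v), collapse = ", "))
  }
  subjects <- subjects[, subj_cols, drop = FALSE]
  visits <- visits[, visit_cols, drop = FALSE]
  subjects$subject_id <- as.character(subjects$subject_id)
  visits$subject_id <- as.character(visits$subject_id)

  if (anyDuplicated(subjects$subject_id)) {
    stop("validation error: duplicate subject_id in subject table: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  }
  unknown <- setdiff(unique(visits$subject_id), subjects$subject_id)
  if (length(unknown)) {
    stop("validation error: visit references unknown subject_id: ",
         paste(unknown, collapse = ", "))
  }
  if (nrow(visits)) {
    dup <- duplicated(visits[, c("subject_id", "day")])
    if (any(dup)) {
      stop("validation error: duplicate (subject_id, day): ",
           paste(unique(visits$subject_id[dup]), collapse = ", "))
    }
    bad_dx <- !visits$diagnosis %in% DIAGNOSIS_LEVELS
    if (any(bad_dx)) {
      stop("validation error: unparseable diagnosis in rows for subject(s): ",
           paste(unique(visits$subject_id[bad_dx]), collapse = ", "))
    }
    if (any(visits$day < 0)) stop("validation error: visit day < 0")
    bad_mmse <- !is.na(visits$mmse) & (visits$mmse < 0 | visits$mmse > 30)
    if (any(bad_mmse)) stop("validation error: MMSE outside 0..30")
    if (any(!is.na(visits$adas) & visits$adas < 0)) {
      stop("validation error: negative ADAS")
    }
    visits <- visits[order(visits$subject_id, visits$day), , drop = FALSE]
    rownames(visits) <- NULL
  }
  if (any(!is.na(subjects$age_baseline) & subjects$age_baseline < 55)) {
    stop("validation error: age_baseline < 55")
  }
  for (vcol in c("hippocampus_vol", "brain_vol")) {
    if (any(!is.na(subjects[[vcol]]) & subjects[[vcol]] <= 0)) {
      stop("validation error: non-positive ", vcol)
    }
  }
  structure(list(subjects = subjects, visits = visits), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", nrow(x$subjects), " subjects, ",
      nrow(x$visits), " visits\n", sep = "")
  invisible(x)
}

#' Read a cohort from subject and visit CSV files
#'
#' Expects UTF-8 comma-separated files with header rows: `subjects.csv`
#' (subject_id, age_baseline, fdg_raw, centiloid, hippocampus_vol,
#' brain_vol, enroll_day) and `visits.csv` (subject_id, day, diagnosis,
#' mmse, adas).  Empty cells are missing values; diagnosis strings go
#' through [normalize_diagnosis()].
#'
#' @param subject_path,visit_path file paths.
#' @return a validated [cohort()] object.
#' @export
read_cohort <- function(subject_path, visit_path) {
  for (p in c(subject_path, visit_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  subjects <- utils::read.csv(subject_path, stringsAsFactors = FALSE,
                              colClasses = c(subject_id = "character"))
  visits <- utils::read.csv(visit_path, stringsAsFactors = FALSE,
                            colClasses = c(subject_id = "character"))
  if ("diagnosis" %in% names(visits)) {
    visits$diagnosis <- normalize_diagnosis(visits$diagnosis)
  }
  cohort(subjects, visits)
}

#' Write a cohort to subject and visit CSV files
#'
#' Output is bit-compatibly re-readable by [read_cohort()]; missing values
#' become empty cells, never sentinel numbers.
#'
#' @param x a [cohort()] object.
#' @param subject_path,visit_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(x, subject_path, visit_path) {
  stopifnot(inherits(x, "cohort"))
  utils::write.csv(x$subjects, subject_path, row.names = FALSE, na = "")
  utils::write.csv(x$visits, visit_path, row.names = FALSE, na = "")
  invisible(c(subject_path, visit_path))
}

#' Apply baseline and follow-up eligibility rules
#'
#' Retains subjects whose first visit is at day 0 with a CN diagnosis, whose
#' baseline FDG MetaROI value is non-missing (complete-case handling), and
#' whose last visit is at least `min_followup_days` after baseline.  One
#' exclusion reason is logged per dropped subject (first failing rule in the
#' order baseline_not_cn, missing_fdg, followup<min).
#'
#' @param x a [cohort()] object.
#' @param min_followup_days minimum follow-up in days (default 180).
#' @return a list with elements `cohort` (the filtered [cohort()]) and
#'   `exclusions` (data.frame subject_id, reason).
#' @export
eligibility_filter <- function(x, min_followup_days = 180) {
  stopifnot(inherits(x, "cohort"))
  ids <- x$subjects$subject_id
  reason <- character(0)
  excl_id <- character(0)
  keep <- logical(length(ids))
  vsplit <- split(x$visits, x$visits$subject_id)
  for (i in seq_along(ids)) {
    id <- ids[i]
    v <- vsplit[[id]]
    fail <-
      if (is.null(v) || nrow(v) == 0L || v$day[1] != 0L ||
          v$diagnosis[1] != "CN") {
        "baseline_not_cn"
      } else if (is.na(x$subjects$fdg_raw[i])) {
        "missing_fdg"
      } else if (max(v$day) < min_followup_days) {
        sprintf("followup<%d", min_followup_days)
      } else NA_character_
    if (is.na(fail)) {
      keep[i] <- TRUE
    } else {
      excl_id <- c(excl_id, id)
      reason <- c(reason, fail)
    }
  }
  if (!any(keep)) stop("no eligible subjects after filtering")
  out <- cohort(x$subjects[keep, , drop = FALSE],
                x$visits[x$visits$subject_id %in% ids[keep], , drop = FALSE])
  list(cohort = out,
       exclusions = data.frame(subject_id = excl_id, reason = reason,
                               stringsAsFactors = FALSE))
}
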