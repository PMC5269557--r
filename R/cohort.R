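# Linked longitudinal + survival data model and delimited-text I/O.
#
# All estimation modules consume a `linked_cohort`, never raw files.  The
# longitudinal component is long-format (one row per subject-week); the
# survival component has one row per subject with the dropout/censoring
# time, the event indicator, and baseline covariates.

RACE_LEVELS <- c("white", "black", "hispanic", "other")
LONG_COLS <- c("subject_id", "time_weeks", "engagement_days")
SURV_COLS <- c("subject_id", "event_time_weeks", "event", "age_years",
               "male", "race")

#' Construct a linked longitudinal + survival cohort
#'
#' Bundles repeated weekly engagement observations with one-row-per-subject
#' dropout/censoring information and validates the joint invariants: every
#' subject appears in both components, engagement values lie in `[0, 7]`
#' days/week, observation times are strictly increasing within subject, and
#' no engagement record occurs after the subject's dropout or censoring
#' time (after dropout, engagement data no longer exist).
#'
#' @param longitudinal data frame with columns `subject_id`, `time_weeks`
#'   (weeks since enrollment, `>= 0`), `engagement_days` (days/week on
#'   `[0, 7]`).
#' @param survival data frame with columns `subject_id`,
#'   `event_time_weeks` (`> 0`), `event` (1 = dropout observed,
#'   0 = administratively censored), `age_years`, `male` (0/1), `race`
#'   (one of `"white"`, `"black"`, `"hispanic"`, `"other"`).
#' @return An object of class `linked_cohort` with components
#'   `longitudinal` and `survival`, rows normalized to
#'   (subject, time) order.
#' @examples
#' long <- data.frame(subject_id = c("A", "A", "A", "B"),
#'                    time_weeks = c(0, 1, 2, 0),
#'                    engagement_days = c(5, 4, 3, 6))
#' surv <- data.frame(subject_id = c("A", "B"),
#'                    event_time_weeks = c(3, 2.5), event = c(1, 0),
#'                    age_years = c(30, 42), male = c(1, 0),
#'                    race = c("white", "black"))
#' ch <- linked_cohort(long, surv)
#' n_subjects(ch)
#' @export
linked_cohort <- function(longitudinal, survival) {
  longitudinal <- as.data.frame(longitudinal)[LONG_COLS]
  survival <- as.data.frame(survival)[SURV_COLS]
  longitudinal$subject_id <- as.character(longitudinal$subject_id)
  survival$subject_id <- as.character(survival$subject_id)
  survival$race <- as.character(survival$race)
  for (col in c("time_weeks", "engagement_days"))
    longitudinal[[col]] <- as.numeric(longitudinal[[col]])
  for (col in c("event_time_weeks", "event", "age_years", "male"))
    survival[[col]] <- as.numeric(survival[[col]])
  longitudinal <- longitudinal[order(longitudinal$subject_id,
                                     longitudinal$time_weeks), ,
                               drop = FALSE]
  survival <- survival[order(survival$subject_id), , drop = FALSE]
  rownames(longitudinal) <- NULL
  rownames(survival) <- NULL
  out <- structure(list(longitudinal = longitudinal, survival = survival),
                   class = "linked_cohort")
  validate_cohort(out)
  out
}

#' Validate a linked cohort
#'
#' Checks all structural invariants of a [linked_cohort()] and stops with a
#' message naming the offending subject (or column) on the first violation.
#'
#' @param cohort a `linked_cohort`.
#' @return `cohort`, invisibly, when valid.
#' @export
validate_cohort <- function(cohort) {
  long <- cohort$longitudinal
  surv <- cohort$survival
  if (!all(LONG_COLS %in% names(long)))
    stop("longitudinal component must have columns ",
         paste(LONG_COLS, collapse = ", "), call. = FALSE)
  if (!all(SURV_COLS %in% names(surv)))
    stop("survival component must have columns ",
         paste(SURV_COLS, collapse = ", "), call. = FALSE)
  if (nrow(surv) == 0L)
    stop("cohort must contain at least one subject", call. = FALSE)
  for (col in c("time_weeks", "engagement_days"))
    if (anyNA(long[[col]]) || any(!is.finite(long[[col]])))
      stop("longitudinal column '", col, "' contains missing/non-finite ",
           "values; missingness must be represented by record absence",
           call. = FALSE)
  for (col in c("event_time_weeks", "event", "age_years", "male"))
    if (anyNA(surv[[col]]) || any(!is.finite(surv[[col]])))
      stop("survival column '", col, "' contains missing/non-finite values",
           call. = FALSE)

  if (anyDuplicated(surv$subject_id))
    stop("duplicated subject_id in survival table: ",
         surv$subject_id[duplicated(surv$subject_id)][1L], call. = FALSE)
  if (any(surv$event_time_weeks <= 0))
    stop("event_time_weeks must be > 0; offending subject: ",
         surv$subject_id[surv$event_time_weeks <= 0][1L], call. = FALSE)
  if (!all(surv$event %in% c(0, 1)))
    stop("event must be 0/1; offending subject: ",
         surv$subject_id[!surv$event %in% c(0, 1)][1L], call. = FALSE)
  if (!all(surv$male %in% c(0, 1)))
    stop("male must be 0/1; offending subject: ",
         surv$subject_id[!surv$male %in% c(0, 1)][1L], call. = FALSE)
  if (!all(surv$race %in% RACE_LEVELS))
    stop("race must be one of ", paste(RACE_LEVELS, collapse = ", "),
         "; offending subject: ",
         surv$subject_id[!surv$race %in% RACE_LEVELS][1L], call. = FALSE)

  if (any(long$time_weeks < 0))
    stop("time_weeks must be >= 0; offending subject: ",
         long$subject_id[long$time_weeks < 0][1L], call. = FALSE)
  bad_y <- long$engagement_days < 0 | long$engagement_days > 7
  if (any(bad_y))
    stop("engagement_days must lie in [0, 7]; offending subject: ",
         long$subject_id[bad_y][1L], call. = FALSE)

  ids_long <- unique(long$subject_id)
  ids_surv <- surv$subject_id
  if (!setequal(ids_long, ids_surv)) {
    missing_long <- setdiff(ids_surv, ids_long)
    missing_surv <- setdiff(ids_long, ids_surv)
    if (length(missing_long))
      stop("subject without longitudinal records (every subject needs >= 1): ",
           missing_long[1L], call. = FALSE)
    stop("longitudinal subject missing from survival table: ",
         missing_surv[1L], call. = FALSE)
  }

  split_t <- split(long$time_weeks, long$subject_id)
  for (id in names(split_t)) {
    tt <- split_t[[id]]
    if (length(tt) > 1L && any(diff(tt) <= 0))
      stop("times within a subject must be strictly increasing; ",
           "offending subject: ", id, call. = FALSE)
  }
  last_t <- vapply(split_t, max, numeric(1))
  et <- stats::setNames(surv$event_time_weeks, surv$subject_id)
  over <- names(last_t)[last_t > et[names(last_t)]]
  if (length(over))
    stop("engagement record after dropout/censoring time for subject: ",
         over[1L], call. = FALSE)
  invisible(cohort)
}

#' @export
print.linked_cohort <- function(x, ...) {
  n <- nrow(x$survival)
  cat("Linked cohort: ", n, " subjects, ",
      nrow(x$longitudinal), " weekly engagement records\n", sep = "")
  cat("  events (dropout observed): ", sum(x$survival$event),
      ", censored: ", sum(1 - x$survival$event), "\n", sep = "")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort a `linked_cohort`.
#' @return integer count of subjects.
#' @export
n_subjects <- function(cohort) nrow(cohort$survival)

read_table_checked <- function(path, expected_cols, what) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1L]]
  if (anyDuplicated(header))
    stop(what, " file has duplicated column(s): ",
         paste(unique(header[duplicated(header)]), collapse = ", "),
         call. = FALSE)
  if (!setequal(header, expected_cols))
    stop(what, " file must have exactly columns ",
         paste(expected_cols, collapse = ", "), "; found ",
         paste(header, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df
}

#' Read a linked cohort from two CSV files
#'
#' The longitudinal file has columns
#' `subject_id,time_weeks,engagement_days`; the survival file has columns
#' `subject_id,event_time_weeks,event,age_years,male,race`.  Comma
#' separated, `.` decimal, UTF-8, explicit header; missing values are not
#' allowed (a missing week is represented by the absence of its record).
#'
#' @param longitudinal_path path to the longitudinal CSV.
#' @param survival_path path to the survival CSV.
#' @return a validated [linked_cohort()].
#' @export
read_cohort <- function(longitudinal_path, survival_path) {
  long <- read_table_checked(longitudinal_path, LONG_COLS, "longitudinal")
  surv <- read_table_checked(survival_path, SURV_COLS, "survival")
  num <- function(x, col, what) {
    out <- suppressWarnings(as.numeric(x))
    if (anyNA(out))
      stop(what, " column '", col, "' has missing or non-numeric entries",
           call. = FALSE)
    out
  }
  long$time_weeks <- num(long$time_weeks, "time_weeks", "longitudinal")
  long$engagement_days <- num(long$engagement_days, "engagement_days",
                              "longitudinal")
  surv$event_time_weeks <- num(surv$event_time_weeks, "event_time_weeks",
                               "survival")
  surv$event <- num(surv$event, "event", "survival")
  surv$age_years <- num(surv$age_years, "age_years", "survival")
  surv$male <- num(surv$male, "male", "survival")
  linked_cohort(long, surv)
}

fmt_num <- function(x) {
  # full round-trip precision for doubles
  vapply(x, function(v) sprintf("%.17g", v), character(1))
}

#' Write a linked cohort to two CSV files
#'
#' Numeric values are written with full double precision so that
#' `read_cohort()` on the written files reproduces the cohort exactly.
#'
#' @param cohort a valid `linked_cohort`.
#' @param longitudinal_path,survival_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_cohort <- function(cohort, longitudinal_path, survival_path) {
  validate_cohort(cohort)
  long <- cohort$longitudinal
  surv <- cohort$survival
  long_out <- data.frame(subject_id = long$subject_id,
                         time_weeks = fmt_num(long$time_weeks),
                         engagement_days = fmt_num(long$engagement_days),
                         stringsAsFactors = FALSE)
  surv_out <- data.frame(subject_id = surv$subject_id,
                         event_time_weeks = fmt_num(surv$event_time_weeks),
                         event = fmt_num(surv$event),
                         age_years = fmt_num(surv$age_years),
                         male = fmt_num(surv$male),
                         race = surv$race,
                         stringsAsFactors = FALSE)
  utils::write.csv(long_out, longitudinal_path, row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(surv_out, survival_path, row.names = FALSE, quote = FALSE)
  invisible(c(longitudinal_path, survival_path))
}

#' Build design matrices for the longitudinal and hazard submodels
#'
#' Fixed-effect longitudinal design per record is `(1, t, t^2)` (quadratic
#' time trend); random-effect design is `(1, t)` (random intercept and
#' slope).  The hazard covariate row per subject is
#' `(age_centered, male, race_black, race_hispanic, race_other)` in that
#' fixed order, with white as the race reference level and age centered at
#' the sample mean (centering leaves the hazard ratio per year unchanged
#' but stabilizes estimation).
#'
#' @param cohort a valid `linked_cohort`.
#' @return a list with components `X` (N x 3 fixed design), `Z` (N x 2
#'   random design), `y` (N engagement values), `subject` (integer subject
#'   index per record), `subject_id` (n ids in index order), `W` (n x 5
#'   hazard covariates), `event_time` (n), `event` (n), and `age_center`
#'   (the mean age used for centering).
#' @export
build_design <- function(cohort) {
  validate_cohort(cohort)
  long <- cohort$longitudinal
  surv <- cohort$survival
  ids <- surv$subject_id
  t <- long$time_weeks
  X <- cbind(intercept = 1, week = t, week_sq = t^2)
  Z <- cbind(intercept = 1, week = t)
  age_center <- mean(surv$age_years)
  W <- cbind(age = surv$age_years - age_center,
             male = surv$male,
             race_black = as.numeric(surv$race == "black"),
             race_hispanic = as.numeric(surv$race == "hispanic"),
             race_other = as.numeric(surv$race == "other"))
  list(X = X, Z = Z, y = long$engagement_days,
       subject = match(long$subject_id, ids),
       subject_id = ids, W = W,
       event_time = surv$event_time_weeks, event = surv$event,
       age_center = age_center)
}
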