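acr_thresholds <- function(sex) {
  sex <- tolower(as.character(sex))
  if (is.na(sex) || !sex %in% c("male", "female", "m", "f", "man", "woman")) {
    stop("unknown sex '", sex, "': ACR thresholds are sex specific")
  }
  if (sex %in% c("male", "m", "man")) c(micro = 2.5, high = 12.5)
  else c(micro = 3.5, high = 17.5)
}

#' Nephropathy case rule from an ACR trajectory
#'
#' A subject is a nephropathy case if microalbuminuria (ACR >= 2.5 mg/mmol
#' for men, >= 3.5 for women) is present at two of three consecutive
#' measurements, or if high micro-/macroalbuminuria (ACR >= 12.5 for men,
#' >= 17.5 for women) is present at a single measurement. All thresholds
#' are inclusive. Trajectories shorter than three visits apply the
#' two-of-three rule to available consecutive pairs only if both members
#' exceed the threshold; a single moderate value is never enough.
#'
#' @param acr numeric vector of ACR values (mg/mmol), chronologically
#'   ordered.
#' @param sex `"male"` or `"female"` (also accepts m/f/man/woman).
#' @return logical: case or not.
#' @export
nephropathy_case <- function(acr, sex) {
  stopifnot(length(acr) >= 1L, all(acr >= 0, na.rm = TRUE))
  thr <- acr_thresholds(sex)
  acr <- acr[!is.na(acr)]
  if (!length(acr)) return(FALSE)
  if (any(acr >= thr["high"])) return(TRUE)
  micro <- acr >= thr["micro"]
  n <- length(micro)
  if (n >= 3L) {
    for (i in seq_len(n - 2L)) {
      if (sum(micro[i:(i + 2L)]) >= 2L) return(TRUE)
    }
    return(FALSE)
  }
  n == 2L && all(micro)
}

#' Apply the nephropathy rule to a long ACR table
#'
#' @param acr_table data.frame with columns `subject_id`, `sex`, `visit`
#'   (sortable visit index or date) and `acr`.
#' @return data.frame `subject_id, case`.
#' @export
nephropathy_cases <- function(acr_table) {
  stopifnot(all(c("subject_id", "sex", "visit", "acr") %in% names(acr_table)))
  acr_table <- acr_table[order(acr_table$subject_id, acr_table$visit), ]
  ids <- unique(acr_table$subject_id)
  case <- vapply(ids, function(id) {
    rows <- acr_table$subject_id == id
    nephropathy_case(acr_table$acr[rows], acr_table$sex[rows][1])
  }, logical(1))
  data.frame(subject_id = ids, case = case, stringsAsFactors = FALSE)
}

#' Split prevalent and incident analysis sets
#'
#' Prevalent analysis uses every subject with known baseline status;
#' subjects free of the endpoint at baseline form the incident risk set,
#' with time = event time minus baseline (years) for cases and censoring at
#' the last visit otherwise. A nominally incident event at or before
#' baseline (time <= 0) is a data inconsistency: the subject is moved to
#' the prevalent set and logged.
#'
#' @param records data.frame with columns `subject_id`, `endpoint`,
#'   `prevalent` (logical), `event` (logical), `event_years` (time to event
#'   or censoring, years).
#' @return named list per endpoint, each with `prevalent` (subject_id,
#'   case), `incident` (subject_id, event, time) and `moved` (subjects
#'   reassigned to prevalent).
#' @export
split_prevalent_incident <- function(records) {
  need <- c("subject_id", "endpoint", "prevalent", "event", "event_years")
  stopifnot(all(need %in% names(records)))
  out <- list()
  for (ep in unique(records$endpoint)) {
    r <- records[records$endpoint == ep, ]
    bad <- !r$prevalent & r$event & r$event_years <= 0
    if (any(bad)) {
      message(sum(bad), " ", ep, " events at or before baseline moved to ",
              "the prevalent set")
      r$prevalent[bad] <- TRUE
    }
    risk <- !r$prevalent
    out[[ep]] <- list(
      prevalent = data.frame(subject_id = r$subject_id,
                             case = r$prevalent, stringsAsFactors = FALSE),
      incident = data.frame(subject_id = r$subject_id[risk],
                            event = r$event[risk],
                            time = r$event_years[risk],
                            stringsAsFactors = FALSE),
      moved = r$subject_id[bad])
  }
  out
}
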