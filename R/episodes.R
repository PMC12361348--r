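#' Split follow-up into unexposed and exposed episodes for a disorder group
#'
#' Implements the time-varying exposure model with half-open (enter, exit]
#' episodes. A subject is unexposed from entry until their first diagnosis
#' of any disorder in the comparator set (default: any mental disorder), and
#' exposed to the analysed group from that group's first diagnosis until the
#' end of follow-up. Prevalent diagnoses (diagnosed at or before entry) are
#' carried forward: such subjects contribute a single exposed episode.
#' Subjects whose comparator diagnosis precedes the analysed group's
#' diagnosis contribute neither arm between the two diagnoses, so person-time
#' is conserved exactly when `group == comparator` and never exceeds
#' follow-up otherwise.
#'
#' @param records Validated subject records; a `cause_category` column is
#'   added via `taxonomy` if absent.
#' @param group Analysed disorder group (see [disorder_groups()]).
#' @param comparator Group whose first diagnosis ends unexposed person-time.
#' @param taxonomy Passed to [add_cause_category()] when needed.
#' @return Data frame of episodes: `subject_id`, `enter`, `exit`, `status`
#'   ("death"/"censored"), `cause` (taxonomy label or NA), `group`
#'   ("exposed"/"unexposed"), `stratum_id`, `sex`. The number of subjects
#'   whose analysed-group diagnosis falls at/after their exit (contributing
#'   unexposed time only) is attached as attribute `n_diagnosis_after_exit`.
#' @export
split_exposure_episodes <- function(records, group,
                                    comparator = "any_mental",
                                    taxonomy = cause_taxonomy("detailed")) {
  stopifnot(group %in% disorder_groups(), comparator %in% disorder_groups())
  if (is.null(records$cause_category))
    records <- add_cause_category(records, taxonomy)
  n <- nrow(records)
  ga <- if (dx_col(group) %in% names(records)) records[[dx_col(group)]] else rep(NA_real_, n)
  ca <- if (dx_col(comparator) %in% names(records)) records[[dx_col(comparator)]] else rep(NA_real_, n)
  ca <- pmin(ca, ga, na.rm = TRUE)            # comparator dx can never be later
  e <- records$entry_age; x <- records$exit_age

  u_end <- pmin(ifelse(is.na(ca), Inf, ca), x)
  has_unexp <- u_end > e
  unexp <- data.frame(
    subject_id = records$subject_id[has_unexp],
    enter = e[has_unexp], exit = u_end[has_unexp],
    status = ifelse(u_end[has_unexp] >= x[has_unexp],
                    records$event[has_unexp], "censored"),
    cause = ifelse(u_end[has_unexp] >= x[has_unexp] &
                     records$event[has_unexp] == "death",
                   records$cause_category[has_unexp], NA_character_),
    group = "unexposed",
    stratum_id = records$stratum_id[has_unexp],
    sex = records$sex[has_unexp],
    stringsAsFactors = FALSE
  )

  has_exp <- !is.na(ga) & ga < x
  gs <- pmax(e[has_exp], ga[has_exp])
  exp_ <- data.frame(
    subject_id = records$subject_id[has_exp],
    enter = gs, exit = x[has_exp],
    status = records$event[has_exp],
    cause = ifelse(records$event[has_exp] == "death",
                   records$cause_category[has_exp], NA_character_),
    group = "exposed",
    stratum_id = records$stratum_id[has_exp],
    sex = records$sex[has_exp],
    stringsAsFactors = FALSE
  )
  out <- rbind(unexp, exp_)
  rownames(out) <- NULL
  attr(out, "n_diagnosis_after_exit") <- sum(!is.na(ga) & ga >= x)
  out
}

#' Restrict a cohort to an administrative study window
#'
#' Moves entries forward to the window opening date (re-deriving entry age
#' in exact fractional years at 365.25 days/year) and truncates exits at the
#' closing date, recoding deaths after the closing date as censorings.
#' Subjects with no follow-up inside the window are dropped. Applying the
#' same window twice is a no-op, and follow-up is never increased.
#'
#' @param records Validated subject records with `entry_date`/`exit_date`.
#' @param open_date,close_date Window bounds (coerced with [as.Date()]).
#' @return Filtered records; attribute `window_counts` holds the numbers of
#'   dropped and truncated subjects. Warns (and returns an empty table) when
#'   no follow-up overlaps the window.
#' @export
apply_study_window <- function(records, open_date, close_date) {
  open_date <- as.Date(open_date); close_date <- as.Date(close_date)
  stopifnot(open_date < close_date)
  if (anyNA(records$entry_date) || anyNA(records$exit_date))
    stop("apply_study_window requires entry_date and exit_date on every record")
  shift_in <- pmax(as.numeric(open_date - records$entry_date) / DAYS_PER_YEAR, 0)
  shift_out <- pmax(as.numeric(records$exit_date - close_date) / DAYS_PER_YEAR, 0)
  new_entry_age <- records$entry_age + shift_in
  new_exit_age <- records$exit_age - shift_out
  keep <- new_entry_age < new_exit_age
  truncated <- shift_out > 0 & keep
  out <- records[keep, , drop = FALSE]
  out$entry_age <- new_entry_age[keep]
  out$exit_age <- new_exit_age[keep]
  out$entry_date <- pmax(out$entry_date, open_date)
  out$exit_date <- pmin(out$exit_date, close_date)
  recode <- truncated[keep]
  out$event[recode] <- "censored"
  out$death_icd[recode] <- NA_character_
  out$cd4_at_death[recode] <- NA_real_
  if (!is.null(out$cause_category)) out$cause_category[recode] <- NA_character_
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("study window overlaps no follow-up: empty cohort")
  attr(out, "window_counts") <- c(dropped = sum(!keep), truncated = sum(truncated))
  attr(out, "validation") <- attr(records, "validation")
  out
}
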