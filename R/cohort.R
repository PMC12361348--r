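DAYS_PER_YEAR <- 365.25

dx_col <- function(group) paste0("dx_age_", group)

#' Column-mapping schema for cohort tables
#'
#' Maps the column names of a delimited input file onto the package's
#' subject-record schema. Diagnosis-age columns are located by
#' `diagnosis_prefix` + group name (e.g. `dx_age_depressive`). Dates are
#' ISO-8601; missing values are empty fields.
#'
#' @param subject_id,sex,stratum_id,entry_age,exit_age,event,death_icd,cd4_at_death,entry_date,exit_date
#'   Input column names for the respective fields.
#' @param diagnosis_prefix Prefix of the per-group first-diagnosis-age columns.
#' @param event_death,event_censored Values of the event column encoding a
#'   death and a censoring.
#' @param sep Field separator of the input file.
#' @return A list of class `cohort_schema`.
#' @export
cohort_schema <- function(subject_id = "subject_id", sex = "sex",
                          stratum_id = "stratum_id", entry_age = "entry_age",
                          exit_age = "exit_age", event = "event",
                          death_icd = "death_icd", cd4_at_death = "cd4_at_death",
                          entry_date = "entry_date", exit_date = "exit_date",
                          diagnosis_prefix = "dx_age_",
                          event_death = "death", event_censored = "censored",
                          sep = ",") {
  structure(as.list(environment()), class = "cohort_schema")
}

#' Validate a cohort table of subject records
#'
#' Applies the record invariants row by row: adult entry (>= 18 years),
#' strictly positive follow-up, exit at or below the cutoff age, event/cause
#' consistency (an ICD cause implies a death), non-negative CD4, and adult
#' diagnosis ages. Violating rows are removed from the returned table and
#' tallied, never silently dropped: the returned object carries a
#' `validation` attribute (a `validation_report`).
#'
#' @param records Data frame in package schema (see [load_cohort()]).
#' @param cutoff Maximum exit age in years (default 85).
#' @return The accepted rows, with a `validation` attribute.
#' @export
validate_cohort <- function(records, cutoff = 85) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  rules <- list(
    "nonpositive follow-up" = !(records$exit_age > records$entry_age),
    "entry before age 18" = records$entry_age < 18,
    "exit beyond cutoff age" = records$exit_age > cutoff + 1e-9,
    "death code without death event" =
      !is.na(records$death_icd) & records$event != "death",
    "invalid event" = !(records$event %in% c("death", "censored")),
    "invalid sex" = !(records$sex %in% c("male", "female")),
    "negative CD4 at death" =
      !is.na(records$cd4_at_death) & records$cd4_at_death < 0
  )
  dxc <- intersect(dx_col(disorder_groups()), names(records))
  if (length(dxc)) {
    dx <- as.matrix(records[dxc])
    rules[["diagnosis before age 18"]] <- rowSums(!is.na(dx) & dx < 18) > 0
  }
  bad <- Reduce(`|`, lapply(rules, function(v) { v[is.na(v)] <- TRUE; v }))
  report <- structure(list(
    n_input = n, n_accepted = sum(!bad), n_rejected = sum(bad),
    violations = vapply(rules, function(v) sum(v, na.rm = TRUE), integer(1)),
    rejected_ids = records$subject_id[bad]
  ), class = "validation_report")
  out <- records[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "validation") <- report
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat("Cohort validation:", x$n_input, "rows,", x$n_accepted, "accepted,",
      x$n_rejected, "rejected\n")
  v <- x$violations[x$violations > 0]
  for (r in names(v)) cat("  ", r, ": ", v[[r]], "\n", sep = "")
  invisible(x)
}

#' Load a cohort table from a delimited text file
#'
#' Reads a CSV/TSV file, maps columns per the schema, parses ISO dates,
#' coerces ages to exact fractional years and validates the records.
#' Missing mandatory columns raise an error naming the column; rows that
#' violate record invariants are collected into the validation report
#' attached to the result. Deaths with no ICD code are accepted (they
#' classify as `unknown_cause`).
#'
#' @param path Path to the delimited file.
#' @param schema A [cohort_schema()].
#' @param cutoff Maximum exit age (years).
#' @return Validated data frame of subject records with columns
#'   `subject_id`, `sex`, `stratum_id`, `entry_age`, `exit_age`, `event`,
#'   `death_icd`, `cd4_at_death`, `entry_date`, `exit_date` and any
#'   `dx_age_*` diagnosis-age columns; `validation` attribute as in
#'   [validate_cohort()].
#' @export
load_cohort <- function(path, schema = cohort_schema(), cutoff = 85) {
  stopifnot(file.exists(path))
  raw <- utils::read.table(path, header = TRUE, sep = schema$sep,
                           stringsAsFactors = FALSE, na.strings = c("", "NA"),
                           check.names = FALSE)
  mandatory <- c("subject_id", "sex", "entry_age", "exit_age", "event")
  for (f in mandatory) {
    if (!(schema[[f]] %in% names(raw)))
      stop("missing mandatory column: ", schema[[f]])
  }
  pick <- function(f, default = NA) {
    if (schema[[f]] %in% names(raw)) raw[[schema[[f]]]] else rep(default, nrow(raw))
  }
  rec <- data.frame(
    subject_id = as.character(pick("subject_id")),
    sex = tolower(as.character(pick("sex"))),
    stratum_id = as.character(pick("stratum_id", "all")),
    entry_age = as.numeric(pick("entry_age")),
    exit_age = as.numeric(pick("exit_age")),
    event = as.character(pick("event")),
    death_icd = as.character(pick("death_icd", NA_character_)),
    cd4_at_death = as.numeric(pick("cd4_at_death", NA_real_)),
    stringsAsFactors = FALSE
  )
  rec$stratum_id[is.na(rec$stratum_id)] <- "all"
  rec$event[rec$event == schema$event_death] <- "death"
  rec$event[rec$event == schema$event_censored] <- "censored"
  rec$entry_date <- as.Date(as.character(pick("entry_date", NA_character_)))
  rec$exit_date <- as.Date(as.character(pick("exit_date", NA_character_)))
  for (g in disorder_groups()) {
    cn <- paste0(schema$diagnosis_prefix, g)
    if (cn %in% names(raw)) rec[[dx_col(g)]] <- as.numeric(raw[[cn]])
  }
  validate_cohort(rec, cutoff = cutoff)
}

#' First-diagnosis ages per disorder group from coded diagnosis histories
#'
#' Turns (subject, ICD code, age) diagnosis events into the wide per-group
#' first-diagnosis-age columns of the record schema, using
#' [disorder_membership()] for the phenotyping.
#'
#' @param subject_id,icd_code,age Parallel vectors: one diagnosis event each.
#' @return Data frame with `subject_id` and one `dx_age_*` column per group.
#' @export
diagnosis_ages_from_codes <- function(subject_id, icd_code, age) {
  stopifnot(length(subject_id) == length(icd_code), length(icd_code) == length(age))
  mem <- disorder_membership(icd_code)
  ids <- unique(subject_id)
  out <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
  for (g in disorder_groups()) {
    keep <- mem[, g]
    if (!any(keep)) { out[[dx_col(g)]] <- NA_real_; next }
    first <- tapply(age[keep], subject_id[keep], min)
    out[[dx_col(g)]] <- as.numeric(first[match(ids, names(first))])
  }
  out
}

#' Attach cause-of-death categories to records
#'
#' Adds a `cause_category` column using [classify_death()]: `NA` for
#' censored subjects, a taxonomy label for deaths (deaths with no ICD code
#' become `unknown_cause`).
#'
#' @param records Validated subject records.
#' @param taxonomy A [cause_taxonomy()].
#' @return `records` with a `cause_category` column.
#' @export
add_cause_category <- function(records, taxonomy = cause_taxonomy("detailed")) {
  records$cause_category <- NA_character_
  dead <- records$event == "death"
  if (any(dead))
    records$cause_category[dead] <- classify_death(records$death_icd[dead],
                                                   records$cd4_at_death[dead],
                                                   taxonomy)
  records
}
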