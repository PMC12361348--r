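#' Percentage with half-up rounding
#'
#' Computes 100 * num / den rounded half-up (not banker's rounding) to
#' `digits` decimals, the convention used for the package's descriptive
#' tables: e.g. 81 of 7709 gives 1.1, not 1.0.
#'
#' @param num,den Numerator and denominator counts.
#' @param digits Decimals (default 1).
#' @return Numeric percentage(s); `NA` where `den` is 0.
#' @export
pct_half_up <- function(num, den, digits = 1) {
  x <- 100 * num / den                    # recycles num against den
  out <- floor(x * 10^digits + 0.5 + 1e-9) / 10^digits
  out[!is.finite(x)] <- NA_real_          # zero denominators
  as.numeric(out)
}

#' Prevalence of disorder-group diagnoses
#'
#' Counts, by sex and overall, the subjects ever diagnosed with each group
#' (any diagnosis age present, including prevalent diagnoses). Subjects may
#' appear in several rows. Percentages use half-up rounding to one decimal.
#'
#' @param records Validated subject records.
#' @param groups Disorder groups to tabulate.
#' @return Data frame: one row per group with `n_<sex>`, `pct_<sex>`,
#'   `n_total`, `pct_total`; denominators attached as attribute
#'   `denominators`.
#' @export
summarize_prevalence <- function(records, groups = disorder_groups()) {
  unknown <- setdiff(groups, disorder_groups())
  if (length(unknown)) stop("unknown disorder group(s): ",
                            paste(unknown, collapse = ", "))
  sexes <- c("male", "female")
  den <- c(vapply(sexes, function(s) sum(records$sex == s), numeric(1)),
           total = nrow(records))
  out <- data.frame(group = groups, stringsAsFactors = FALSE)
  for (s in c(sexes, "total")) {
    sel <- if (s == "total") rep(TRUE, nrow(records)) else records$sex == s
    cnt <- vapply(groups, function(g) {
      col <- dx_col(g)
      if (!col %in% names(records)) return(0L)
      sum(sel & !is.na(records[[col]]))
    }, integer(1))
    out[[paste0("n_", s)]] <- cnt
    out[[paste0("pct_", s)]] <- pct_half_up(cnt, den[[s]])
  }
  attr(out, "denominators") <- den
  out
}

#' Deaths by cause category and CD4 band
#'
#' Tabulates deaths for diagnosed (any mental disorder) and undiagnosed
#' subjects and overall: all-cause deaths, natural/unnatural/unknown-cause
#' deaths as percentages of total deaths in that column, and CD4 bands of
#' natural deaths as percentages of natural deaths in that column.
#'
#' @param records Validated subject records.
#' @param taxonomy A [cause_taxonomy()].
#' @return Data frame with columns `row`, `denominator` ("subjects",
#'   "deaths" or "natural deaths") and per column-group `n_*`/`pct_*`.
#' @export
summarize_deaths <- function(records, taxonomy = cause_taxonomy("detailed")) {
  if (is.null(records$cause_category))
    records <- add_cause_category(records, taxonomy)
  diag <- dx_col("any_mental") %in% names(records) &
    !is.na(records[[dx_col("any_mental")]])
  cols <- list(diagnosed = diag, undiagnosed = !diag,
               total = rep(TRUE, nrow(records)))
  natural <- taxonomy$natural_labels
  unnat <- setdiff(taxonomy$labels, c(natural, "unknown_cause"))
  rows <- c("all_deaths", "natural", natural, "unnatural", "unknown_cause")
  out <- data.frame(row = rows,
                    denominator = c("subjects", "deaths",
                                    rep("natural deaths", length(natural)),
                                    "deaths", "deaths"),
                    stringsAsFactors = FALSE)
  for (cn in names(cols)) {
    sel <- cols[[cn]]
    dead <- sel & records$event == "death"
    cz <- records$cause_category[dead]
    n_dead <- sum(dead)
    n_nat <- sum(cz %in% natural)
    n <- c(all_deaths = n_dead, natural = n_nat,
           vapply(natural, function(l) sum(cz == l), numeric(1)),
           unnatural = sum(cz %in% unnat),
           unknown_cause = sum(cz == "unknown_cause"))
    den <- c(sum(sel), n_dead, rep(n_nat, length(natural)), n_dead, n_dead)
    out[[paste0("n_", cn)]] <- as.integer(n)
    out[[paste0("pct_", cn)]] <- pct_half_up(n, den)
  }
  out
}

#' Standardized difference between two groups
#'
#' (mean1 - mean2) / sqrt((var1 + var2) / 2), with n-1 variance denominators.
#' A dimensionless balance measure. With zero pooled variance the result is
#' 0 for equal means and signals an infinite difference otherwise.
#'
#' @param values_group1,values_group2 Numeric vectors (>= 2 finite values each).
#' @return A single number.
#' @export
standardized_difference <- function(values_group1, values_group2) {
  x <- values_group1[is.finite(values_group1)]
  y <- values_group2[is.finite(values_group2)]
  if (length(x) < 2 || length(y) < 2)
    stop("need at least 2 finite observations per group")
  pooled <- (stats::var(x) + stats::var(y)) / 2
  d <- mean(x) - mean(y)
  if (pooled == 0) {
    if (d == 0) return(0)
    warning("zero pooled variance with unequal means: infinite standardized difference")
    return(sign(d) * Inf)
  }
  d / sqrt(pooled)
}

#' Aligned plain-text rendering of a summary table
#'
#' @param x Data frame from [summarize_prevalence()] or [summarize_deaths()].
#' @param file Optional path; when given the text is written there.
#' @return The formatted lines, invisibly.
#' @export
format_summary_text <- function(x, file = NULL) {
  lines <- utils::capture.output(print(x, row.names = FALSE))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
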