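#' Mental-disorder group names
#'
#' The nine ICD-10 code-range phenotypes supported by the package, from the
#' broadest ("any_mental", F10-F99 excluding tobacco use disorder F17) to
#' single-block groups such as bipolar disorder (F31).
#'
#' @return Character vector of group names.
#' @export
disorder_groups <- function() {
  c("any_mental", "any_except_sud", "severe", "psychotic", "bipolar",
    "common", "depressive", "anxiety", "sud")
}

#' ICD-10 range definitions for the disorder groups
#'
#' Each group is a set of two-digit F-code stem ranges plus optional
#' four-character prefixes (e.g. "F341" for F34.1) and stem exclusions.
#' Containment uses prefix semantics: F32.1 belongs to F32.
#'
#' @return Named list; one element per group with `stems` (integer vector of
#'   included two-digit stems), `prefixes` (normalized code prefixes included
#'   beyond whole stems) and `exclude_stems`.
#' @export
disorder_definitions <- function() {
  psychotic <- list(stems = 20:29, prefixes = character(0), exclude_stems = integer(0))
  bipolar <- list(stems = 31L, prefixes = character(0), exclude_stems = integer(0))
  depressive <- list(stems = c(32L, 33L), prefixes = "F341", exclude_stems = integer(0))
  anxiety <- list(stems = 40:49, prefixes = character(0), exclude_stems = integer(0))
  sud <- list(stems = c(10:16, 18:19), prefixes = character(0), exclude_stems = integer(0))
  list(
    any_mental = list(stems = 10:99, prefixes = character(0), exclude_stems = 17L),
    any_except_sud = list(stems = 20:99, prefixes = character(0), exclude_stems = integer(0)),
    severe = list(stems = c(psychotic$stems, bipolar$stems), prefixes = character(0),
                  exclude_stems = integer(0)),
    psychotic = psychotic,
    bipolar = bipolar,
    common = list(stems = c(depressive$stems, anxiety$stems), prefixes = depressive$prefixes,
                  exclude_stems = integer(0)),
    depressive = depressive,
    anxiety = anxiety,
    sud = sud
  )
}

# Normalize an ICD-10 code: uppercase, strip whitespace and the dot.
# Returns NA for syntactically invalid codes.
icd_normalize <- function(code) {
  x <- toupper(gsub("[[:space:].]", "", as.character(code)))
  ok <- grepl("^[A-Z][0-9]{2}[0-9A-Z]{0,4}$", x)
  x[!ok] <- NA_character_
  x
}

icd_letter <- function(norm) substr(norm, 1L, 1L)
icd_stem <- function(norm) as.integer(substr(norm, 2L, 3L))

#' Classify an ICD-10 code into disorder groups
#'
#' Returns every disorder group whose code ranges contain the code.
#' Containment is by prefix: "F32.1" falls under the F32 block; "F34.12"
#' falls under F34.1. Tobacco use disorder (F17) is excluded from all
#' groups; non-F codes return an empty set.
#'
#' @param icd_code A single ICD-10 code string, e.g. "F31" or "F34.1".
#' @return Character vector of group names (possibly empty).
#' @examples
#' classify_disorder("F31")    # severe & bipolar (and the umbrella groups)
#' classify_disorder("F17.2")  # character(0): tobacco excluded
#' @export
classify_disorder <- function(icd_code) {
  stopifnot(length(icd_code) == 1L)
  norm <- icd_normalize(icd_code)
  if (is.na(norm)) stop("malformed ICD-10 code: ", icd_code)
  if (icd_letter(norm) != "F") return(character(0))
  stem <- icd_stem(norm)
  defs <- disorder_definitions()
  hit <- vapply(defs, function(d) {
    if (stem %in% d$exclude_stems) return(FALSE)
    if (stem %in% d$stems) return(TRUE)
    any(startsWith(norm, d$prefixes))
  }, logical(1))
  names(defs)[hit]
}

#' Disorder-group membership matrix for a vector of codes
#'
#' Vectorized companion to [classify_disorder()]: one row per code, one
#' logical column per disorder group. Invalid codes raise an error.
#'
#' @param icd_codes Character vector of ICD-10 codes.
#' @return Logical matrix `length(icd_codes)` x 9 with group columns.
#' @export
disorder_membership <- function(icd_codes) {
  norm <- icd_normalize(icd_codes)
  if (anyNA(norm) && any(!is.na(icd_codes) & is.na(norm)))
    stop("malformed ICD-10 code(s): ",
         paste(unique(icd_codes[!is.na(icd_codes) & is.na(norm)]), collapse = ", "))
  defs <- disorder_definitions()
  isF <- !is.na(norm) & icd_letter(norm) == "F"
  stem <- ifelse(isF, icd_stem(norm), NA_integer_)
  out <- matrix(FALSE, length(icd_codes), length(defs),
                dimnames = list(NULL, names(defs)))
  for (g in names(defs)) {
    d <- defs[[g]]
    m <- isF & stem %in% d$stems & !(stem %in% d$exclude_stems)
    if (length(d$prefixes))
      for (p in d$prefixes) m <- m | (isF & startsWith(norm, p))
    out[, g] <- m & !(stem %in% d$exclude_stems)
  }
  out
}

#' Cause-of-death taxonomy
#'
#' Defines which cause-of-death labels are distinguished. The detailed
#' taxonomy splits unnatural deaths into suicide, homicide, accident and
#' other unnatural causes; the grouped taxonomy merges them into a single
#' "unnatural" label (as used where sub-cause coding is unavailable).
#' Natural deaths are always banded by the last CD4 count within a year of
#' death (<200, 200-349, >=350 cells/ul, or unknown).
#'
#' @param name "detailed" or "grouped".
#' @return An object of class `cause_taxonomy` with elements `name`,
#'   `labels` (active labels, in reporting order), `natural_labels`,
#'   and `map` (named character vector: detailed label -> active label).
#' @export
cause_taxonomy <- function(name = c("detailed", "grouped")) {
  name <- match.arg(name)
  detailed <- c("natural_cd4_lt200", "natural_cd4_200_349", "natural_cd4_ge350",
                "natural_cd4_unknown", "suicide", "homicide", "accident",
                "unnatural_other", "unknown_cause")
  map <- stats::setNames(detailed, detailed)
  if (name == "grouped")
    map[c("suicide", "homicide", "accident", "unnatural_other")] <- "unnatural"
  labels <- unique(unname(map))
  structure(list(name = name, labels = labels,
                 natural_labels = detailed[1:4], map = map),
            class = "cause_taxonomy")
}

# Detailed unnatural sub-cause for a normalized code, or NA if the code is
# not in the unnatural universe (letters S,T,V,W,X,Y and U01-U03).
# Precedence suicide -> homicide -> accident; remaining external codes are
# unnatural_other.
unnatural_subcause <- function(norm) {
  letter <- icd_letter(norm)
  stem <- icd_stem(norm)
  n <- length(norm)
  out <- rep(NA_character_, n)
  external <- letter %in% c("S", "T", "V", "W", "X", "Y") |
    (letter == "U" & stem %in% 1:3)
  suicide <- (letter == "X" & stem >= 66 & stem <= 84) |
    (letter == "Y" & stem == 87 & startsWith(norm, "Y870")) |
    (letter == "U" & stem == 3L)
  homicide <- (letter == "X" & stem >= 85) | (letter == "Y" & stem <= 9) |
    (letter == "Y" & stem == 87 & startsWith(norm, "Y871")) |
    (letter == "U" & stem %in% 1:2)
  accident <- (letter == "S") | (letter == "T" & stem <= 79) |
    (letter %in% c("V", "W")) | (letter == "X" & stem <= 59) |
    (letter == "Y" & stem >= 10 & stem <= 36) |
    (letter == "Y" & stem >= 85 & stem <= 89)
  out[external] <- "unnatural_other"
  out[external & accident] <- "accident"
  out[external & homicide] <- "homicide"
  out[external & suicide] <- "suicide"
  out
}

#' Classify a death by ICD-10 code and CD4 count
#'
#' Deaths with a code in the printed unnatural ranges (suicide X66-84,
#' Y87.0, U03; homicide X85-Y09, Y87.1, U01-02; injuries/accidents S00-99,
#' T00-79, V00-99, W00-99, X00-59, Y10-36, Y85-89) are classified as
#' unnatural, with sub-cause precedence suicide, homicide, accident, then
#' other unnatural. All other resolvable codes are natural deaths, banded by
#' the last CD4 count within the year before death. Absent or unresolvable
#' codes map to `unknown_cause`.
#'
#' @param death_icd ICD-10 code string(s) or `NA`.
#' @param cd4_at_death CD4 count (cells/ul) or `NA` for unknown; must be
#'   non-negative.
#' @param taxonomy A [cause_taxonomy()]; sub-causes are merged per its map.
#' @return Character vector of cause labels from `taxonomy$labels`.
#' @examples
#' classify_death("X70", NA)                    # suicide
#' classify_death("C34.9", 150)                 # natural_cd4_lt200
#' @export
classify_death <- function(death_icd, cd4_at_death = NA_real_,
                           taxonomy = cause_taxonomy("detailed")) {
  stopifnot(inherits(taxonomy, "cause_taxonomy"))
  n <- max(length(death_icd), length(cd4_at_death))
  death_icd <- rep_len(as.character(death_icd), n)
  cd4 <- rep_len(as.numeric(cd4_at_death), n)
  if (any(!is.na(cd4) & cd4 < 0)) stop("negative CD4 count at death")
  norm <- icd_normalize(death_icd)
  out <- rep("unknown_cause", n)
  resolvable <- !is.na(norm) & nzchar(norm)
  sub <- unnatural_subcause(norm[resolvable])
  band <- ifelse(is.na(cd4[resolvable]), "natural_cd4_unknown",
          ifelse(cd4[resolvable] < 200, "natural_cd4_lt200",
          ifelse(cd4[resolvable] < 350, "natural_cd4_200_349", "natural_cd4_ge350")))
  out[resolvable] <- ifelse(is.na(sub), band, sub)
  lab <- unname(taxonomy$map[out])
  if (anyNA(lab)) stop("taxonomy lacks a label for: ",
                       paste(unique(out[is.na(lab)]), collapse = ", "))
  lab
}

#' Export the classification tables as machine-readable JSON
#'
#' Writes the disorder-group ICD ranges and the cause-of-death rule table to
#' a JSON file for audit.
#'
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_classification_json <- function(path) {
  obj <- list(
    disorder_groups = disorder_definitions(),
    cause_rules = list(
      suicide = c("X66-X84", "Y87.0", "U03"),
      homicide = c("X85-Y09", "Y87.1", "U01-U02"),
      accident = c("S00-S99", "T00-T79", "V00-V99", "W00-W99", "X00-X59",
                   "Y10-Y36", "Y85-Y89"),
      unnatural_other = "other codes with letters S,T,V,W,X,Y or U01-U03",
      natural = "all other resolvable codes, banded by CD4 (<200, 200-349, >=350, unknown)",
      unknown_cause = "absent or unresolvable code"
    ),
    cd4_bands = c("<200", "200-349", ">=350", "unknown")
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
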