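## Registry table schemas and delimited-text I/O.
##
## Four linked tables keyed by person_id: persons, dispensations, diagnoses,
## procedures.  Files are UTF-8 CSV with a header row and ISO dates.

EDUCATION_LEVELS <- c("elementary", "high_school", "higher_education",
                      "research", "unknown")
REGION_OF_BIRTH_LEVELS <- c("Nordics", "Africa", "Asia", "Europe_non_Nordic",
                            "North_America", "Oceania", "South_America")
GEO_REGION_LEVELS <- c("urban", "semi_urban", "semi_rural", "rural")
ROUTE_LEVELS <- c("oral", "transdermal", "local")
HORMONE_CONTENT_LEVELS <- c("oestrogen_only", "progestogen_only",
                            "fixed_combined_continuous",
                            "fixed_combined_sequential",
                            "tibolone", "lng_ius", "none")
DIAGNOSIS_SOURCES <- c("patient_register", "cause_of_death", "cancer_register")
PROCEDURE_LEVELS <- c("hysterectomy", "bilateral_oophorectomy",
                      "unilateral_oophorectomy", "sterilisation")

REGISTRY_SCHEMAS <- list(
  persons = c("person_id", "birth_date", "education", "region_of_birth",
              "geo_region", "first_registered", "death_date",
              "emigration_date"),
  dispensations = c("person_id", "dispense_date", "atc_code", "route",
                    "hormone_content", "oestrogen_dose", "progestogen_dose",
                    "n_packages", "ddd_per_package"),
  diagnoses = c("person_id", "event_date", "icd10_code", "source"),
  procedures = c("person_id", "event_date", "procedure")
)

check_columns <- function(df, table) {
  need <- REGISTRY_SCHEMAS[[table]]
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("table '%s' is missing required column(s): %s",
                 table, paste(miss, collapse = ", ")), call. = FALSE)
  df[need]
}

## Row-level invariant checks.  Violating rows are dropped with a warning
## carrying per-row diagnostics; structural problems are errors.
reject_rows <- function(df, bad, table, reason) {
  if (!any(bad)) return(df)
  warning(sprintf("%s: rejected %d row(s) (%s): line(s) %s",
                  table, sum(bad), reason,
                  paste(utils::head(which(bad) + 1L, 10L), collapse = ", ")),
          call. = FALSE)
  df[!bad, , drop = FALSE]
}

validate_persons <- function(df, file = "") {
  df <- check_columns(df, "persons")
  for (col in c("birth_date", "first_registered", "death_date",
                "emigration_date"))
    df[[col]] <- parse_date_column(df[[col]], col, file)
  df$person_id <- as.character(df$person_id)
  if (anyDuplicated(df$person_id))
    stop("persons: person_id values are not unique", call. = FALSE)
  bad <- (!is.na(df$death_date) & df$death_date < df$birth_date) |
    (!is.na(df$emigration_date) & df$emigration_date < df$birth_date)
  df <- reject_rows(df, bad, "persons", "death/emigration before birth")
  df <- reject_rows(df, !(df$education %in% EDUCATION_LEVELS),
                    "persons", "unknown education level")
  df <- reject_rows(df, !(df$region_of_birth %in% REGION_OF_BIRTH_LEVELS),
                    "persons", "unknown region of birth")
  df <- reject_rows(df, !(df$geo_region %in% GEO_REGION_LEVELS),
                    "persons", "unknown geographical region")
  df
}

validate_dispensations <- function(df, file = "") {
  df <- check_columns(df, "dispensations")
  df$dispense_date <- parse_date_column(df$dispense_date, "dispense_date", file)
  df$person_id <- as.character(df$person_id)
  for (col in c("oestrogen_dose", "progestogen_dose"))
    df[[col]] <- as.numeric(df[[col]])
  for (col in c("n_packages", "ddd_per_package"))
    df[[col]] <- as.integer(df[[col]])
  df <- reject_rows(df, is.na(df$ddd_per_package) | df$ddd_per_package < 1L,
                    "dispensations", "ddd_per_package < 1")
  df <- reject_rows(df, is.na(df$n_packages) | df$n_packages < 1L,
                    "dispensations", "n_packages < 1")
  df <- reject_rows(df, df$oestrogen_dose < 0 | df$progestogen_dose < 0,
                    "dispensations", "negative dose")
  df <- reject_rows(df, !(df$route %in% ROUTE_LEVELS),
                    "dispensations", "unknown route")
  df <- reject_rows(df, !(df$hormone_content %in% HORMONE_CONTENT_LEVELS),
                    "dispensations", "unknown hormone content")
  ## hormone content must be consistent with the dose fields
  bad <- (df$hormone_content == "oestrogen_only" & df$progestogen_dose > 0) |
    (df$hormone_content == "progestogen_only" & df$oestrogen_dose > 0) |
    (df$hormone_content %in% c("lng_ius", "none") & df$oestrogen_dose > 0)
  df <- reject_rows(df, bad, "dispensations",
                    "hormone_content inconsistent with doses")
  df
}

validate_diagnoses <- function(df, file = "") {
  df <- check_columns(df, "diagnoses")
  df$event_date <- parse_date_column(df$event_date, "event_date", file)
  df$person_id <- as.character(df$person_id)
  df$icd10_code <- as.character(df$icd10_code)
  reject_rows(df, !(df$source %in% DIAGNOSIS_SOURCES),
              "diagnoses", "unknown source register")
}

validate_procedures <- function(df, file = "") {
  df <- check_columns(df, "procedures")
  df$event_date <- parse_date_column(df$event_date, "event_date", file)
  df$person_id <- as.character(df$person_id)
  reject_rows(df, !(df$procedure %in% PROCEDURE_LEVELS),
              "procedures", "unknown procedure")
}

#' Assemble a validated registry bundle
#'
#' @param persons,dispensations,diagnoses,procedures data frames following
#'   the documented column schemas (see [read_registry()])
#' @return an object of class `mht_registry`: a list of the four validated
#'   tables
#' @export
new_registry <- function(persons, dispensations, diagnoses, procedures) {
  out <- list(
    persons       = validate_persons(persons),
    dispensations = validate_dispensations(dispensations),
    diagnoses     = validate_diagnoses(diagnoses),
    procedures    = validate_procedures(procedures)
  )
  structure(out, class = "mht_registry")
}

#' Read a registry bundle from delimited text files
#'
#' Expects `persons.csv`, `dispensations.csv`, `diagnoses.csv` and
#' `procedures.csv` (UTF-8, header row, ISO `YYYY-MM-DD` dates) either in a
#' directory or as a named list/vector of paths.  Rows violating row-level
#' invariants (e.g. `ddd_per_package < 1`, death before birth) are rejected
#' with a warning naming the offending lines; a missing required column or
#' an unparseable date is an error.
#'
#' @param paths a directory containing the four files, or a named character
#'   vector/list with elements `persons`, `dispensations`, `diagnoses`,
#'   `procedures`
#' @return an `mht_registry`
#' @export
read_registry <- function(paths) {
  if (is.character(paths) && length(paths) == 1L && dir.exists(paths)) {
    paths <- file.path(paths, paste0(names(REGISTRY_SCHEMAS), ".csv"))
    names(paths) <- names(REGISTRY_SCHEMAS)
  }
  paths <- as.list(paths)
  miss <- setdiff(names(REGISTRY_SCHEMAS), names(paths))
  if (length(miss))
    stop("read_registry: no path given for table(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  read1 <- function(p) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    utils::read.csv(p, stringsAsFactors = FALSE, colClasses = "character",
                    na.strings = c("NA", ""))
  }
  tabs <- lapply(paths[names(REGISTRY_SCHEMAS)], read1)
  new_registry(tabs$persons, tabs$dispensations, tabs$diagnoses,
               tabs$procedures)
}

#' Write a registry bundle to delimited text files
#'
#' @param registry an `mht_registry`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_registry <- function(registry, dir) {
  stopifnot(inherits(registry, "mht_registry"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(REGISTRY_SCHEMAS)) {
    df <- registry[[nm]]
    for (col in names(df))
      if (inherits(df[[col]], "Date")) df[[col]] <- format(df[[col]], "%Y-%m-%d")
    utils::write.csv(df, file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' @export
print.mht_registry <- function(x, ...) {
  cat("Linked registry bundle\n")
  cat(sprintf("  persons:       %d women\n", nrow(x$persons)))
  cat(sprintf("  dispensations: %d fills\n", nrow(x$dispensations)))
  cat(sprintf("  diagnoses:     %d records\n", nrow(x$diagnoses)))
  cat(sprintf("  procedures:    %d records\n", nrow(x$procedures)))
  invisible(x)
}
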