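## ICD-10 / ATC code lists driving inclusion, exclusion, outcomes and
## covariates.  ICD-10 matching is by prefix: the 3-character rubric I21
## matches I21, I210, I21.4 and so on.

#' Match codes against a set of prefixes
#'
#' Prefix semantics are used throughout for ICD-10 and ATC codes: a record
#' code matches if it starts with any listed prefix.  Matching is reflexive
#' (a code matches itself) and monotone (appending characters to a record's
#' code never removes a match against a shorter prefix).
#'
#' @param codes character vector of record codes (e.g. `"I210"`)
#' @param prefixes character vector of code prefixes (e.g. `"I21"`)
#' @return logical vector, one element per code
#' @examples
#' code_match(c("I210", "I63", "C509"), c("I21", "I22"))
#' @export
code_match <- function(codes, prefixes) {
  codes <- as.character(codes)
  out <- logical(length(codes))
  for (p in prefixes) out <- out | startsWith(codes, p)
  out & !is.na(codes)
}

#' Default code book
#'
#' Outcome sets use the published 3-character ICD-10 rubrics: ischaemic
#' heart disease I20/I21/I22/I24/I25, myocardial infarction I21/I22,
#' cerebral infarction I63, venous thromboembolism I26/I80/I81/I82, and the
#' composite cardiovascular outcome I20/I21/I22/I24/I25/I63.  Exclusion
#' diagnoses cover prior ischaemic heart disease, stroke, peripheral
#' vascular/arterial disease and any cancer; the exact supplementary code
#' lists of the source registries are not public, so these ship as editable
#' defaults covering the named conditions.
#'
#' @return an object of class `mht_codebook`
#' @seealso [load_codebook()], [write_codebook()]
#' @export
default_codebook <- function() {
  cb <- list(
    outcome_codes = list(
      ihd                = c("I20", "I21", "I22", "I24", "I25"),
      mi                 = c("I21", "I22"),
      cerebral_infarction = "I63",
      vte                = c("I26", "I80", "I81", "I82"),
      composite_cvd      = c("I20", "I21", "I22", "I24", "I25", "I63")
    ),
    exclusion_diagnosis_codes = c(
      "I20", "I21", "I22", "I24", "I25",  # ischaemic heart disease
      "I60", "I61", "I63", "I64",          # stroke
      "I70", "I73",                        # peripheral vascular/arterial
      "C"                                  # any cancer (chapter C)
    ),
    covariate_atc = list(
      hypertension  = c("C02", "C03", "C08", "C09"),
      heart_disease = c("C01", "C07", "B01"),
      diabetes      = "A10"
    ),
    mht_atc = c("G03C", "G03D", "G03F")
  )
  validate_codebook(cb)
}

#' Validate a code book
#'
#' Checks the structural invariants: the myocardial-infarction set is a
#' subset of the ischaemic-heart-disease set, the composite cardiovascular
#' set equals ihd plus cerebral infarction, and the venous-thromboembolism
#' set is disjoint (under prefix matching, in both directions) from the
#' composite set.
#'
#' @param cb a list with `outcome_codes`, `exclusion_diagnosis_codes`,
#'   `covariate_atc` and `mht_atc` components
#' @return the validated object, classed `mht_codebook`
#' @export
validate_codebook <- function(cb) {
  need <- c("outcome_codes", "exclusion_diagnosis_codes",
            "covariate_atc", "mht_atc")
  miss <- setdiff(need, names(cb))
  if (length(miss))
    stop("codebook is missing section(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  oc <- cb$outcome_codes
  need_oc <- c("ihd", "mi", "cerebral_infarction", "vte", "composite_cvd")
  miss <- setdiff(need_oc, names(oc))
  if (length(miss))
    stop("outcome_codes is missing set(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(oc$mi %in% oc$ihd))
    stop("codebook invariant violated: mi codes must be a subset of ihd",
         call. = FALSE)
  if (!setequal(oc$composite_cvd, union(oc$ihd, oc$cerebral_infarction)))
    stop("codebook invariant violated: composite_cvd must equal the union ",
         "of ihd and cerebral_infarction", call. = FALSE)
  cross <- outer(oc$vte, oc$composite_cvd,
                 Vectorize(function(a, b) startsWith(a, b) || startsWith(b, a)))
  if (any(cross))
    stop("codebook invariant violated: vte codes overlap composite_cvd codes",
         call. = FALSE)
  structure(cb, class = "mht_codebook")
}

#' Read a code book from a YAML file
#'
#' @param path path to a YAML file with the four named sections of
#'   [default_codebook()]
#' @return a validated `mht_codebook`
#' @export
load_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  raw$outcome_codes <- lapply(raw$outcome_codes, as.character)
  raw$covariate_atc <- lapply(raw$covariate_atc, as.character)
  raw$exclusion_diagnosis_codes <- as.character(raw$exclusion_diagnosis_codes)
  raw$mht_atc <- as.character(raw$mht_atc)
  validate_codebook(raw)
}

#' Write a code book to a YAML file
#' @param cb an `mht_codebook`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_codebook <- function(cb, path) {
  yaml::write_yaml(unclass(cb), path)
  invisible(path)
}

#' @export
print.mht_codebook <- function(x, ...) {
  cat("MHT analysis code book\n")
  for (nm in names(x$outcome_codes))
    cat(sprintf("  outcome %-20s %s\n", nm,
                paste(x$outcome_codes[[nm]], collapse = ", ")))
  cat("  exclusion diagnoses:", paste(x$exclusion_diagnosis_codes,
                                      collapse = ", "), "\n")
  cat("  systemic MHT ATC:   ", paste(x$mht_atc, collapse = ", "), "\n")
  for (nm in names(x$covariate_atc))
    cat(sprintf("  covariate ATC %-13s %s\n", nm,
                paste(x$covariate_atc[[nm]], collapse = ", ")))
  invisible(x)
}
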