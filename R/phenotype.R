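#' Expand an ICD-10 code into its description
#'
#' Exact-code lookup first, then longest-prefix fallback (so a table holding
#' only "I42" still describes "I42.1"). Unknown codes yield an empty string
#' with a warning; malformed codes are an error.
#'
#' @param code ICD-10 code string (letter + two digits, optional extension).
#' @param code_table Named character vector mapping codes to descriptions.
#' @return Description text ("" when unknown).
#' @export
expand_icd10 <- function(code, code_table) {
  if (!is.character(code) || length(code) != 1L ||
      !grepl("^[A-Za-z][0-9]{2}(\\.[0-9A-Za-z]{1,4})?$", code)) {
    stop("expand_icd10(): malformed ICD-10 code: ", deparse(code))
  }
  code <- toupper(code)
  keys <- names(code_table)
  hit <- match(code, keys)
  if (!is.na(hit)) return(unname(code_table[hit]))
  pref <- keys[startsWith(code, keys)]
  if (length(pref) > 0L) {
    return(unname(code_table[pref[which.max(nchar(pref))]]))
  }
  warning("expand_icd10(): unknown code ", code)
  ""
}

#' Read an ICD-10 code table from a two-column CSV
#'
#' @param path CSV with columns `code` and `description`.
#' @return Named character vector (code to description).
#' @export
read_icd10_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("code", "description") %in% names(df))) {
    stop("read_icd10_table(): need columns 'code' and 'description'")
  }
  stats::setNames(df$description, toupper(df$code))
}

#' The packaged minimal ICD-10 table
#'
#' Covers only the codes the default catalog references; full national code
#' tables are user-supplied.
#' @return Named character vector.
#' @export
default_icd10_table <- function() {
  read_icd10_table(system.file("extdata", "icd10_codes.csv", package = "fabryscreen",
                               mustWork = TRUE))
}

#' Derive clinical findings from structured laboratory results
#'
#' A finding (e.g. reduced eGFR) is emitted when the rule's comparator holds
#' on the value; a unit mismatch skips the result with a warning.
#'
#' @param labs List of lab results, each a list with `analyte`, `value`,
#'   `unit` (and optionally `flag`).
#' @param rules Laboratory rules (see [build_catalog()]).
#' @return Data frame with columns `finding`, `analyte`, `value`.
#' @export
parse_labs <- function(labs, rules) {
  out <- data.frame(finding = character(), analyte = character(),
                    value = numeric(), stringsAsFactors = FALSE)
  if (is.null(labs) || length(labs) == 0L || length(rules) == 0L) return(out)
  for (lab in labs) {
    for (rule in rules) {
      if (tolower(lab$analyte) != tolower(rule$analyte)) next
      if (!is.null(rule$unit) && !is.null(lab$unit) &&
          tolower(lab$unit) != tolower(rule$unit)) {
        warning("parse_labs(): unit mismatch for ", lab$analyte,
                " (", lab$unit, " vs ", rule$unit, "), skipped")
        next
      }
      cmp <- switch(rule$op,
                    "<" = lab$value < rule$threshold,
                    "<=" = lab$value <= rule$threshold,
                    ">" = lab$value > rule$threshold,
                    ">=" = lab$value >= rule$threshold,
                    stop("parse_labs(): unknown comparator ", rule$op))
      if (isTRUE(cmp)) {
        out <- rbind(out, data.frame(finding = rule$finding,
                                     analyte = lab$analyte,
                                     value = lab$value,
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out
}

# is a confounder/exclusion condition evidenced by affirmed mentions or codes?
condition_evidenced <- function(condition_id, catalog, affirmed_terms, icd_codes) {
  cond <- catalog$conditions[[condition_id]]
  if (is.null(cond)) return(FALSE)
  terms <- as.character(unlist(cond$terms %||% character()))
  prefixes <- as.character(unlist(cond$icd10_prefixes %||% character()))
  if (length(terms) > 0L && any(terms %in% affirmed_terms)) return(TRUE)
  if (length(prefixes) > 0L && length(icd_codes) > 0L) {
    for (p in prefixes) if (any(startsWith(toupper(icd_codes), toupper(p)))) return(TRUE)
  }
  FALSE
}

#' Apply cohort inclusion and exclusion criteria to a record
#'
#' A patient is excluded when their age falls outside the catalog's
#' inclusion bounds (default 18-75, inclusive), or when any cohort-level
#' exclusion condition (e.g. palliative care, chemotherapy) is evidenced by
#' an affirmed mention or an ICD-10 code. The reason names the first
#' criterion triggered, age first.
#'
#' @param record A patient record list (`age`, `icd10_codes`, ...).
#' @param catalog An `fd_catalog`.
#' @param entities Optional pre-computed entity data frame for the record
#'   (from [extract_record_entities()]); affirmed mentions are used as
#'   condition evidence.
#' @return List with `eligible` (logical) and, when excluded, `reason`.
#' @export
cohort_filter <- function(record, catalog, entities = NULL) {
  age <- record$age
  if (is.null(age) || is.na(age)) return(list(eligible = FALSE, reason = "age"))
  if (age < catalog$inclusion$age_min || age > catalog$inclusion$age_max) {
    return(list(eligible = FALSE, reason = "age"))
  }
  affirmed <- affirmed_term_ids(entities)
  codes <- as.character(unlist(record$icd10_codes %||% character()))
  for (cid in catalog$cohort_exclusions) {
    if (condition_evidenced(cid, catalog, affirmed, codes)) {
      return(list(eligible = FALSE, reason = cid))
    }
  }
  list(eligible = TRUE)
}

affirmed_term_ids <- function(entities) {
  if (is.null(entities) || NROW(entities) == 0L) return(character())
  unique(entities$term_id[entities$polarity == "affirmed"])
}

#' Map evidence onto clinical features (pre-exclusion)
#'
#' A feature is present when at least one of its evidence channels fires:
#' an affirmed entity whose term id is listed for the feature, an ICD-10
#' code matching one of its prefixes, or a lab-derived finding. Negated
#' mentions never count; each presence records its supporting evidence.
#'
#' @param entities Entity data frame (only affirmed rows are used).
#' @param icd_codes Character vector of the record's ICD-10 codes.
#' @param lab_findings Data frame from [parse_labs()] (or NULL).
#' @param catalog An `fd_catalog`.
#' @param patient_id Optional id carried through to the assignment.
#' @return An object of class `fd_assignment`: list with `patient_id`,
#'   `present` (named list feature_id -> character vector of evidence
#'   descriptors) and `vetoed` (named list feature_id -> vetoing condition).
#' @export
assign_features <- function(entities, icd_codes = character(),
                            lab_findings = NULL, catalog = default_catalog(),
                            patient_id = NA_character_) {
  affirmed <- affirmed_term_ids(entities)
  codes <- toupper(as.character(unlist(icd_codes %||% character())))
  findings <- if (is.null(lab_findings) || NROW(lab_findings) == 0L) character() else lab_findings$finding
  present <- list()
  for (fid in catalog$order) {
    f <- catalog$features[[fid]]
    ev <- character()
    hit_terms <- intersect(f$evidence_terms, affirmed)
    if (length(hit_terms) > 0L) ev <- c(ev, paste0("term:", hit_terms))
    if (length(f$icd10_prefixes) > 0L && length(codes) > 0L) {
      for (p in f$icd10_prefixes) {
        hc <- codes[startsWith(codes, toupper(p))]
        if (length(hc) > 0L) ev <- c(ev, paste0("icd10:", hc))
      }
    }
    hit_lab <- intersect(f$lab_findings, findings)
    if (length(hit_lab) > 0L) ev <- c(ev, paste0("lab:", hit_lab))
    if (length(ev) > 0L) present[[fid]] <- unique(ev)
  }
  structure(list(patient_id = patient_id, present = present, vetoed = list()),
            class = "fd_assignment")
}

#' Apply feature-level exclusion (veto) rules
#'
#' A present feature is vetoed when any of its confounder conditions is
#' evidenced in the same record (affirmed mention or ICD-10 code): e.g.
#' amyloidosis vetoes renal failure, a patent foramen ovale vetoes stroke.
#' Vetoed features score zero downstream. The operation is idempotent.
#'
#' @param assignment An `fd_assignment` from [assign_features()].
#' @param record The patient record (for its ICD-10 codes).
#' @param catalog An `fd_catalog`.
#' @param entities Entity data frame for the record (affirmed mentions are
#'   condition evidence).
#' @return The finalized `fd_assignment`.
#' @export
apply_exclusions <- function(assignment, record, catalog, entities = NULL) {
  stopifnot(inherits(assignment, "fd_assignment"))
  affirmed <- affirmed_term_ids(entities)
  codes <- as.character(unlist(record$icd10_codes %||% character()))
  for (fid in names(assignment$present)) {
    f <- catalog$features[[fid]]
    for (cid in f$exclusion_conditions) {
      if (condition_evidenced(cid, catalog, affirmed, codes)) {
        assignment$vetoed[[fid]] <- cid
        assignment$present[[fid]] <- NULL
        break
      }
    }
  }
  assignment
}

#' @export
print.fd_assignment <- function(x, ...) {
  cat("fd_assignment", if (!is.na(x$patient_id)) paste0("(", x$patient_id, ")"), ":",
      length(x$present), "present,", length(x$vetoed), "vetoed\n")
  invisible(x)
}
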