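#' Build a clinical feature catalog
#'
#' The catalog defines the scored clinical features (default: 13 features in
#' 5 sign groups), the confounder conditions that can veto them, the cohort
#' inclusion/exclusion rules, and the laboratory threshold rules.
#'
#' @param features List of feature definitions; each a list with
#'   `feature_id`, `name`, `sign_group`, `base_score` (0-3), optional
#'   `age_modifier` (list with `age_below` and `score`, the boosted value,
#'   capped at 3), `evidence_terms` (lexicon term ids), `icd10_prefixes`,
#'   `lab_findings`, `exclusion_conditions` (condition ids).
#' @param conditions Named list of confounder/exclusion conditions, each a
#'   list with `terms` (lexicon term ids) and `icd10_prefixes`.
#' @param inclusion List with `age_min`, `age_max` (cohort age bounds).
#' @param cohort_exclusions Character vector of condition ids that remove a
#'   patient from the cohort entirely.
#' @param lab_rules List of laboratory rules, each with `analyte`, `op`
#'   (one of `<`, `<=`, `>`, `>=`), `threshold`, `unit`, `finding`.
#' @return An object of class `fd_catalog`.
#' @export
build_catalog <- function(features, conditions = list(),
                          inclusion = list(age_min = 18, age_max = 75),
                          cohort_exclusions = character(),
                          lab_rules = list()) {
  groups <- c("cardiovascular", "kidney", "skin", "neurological", "eye")
  ids <- vapply(features, function(f) f$feature_id, "")
  if (anyDuplicated(ids)) stop("build_catalog(): duplicate feature ids")
  feats <- list()
  for (f in features) {
    if (!f$sign_group %in% groups) {
      stop("build_catalog(): unknown sign group '", f$sign_group, "' for ", f$feature_id)
    }
    bs <- as.integer(f$base_score)
    if (bs < 0L || bs > 3L) stop("build_catalog(): base_score out of [0,3] for ", f$feature_id)
    am <- f$age_modifier
    if (!is.null(am)) {
      am$score <- min(3L, as.integer(am$score))
      am$age_below <- as.numeric(am$age_below)
    }
    feats[[f$feature_id]] <- list(
      feature_id = f$feature_id,
      name = f$name %||% f$feature_id,
      sign_group = f$sign_group,
      base_score = bs,
      age_modifier = am,
      evidence_terms = as.character(unlist(f$evidence_terms %||% character())),
      icd10_prefixes = as.character(unlist(f$icd10_prefixes %||% character())),
      lab_findings = as.character(unlist(f$lab_findings %||% character())),
      exclusion_conditions = as.character(unlist(f$exclusion_conditions %||% character())))
  }
  cond_ids <- names(conditions)
  for (f in feats) {
    bad <- setdiff(f$exclusion_conditions, cond_ids)
    if (length(bad) > 0L) {
      stop("build_catalog(): feature ", f$feature_id,
           " references unknown condition(s): ", paste(bad, collapse = ", "))
    }
  }
  bad <- setdiff(cohort_exclusions, cond_ids)
  if (length(bad) > 0L) {
    stop("build_catalog(): unknown cohort exclusion condition(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(features = feats, order = names(feats),
                 conditions = conditions,
                 inclusion = list(age_min = as.numeric(inclusion$age_min %||% 18),
                                  age_max = as.numeric(inclusion$age_max %||% 75)),
                 cohort_exclusions = cohort_exclusions,
                 lab_rules = lab_rules),
            class = "fd_catalog")
}

#' @export
print.fd_catalog <- function(x, ...) {
  tab <- table(vapply(x$features, function(f) f$sign_group, ""))
  cat("fd_catalog:", length(x$features), "clinical features in",
      length(tab), "sign groups\n")
  for (g in names(tab)) cat("  ", g, ": ", tab[[g]], "\n", sep = "")
  invisible(x)
}

#' Read a feature catalog from YAML or JSON
#'
#' @param path File path mirroring the arguments of [build_catalog()].
#' @return An `fd_catalog`.
#' @export
read_catalog <- function(path) {
  spec <- read_config_file(path)
  if (is.null(spec$features)) stop("read_catalog(): no 'features' in ", path)
  build_catalog(features = spec$features,
                conditions = spec$conditions %||% list(),
                inclusion = spec$inclusion %||% list(age_min = 18, age_max = 75),
                cohort_exclusions = as.character(unlist(spec$cohort_exclusions %||% character())),
                lab_rules = spec$lab_rules %||% list())
}

#' The packaged default 13-feature catalog
#'
#' A reconstruction of a Fabry-disease screening feature set: 13 clinical
#' features in the five classic sign groups (cardiovascular, kidney, skin,
#' neurological, eye), scored 0-3 with age boosts for features that are
#' normally diseases of the elderly (stroke, myocardial infarction, renal
#' failure, hearing loss) when seen before age 55. Membership, scores and
#' thresholds are configuration, not code; this default is documented as a
#' reconstruction, not a published table.
#'
#' @return An `fd_catalog`.
#' @export
default_catalog <- function() {
  read_catalog(system.file("extdata", "catalog.yaml", package = "fabryscreen",
                           mustWork = TRUE))
}
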