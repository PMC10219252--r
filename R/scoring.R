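#' Score one clinical feature for one patient
#'
#' Absent (or vetoed) features score 0. A present feature scores its base
#' score, raised to the age modifier's boosted value when the patient is
#' younger than the modifier's threshold — features that are normally
#' diseases of the elderly weigh more when seen in the young. Scores never
#' exceed 3.
#'
#' @param feature A feature definition from an `fd_catalog`.
#' @param present Logical, whether the feature is present (and not vetoed).
#' @param age Patient age in years.
#' @return Integer score in 0-3.
#' @export
score_feature <- function(feature, present, age) {
  stopifnot(age >= 0)
  if (!isTRUE(present)) return(0L)
  s <- feature$base_score
  am <- feature$age_modifier
  if (!is.null(am) && age < am$age_below) s <- max(s, am$score)
  min(3L, as.integer(s))
}

#' Compute a patient's screening risk factor
#'
#' Scores every catalog feature (present, non-vetoed features score as in
#' [score_feature()]; all others 0) and sums the scores into the per-patient
#' risk factor.
#'
#' @param assignment Finalized `fd_assignment` (exclusions applied).
#' @param record The patient record (for `age` and `patient_id`).
#' @param catalog An `fd_catalog`.
#' @return An object of class `fd_risk_profile`: list with `patient_id`,
#'   `feature_scores` (named integer vector over all catalog features),
#'   `risk_factor` (their sum) and `age_boost_applied` (feature ids whose
#'   age modifier raised the score).
#' @export
compute_risk_factor <- function(assignment, record, catalog) {
  age <- record$age
  scores <- stats::setNames(integer(length(catalog$order)), catalog$order)
  boosted <- character()
  for (fid in catalog$order) {
    f <- catalog$features[[fid]]
    present <- fid %in% names(assignment$present)
    s <- score_feature(f, present, age)
    scores[fid] <- s
    if (present && !is.null(f$age_modifier) && age < f$age_modifier$age_below &&
        s > f$base_score) {
      boosted <- c(boosted, fid)
    }
  }
  structure(list(patient_id = record$patient_id %||% assignment$patient_id,
                 feature_scores = scores,
                 risk_factor = sum(scores),
                 age_boost_applied = boosted),
            class = "fd_risk_profile")
}

#' @export
print.fd_risk_profile <- function(x, ...) {
  cat("fd_risk_profile", if (!is.null(x$patient_id)) paste0("(", x$patient_id, ")"),
      "- risk factor", x$risk_factor, "\n")
  nz <- x$feature_scores[x$feature_scores > 0]
  if (length(nz) > 0) {
    for (i in seq_along(nz)) cat("  ", names(nz)[i], ": ", nz[i], "\n", sep = "")
  }
  invisible(x)
}

#' Rank a cohort by risk factor
#'
#' Stable descending sort; ties keep input order.
#'
#' @param profiles Data frame with a `risk_factor` column (one row per
#'   patient), or a list of `fd_risk_profile` objects.
#' @return The input, reordered by decreasing risk factor.
#' @export
rank_cohort <- function(profiles) {
  if (is.data.frame(profiles)) {
    if (nrow(profiles) == 0L) return(profiles)
    out <- profiles[order(-profiles$risk_factor), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  if (length(profiles) == 0L) return(profiles)
  rf <- vapply(profiles, function(p) p$risk_factor, 0)
  profiles[order(-rf)]
}
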