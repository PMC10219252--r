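#' Screen a cohort of patient records for Fabry disease risk
#'
#' Runs the full pipeline over a cohort: entity extraction from free-text
#' notes (ICD-10 codes are first expanded to descriptions and processed as
#' an additional note), cohort inclusion/exclusion filtering, mapping of
#' affirmed evidence and labs onto the clinical feature catalog, confounder
#' vetoes, and per-patient risk scoring.
#'
#' @param records List of patient records (see [read_records()]), each with
#'   `patient_id`, `age`, `sex`, `notes`, `icd10_codes`, `labs`, and
#'   optionally `true_label`.
#' @param lexicon An `fd_lexicon` (default: the packaged English lexicon).
#' @param catalog An `fd_catalog` (default: the packaged 13-feature catalog).
#' @param icd10_table Named code-to-description vector for ICD-10 expansion.
#' @param config Matcher settings from [matcher_config()].
#' @param cutoff Integer decision cut-off on the risk factor (predicted
#'   positive when risk factor >= cutoff).
#' @param keep_entities Keep per-patient entity tables in the result (off by
#'   default to bound memory on large cohorts).
#' @return An object of class `fd_screen` with components `profiles` (data
#'   frame: `patient_id`, `age`, `sex`, one column per catalog feature,
#'   `risk_factor`, `true_label`), `excluded` (data frame of filtered-out
#'   patients with reasons), `assignments`, `cutoff`, `catalog`, `lexicon`,
#'   `config`.
#' @examples
#' lex <- default_lexicon()
#' cat13 <- default_catalog()
#' rec <- list(patient_id = "p1", age = 40, sex = "male",
#'             notes = "Angiokeratoma present. No proteinuria.",
#'             icd10_codes = list("I42.1"), labs = list())
#' scr <- fd_screen(list(rec), lexicon = lex, catalog = cat13)
#' scr$profiles$risk_factor
#' @export
fd_screen <- function(records, lexicon = default_lexicon(),
                      catalog = default_catalog(),
                      icd10_table = default_icd10_table(),
                      config = matcher_config(), cutoff = 4L,
                      keep_entities = FALSE) {
  res <- lapply(records, screen_record, lexicon = lexicon, catalog = catalog,
                icd10_table = icd10_table, config = config,
                keep_entities = keep_entities)
  eligible <- vapply(res, function(r) r$eligible, TRUE)
  prof_rows <- lapply(res[eligible], function(r) r$profile_row)
  profiles <- if (length(prof_rows) > 0L) {
    do.call(rbind, prof_rows)
  } else {
    empty_profile_frame(catalog)
  }
  rownames(profiles) <- NULL
  excl <- res[!eligible]
  excluded <- data.frame(
    patient_id = vapply(excl, function(r) as.character(r$patient_id), ""),
    reason = vapply(excl, function(r) r$reason, ""),
    stringsAsFactors = FALSE)
  structure(list(profiles = profiles,
                 excluded = excluded,
                 assignments = lapply(res[eligible], function(r) r$assignment),
                 entities = if (keep_entities) lapply(res, function(r) r$entities) else NULL,
                 cutoff = as.integer(cutoff),
                 catalog = catalog, lexicon = lexicon, config = config,
                 call = match.call()),
            class = "fd_screen")
}

empty_profile_frame <- function(catalog) {
  cols <- c(list(patient_id = character(), age = numeric(), sex = character()),
            stats::setNames(rep(list(integer()), length(catalog$order)), catalog$order),
            list(risk_factor = integer(), true_label = character()))
  do.call(data.frame, c(cols, stringsAsFactors = FALSE))
}

# run one record through extract -> filter -> assign -> veto -> score
screen_record <- function(record, lexicon, catalog, icd10_table, config,
                          keep_entities = FALSE) {
  icd_codes <- as.character(unlist(record$icd10_codes %||% character()))
  icd_text <- if (length(icd_codes) > 0L) {
    descs <- vapply(icd_codes, function(cd) {
      tryCatch(suppressWarnings(expand_icd10(cd, icd10_table)),
               error = function(e) "")
    }, "")
    descs <- descs[nzchar(descs)]
    if (length(descs) > 0L) paste0(descs, ".", collapse = " ") else NULL
  } else NULL
  rec <- record
  rec$notes <- c(as.character(unlist(record$notes %||% character())), icd_text)
  entities <- extract_record_entities(rec, lexicon, config)
  filt <- cohort_filter(record, catalog, entities)
  if (!filt$eligible) {
    return(list(eligible = FALSE, patient_id = record$patient_id %||% NA_character_,
                reason = filt$reason,
                entities = if (keep_entities) entities else NULL))
  }
  labs <- parse_labs(record$labs, catalog$lab_rules)
  assignment <- assign_features(entities, icd_codes, labs, catalog,
                                patient_id = record$patient_id %||% NA_character_)
  assignment <- apply_exclusions(assignment, record, catalog, entities)
  profile <- compute_risk_factor(assignment, record, catalog)
  row <- data.frame(patient_id = as.character(record$patient_id %||% NA_character_),
                    age = record$age, sex = record$sex %||% NA_character_,
                    stringsAsFactors = FALSE)
  for (fid in catalog$order) row[[fid]] <- profile$feature_scores[[fid]]
  row$risk_factor <- profile$risk_factor
  row$true_label <- record$true_label %||% NA_character_
  list(eligible = TRUE, profile_row = row, assignment = assignment,
       profile = profile, entities = if (keep_entities) entities else NULL)
}

#' @export
print.fd_screen <- function(x, ...) {
  n <- nrow(x$profiles)
  cat("Fabry disease screening of", n, "eligible patients",
      sprintf("(%d excluded)\n", nrow(x$excluded)))
  cat("Risk factor: median", stats::median(x$profiles$risk_factor),
      " max", max(c(x$profiles$risk_factor, 0L)), "\n")
  cat("Cut-off", x$cutoff, "->", sum(x$profiles$risk_factor >= x$cutoff),
      "patients flagged for review\n")
  invisible(x)
}

#' Summarize a screening run
#'
#' Tabulates the risk-factor distribution and, when true labels are
#' available, evaluates screening performance at the chosen cut-off
#' (confusion matrix, accuracy/precision/recall/specificity/F1, cut-off
#' sweep, ROC and PR areas, enrichment versus a 1:40,000 population rate).
#'
#' @param object An `fd_screen`.
#' @param cutoff Cut-off override (defaults to the object's).
#' @param population_rate Background disease rate expressed as 1-in-N.
#' @param ... Unused.
#' @return An object of class `summary.fd_screen`.
#' @export
summary.fd_screen <- function(object, cutoff = object$cutoff,
                              population_rate = 40000, ...) {
  prof <- object$profiles
  out <- list(n = nrow(prof), n_excluded = nrow(object$excluded),
              cutoff = cutoff,
              score_table = table(prof$risk_factor),
              n_flagged = sum(prof$risk_factor >= cutoff))
  if (any(!is.na(prof$true_label))) {
    labeled <- prof[!is.na(prof$true_label), , drop = FALSE]
    cm <- confusion_at_cutoff(labeled, cutoff)
    out$confusion <- cm
    out$metrics <- screen_metrics(cm)
    out$sweep <- sweep_cutoffs(labeled, 3:11)
    if (length(unique(labeled$true_label)) == 2L) {
      out$curves <- roc_pr_curves(labeled)
    }
    out$enrichment <- tryCatch(enrichment_ratio(cm, population_rate),
                               error = function(e) NULL)
  }
  class(out) <- "summary.fd_screen"
  out
}

#' @export
print.summary.fd_screen <- function(x, ...) {
  cat("Cohort:", x$n, "eligible patients,", x$n_excluded, "excluded\n")
  cat("Flagged at cut-off ", x$cutoff, ": ", x$n_flagged, "\n", sep = "")
  if (!is.null(x$confusion)) {
    cm <- x$confusion
    cat(sprintf("Confusion (cutoff %d): TP=%d FP=%d TN=%d FN=%d\n",
                x$cutoff, cm$TP, cm$FP, cm$TN, cm$FN))
    m <- x$metrics
    cat(sprintf("accuracy %.3f  sensitivity %.1f%%  specificity %.2f%%\n",
                m$accuracy, 100 * m$recall, 100 * m$specificity))
    cat(sprintf("precision %.4f  F1 %.4f\n", m$precision, m$f1))
    if (!is.null(x$curves)) {
      cat(sprintf("AUC-ROC %.3f  AUC-PR %.3f\n", x$curves$auc_roc, x$curves$auc_pr))
    }
    if (!is.null(x$enrichment)) {
      if (isTRUE(x$enrichment$all_true_positive)) {
        cat("Flagged group contains no false positives\n")
      } else {
        cat(sprintf("Flagged case:control ratio 1:%d (%d-fold over 1:%d population rate)\n",
                    x$enrichment$k, x$enrichment$fold, x$enrichment$population_n))
      }
    }
  }
  invisible(x)
}

#' Feature score table of a screening run
#'
#' Returns the scoring weights in use: base score and (where defined) the
#' age-boosted score and its age threshold, per clinical feature.
#'
#' @param object An `fd_screen`.
#' @param ... Unused.
#' @return Data frame of per-feature scoring parameters.
#' @export
coef.fd_screen <- function(object, ...) {
  feats <- object$catalog$features
  data.frame(
    feature_id = names(feats),
    sign_group = vapply(feats, function(f) f$sign_group, ""),
    base_score = vapply(feats, function(f) f$base_score, 0L),
    boost_score = vapply(feats, function(f)
      if (is.null(f$age_modifier)) NA_integer_ else f$age_modifier$score, NA_integer_),
    boost_age_below = vapply(feats, function(f)
      if (is.null(f$age_modifier)) NA_real_ else f$age_modifier$age_below, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Score new records with an existing screening configuration
#'
#' @param object An `fd_screen`.
#' @param newdata List of patient records; defaults to returning the
#'   training cohort's values.
#' @param type `"risk"` for numeric risk factors, `"class"` for the
#'   flagged/not-flagged decision at the object's cut-off.
#' @param ... Unused.
#' @return Named numeric vector (risk) or character vector (class).
#' @export
predict.fd_screen <- function(object, newdata = NULL,
                              type = c("risk", "class"), ...) {
  type <- match.arg(type)
  prof <- if (is.null(newdata)) {
    object$profiles
  } else {
    fd_screen(newdata, lexicon = object$lexicon, catalog = object$catalog,
              config = object$config, cutoff = object$cutoff)$profiles
  }
  rf <- stats::setNames(prof$risk_factor, prof$patient_id)
  if (type == "risk") rf else {
    stats::setNames(ifelse(rf >= object$cutoff, "flagged", "not_flagged"), names(rf))
  }
}

#' Plot the risk-factor distribution of a screened cohort
#'
#' Histogram of risk factors; when labels are present, cases and controls
#' are drawn separately and the cut-off marked.
#'
#' @param x An `fd_screen`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.fd_screen <- function(x, ...) {
  prof <- x$profiles
  rng <- 0:max(c(prof$risk_factor, x$cutoff, 1L))
  if (any(!is.na(prof$true_label))) {
    pos <- table(factor(prof$risk_factor[prof$true_label == "FD-positive"], levels = rng))
    neg <- table(factor(prof$risk_factor[prof$true_label == "control"], levels = rng))
    m <- rbind(control = as.numeric(neg), case = as.numeric(pos))
    graphics::barplot(m, beside = TRUE, names.arg = rng,
                      col = c("grey70", "firebrick"),
                      xlab = "risk factor", ylab = "patients",
                      legend.text = c("control", "case"), ...)
  } else {
    tab <- table(factor(prof$risk_factor, levels = rng))
    graphics::barplot(as.numeric(tab), names.arg = rng,
                      xlab = "risk factor", ylab = "patients", ...)
  }
  invisible(x)
}
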