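#' Read patient records from a JSON Lines file
#'
#' One JSON object per line with fields `patient_id`, `age`, `sex`, `notes`
#' (string or array of strings), `icd10_codes`, `labs`, optional
#' `true_label`. Malformed lines are skipped with a warning.
#'
#' @param path File path.
#' @return List of patient record lists.
#' @export
read_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e) NULL)
    if (is.null(rec) || is.null(rec$patient_id)) {
      warning("read_records(): skipping malformed record on line ", i)
      next
    }
    rec$age <- as.numeric(rec$age %||% NA_real_)
    rec$notes <- as.character(unlist(rec$notes %||% character()))
    rec$icd10_codes <- as.list(unlist(rec$icd10_codes %||% character()))
    rec$true_label <- if (is.null(rec$true_label)) NULL else as.character(rec$true_label)
    out[[i]] <- rec
    keep[i] <- TRUE
  }
  out[keep]
}

#' Write patient records to a JSON Lines file
#' @param records List of patient record lists.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(r)
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA, null = "null")), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write gold annotations to JSON Lines
#' @param gold List of gold annotation lists (see [generate_cohort()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gold <- function(gold, path) {
  lines <- vapply(gold, function(g) {
    g$mentions <- if (NROW(g$mentions) > 0L) g$mentions else list()
    as.character(jsonlite::toJSON(g, auto_unbox = TRUE, digits = NA, dataframe = "rows"))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read gold annotations from JSON Lines
#' @param path File path.
#' @return List of gold annotation lists with `mentions` as a data frame.
#' @export
read_gold <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    g <- jsonlite::fromJSON(ln, simplifyVector = TRUE)
    if (is.null(g$mentions) || NROW(g$mentions) == 0L) {
      g$mentions <- data.frame(term_id = character(), note_index = integer(),
                               sentence_index = integer(), start = integer(),
                               end = integer(), polarity = character(),
                               stringsAsFactors = FALSE)
    }
    g$true_features <- as.character(unlist(g$true_features))
    g
  })
}

#' Write a per-patient score table to CSV
#'
#' Fixed column order: `patient_id`, `age`, `sex`, one column per catalog
#' feature (in catalog order), `risk_factor`, `true_label`.
#'
#' @param profiles Profile data frame from [fd_screen()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(profiles, path) {
  utils::write.csv(profiles, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write a cohort evaluation report to JSON
#'
#' @param evaluation List as produced by [cmd_evaluate()] internals:
#'   confusion matrix, metrics, cut-off sweep, curves, enrichment.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(evaluation, path) {
  jsonlite::write_json(evaluation, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}
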