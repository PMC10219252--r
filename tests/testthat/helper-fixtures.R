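# Shared fixtures and independent oracles, built in code at test time.

tiny_lexicon <- function() {
  build_lexicon(list(
    list(term_id = "angiokeratoma", canonical = "angiokeratoma",
         feature_id = "angiokeratoma"),
    list(term_id = "proteinuria", canonical = "proteinuria",
         synonyms = list("protein in urine"), feature_id = "proteinuria"),
    list(term_id = "cornea", canonical = "cornea", feature_id = "eye"),
    list(term_id = "cornea_verticillata", canonical = "cornea verticillata",
         feature_id = "cornea_verticillata"),
    list(term_id = "stroke", canonical = "stroke", feature_id = "stroke")))
}

# naive O(n*m) scan oracle for pattern matching: enumerate every
# (entry, pattern, start) literal hit, then resolve longest / leftmost /
# lexicon-order greedily
naive_match_oracle <- function(tokens, lexicon) {
  cand <- list()
  for (ei in seq_along(lexicon$order)) {
    e <- lexicon$entries[[lexicon$order[ei]]]
    for (pat in e$patterns) {
      ptoks <- attr(pat, "tokens")
      m <- length(ptoks)
      if (m > length(tokens) || m == 0L) next
      for (s in seq_len(length(tokens) - m + 1L)) {
        if (all(tokens[s:(s + m - 1L)] == ptoks)) {
          cand[[length(cand) + 1L]] <- list(term = e$term_id, start = s,
                                            len = m, ord = ei)
        }
      }
    }
  }
  if (length(cand) == 0L) {
    return(data.frame(term_id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  lens <- vapply(cand, `[[`, 0L, "len")
  starts <- vapply(cand, `[[`, 0L, "start")
  ords <- vapply(cand, `[[`, 0L, "ord")
  o <- order(-lens, starts, ords)
  taken <- logical(length(tokens))
  rows <- list()
  for (i in o) {
    idx <- starts[i]:(starts[i] + lens[i] - 1L)
    if (!any(taken[idx])) {
      taken[idx] <- TRUE
      rows[[length(rows) + 1L]] <- data.frame(term_id = cand[[i]]$term,
                                              start = starts[i] - 1L,
                                              end = starts[i] + lens[i] - 1L,
                                              stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# rank-statistic (Mann-Whitney) formulation of the ROC area
rank_auc_oracle <- function(case_scores, control_scores) {
  r <- rank(c(case_scores, control_scores))
  nx <- length(case_scores); ny <- length(control_scores)
  (sum(r[seq_len(nx)]) - nx * (nx + 1) / 2) / (nx * ny)
}

# per-patient recount of the confusion matrix
recount_oracle <- function(profiles, cutoff) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(profiles))) {
    pos <- profiles$risk_factor[i] >= cutoff
    case <- profiles$true_label[i] == "FD-positive"
    if (pos && case) tp <- tp + 1L
    else if (pos && !case) fp <- fp + 1L
    else if (!pos && case) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# exhaustive-enumeration two-sided Fisher p for a 2x2 table
fisher_enum_oracle <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# a random labeled cohort for evaluation properties
random_cohort <- function(n_cases, n_controls) {
  data.frame(
    patient_id = sprintf("p%03d", seq_len(n_cases + n_controls)),
    risk_factor = c(sample(0:12, n_cases, replace = TRUE, prob = (1:13)^1.5),
                    sample(0:8, n_controls, replace = TRUE, prob = (9:1)^2)),
    true_label = rep(c("FD-positive", "control"), c(n_cases, n_controls)),
    stringsAsFactors = FALSE)
}
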