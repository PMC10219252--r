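#' Default synthetic cohort specification
#'
#' The default emulates, at desk scale, a highly imbalanced hospital
#' screening cohort: 5 cases to 7,450 controls (about the 1:1,490 case:
#' control imbalance of the motivating cohort), truncated-normal ages
#' (cases mean 45.2, SD 10.5; controls mean 55.5, SD 13.3; clipped to
#' 18-75), sex ratios of 38.5% / 50.5% female, and per-feature presence
#' probabilities chosen so that control sign-group frequencies match the
#' published group marginals (cardiovascular 34.3%, skin 0.8%, neurological
#' 26.0%, kidney 10.5%, eye 1.5%) while case risk factors concentrate in
#' 3-11 and control risk factors in 0-3.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param seed Integer seed; fully determines the generated cohort.
#' @param case_feature_probs,control_feature_probs Named per-feature
#'   presence probabilities (defaults described above).
#' @param negation_rate Probability that a record carries a denial sentence
#'   for one absent feature (exercises negation handling).
#' @param typo_rate Probability that a planted text mention carries a
#'   recoverable single-character typo.
#' @param paraphrase_rate Probability that a text mention uses a synonym
#'   instead of the canonical form.
#' @param confounder_rate Probability that a present renal-failure or
#'   stroke feature is accompanied by a vetoing confounder condition.
#' @param distractor_range Integer range (min, max) of distractor sentences
#'   per note.
#' @param channel_probs Probabilities that a present feature is realized as
#'   free text, an ICD-10 code, or a laboratory value (falls back to text
#'   when a feature has no code/lab evidence).
#' @param case_age,control_age Lists with `mean` and `sd` of the truncated
#'   normal age distributions.
#' @param age_bounds Truncation bounds for age.
#' @param case_female,control_female Probability of female sex per group.
#' @return A list of class `fd_cohort_spec`.
#' @export
cohort_spec <- function(n_cases = 5L, n_controls = 7450L, seed = 20230522L,
                        case_feature_probs = default_case_feature_probs(),
                        control_feature_probs = default_control_feature_probs(),
                        negation_rate = 0.3, typo_rate = 0.1,
                        paraphrase_rate = 0.2, confounder_rate = 0.25,
                        distractor_range = c(1L, 3L),
                        channel_probs = c(text = 0.7, icd = 0.2, lab = 0.1),
                        case_age = list(mean = 45.2, sd = 10.5),
                        control_age = list(mean = 55.5, sd = 13.3),
                        age_bounds = c(18, 75),
                        case_female = 0.385, control_female = 0.505) {
  stopifnot(n_cases >= 0L, n_controls >= 0L,
            all(c(negation_rate, typo_rate, paraphrase_rate, confounder_rate) >= 0),
            all(c(negation_rate, typo_rate, paraphrase_rate, confounder_rate) <= 1))
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 seed = as.integer(seed),
                 case_feature_probs = case_feature_probs,
                 control_feature_probs = control_feature_probs,
                 negation_rate = negation_rate, typo_rate = typo_rate,
                 paraphrase_rate = paraphrase_rate,
                 confounder_rate = confounder_rate,
                 distractor_range = as.integer(distractor_range),
                 channel_probs = channel_probs,
                 case_age = case_age, control_age = control_age,
                 age_bounds = age_bounds,
                 case_female = case_female, control_female = control_female),
            class = "fd_cohort_spec")
}

#' @rdname cohort_spec
#' @export
default_case_feature_probs <- function() {
  c(hypertrophic_cardiomyopathy = 0.45, myocardial_infarction = 0.55,
    arrhythmia = 0.35, renal_failure = 0.30, proteinuria = 0.35,
    angiokeratoma = 0.60, hypohidrosis = 0.45, stroke = 0.30,
    neuropathic_pain = 0.60, hearing_impairment = 0.30,
    gastrointestinal_symptoms = 0.35, recurrent_fever = 0.30,
    cornea_verticillata = 0.0)
}

#' @rdname cohort_spec
#' @export
default_control_feature_probs <- function() {
  c(hypertrophic_cardiomyopathy = 0.22, myocardial_infarction = 0.07,
    arrhythmia = 0.09, renal_failure = 0.03, proteinuria = 0.08,
    angiokeratoma = 0.002, hypohidrosis = 0.006, stroke = 0.02,
    neuropathic_pain = 0.02, hearing_impairment = 0.09,
    gastrointestinal_symptoms = 0.11, recurrent_fever = 0.05,
    cornea_verticillata = 0.004)
}

# neutral sentences free of lexicon tokens and of their edit-distance-1
# neighbours (checked by test)
distractor_pool <- function() {
  c("Routine follow up visit completed today.",
    "Vital parameters within normal limits.",
    "Advised to continue current medication.",
    "General condition remains satisfactory.",
    "Vaccination status reviewed and updated.",
    "Physical examination otherwise unremarkable.",
    "Counselled regarding lifestyle and nutrition.",
    "Outpatient review scheduled in three months.")
}

affirmed_templates <- function() {
  list(c("patient", "reports"), c("examination", "revealed"),
       c("documented", "finding", "of"), c("assessment", "confirmed"))
}

negated_templates <- function() {
  list(c("no"), c("patient", "denies"), c("no", "evidence", "of"),
       c("without"))
}

sample_range <- function(lo, hi) if (lo >= hi) lo else sample(seq(lo, hi), 1L)

# truncated normal sampler (one draw)
rtnorm1 <- function(mean, sd, lo, hi) {
  u <- stats::runif(1, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

detokenize <- function(tokens) {
  s <- paste(tokens, collapse = " ")
  s <- gsub(" ([.,;:!?])", "\\1", s)
  paste0(toupper(substr(s, 1, 1)), substr(s, 2, nchar(s)))
}

# pick a recoverable single-character typo for a token: the result must be
# out of vocabulary and have the original as its unique distance-1
# vocabulary neighbour
make_typo <- function(token, vocabulary) {
  letters_pool <- letters
  for (attempt in 1:8) {
    pos <- sample.int(nchar(token), 1L)
    mode <- sample.int(3L, 1L)
    cand <- if (mode == 1L) {            # substitution
      repl <- sample(setdiff(letters_pool, substr(token, pos, pos)), 1L)
      paste0(substr(token, 1, pos - 1L), repl, substr(token, pos + 1L, nchar(token)))
    } else if (mode == 2L) {             # deletion
      paste0(substr(token, 1, pos - 1L), substr(token, pos + 1L, nchar(token)))
    } else {                             # insertion
      paste0(substr(token, 1, pos), sample(letters_pool, 1L),
             substr(token, pos + 1L, nchar(token)))
    }
    if (cand %in% vocabulary) next
    d <- utils::adist(cand, vocabulary)
    nn <- which(d == 1L)
    if (length(nn) >= 1L && vocabulary[nn[1L]] == token) return(cand)
  }
  token
}

#' Plant noise into a sentence while keeping gold annotations consistent
#'
#' Applies recoverable single-character typos to eligible non-cue tokens
#' and, per mention, optionally prepends a negation cue directly before the
#' mention (flipping its gold polarity and shifting downstream spans).
#' Draws come from the current RNG stream.
#'
#' @param tokens Character vector of sentence tokens.
#' @param mentions Data frame with `start`, `end` (0-based half-open token
#'   spans into `tokens`) and `polarity`.
#' @param typo_rate,negation_rate Noise probabilities.
#' @param lexicon The lexicon (vocabulary and cues constrain the edits).
#' @return List with `tokens` and updated `mentions`.
#' @export
plant_noise <- function(tokens, mentions, typo_rate = 0, negation_rate = 0,
                        lexicon = default_lexicon()) {
  stopifnot(all(mentions$start >= 0), all(mentions$end <= length(tokens)))
  vocab <- lexicon$typo_vocabulary
  cues <- lexicon$negation_cues
  if (typo_rate > 0) {
    for (i in seq_along(tokens)) {
      tok <- tokens[i]
      if (nchar(tok) >= 5L && grepl("^[[:alpha:]]+$", tok) &&
          !(tolower(tok) %in% cues) && tolower(tok) %in% vocab &&
          stats::runif(1) < typo_rate) {
        tokens[i] <- make_typo(tolower(tok), vocab)
      }
    }
  }
  if (negation_rate > 0 && NROW(mentions) > 0L) {
    for (m in order(mentions$start, decreasing = TRUE)) {
      if (mentions$polarity[m] == "affirmed" && stats::runif(1) < negation_rate) {
        at <- mentions$start[m]
        tokens <- append(tokens, "no", after = at)
        shift <- mentions$start >= at
        mentions$start[shift] <- mentions$start[shift] + 1L
        mentions$end[mentions$end > at] <- mentions$end[mentions$end > at] + 1L
        mentions$polarity[m] <- "negated"
      }
    }
  }
  list(tokens = tokens, mentions = mentions)
}

# build one mention sentence; returns tokens + 0-based half-open span
mention_sentence <- function(surface, template) {
  term_toks <- strsplit(surface, " ")[[1]]
  toks <- c(template, term_toks, ".")
  list(tokens = toks,
       start = length(template), end = length(template) + length(term_toks))
}

term_surface <- function(entry, paraphrase_rate) {
  syn <- entry$synonyms
  if (length(syn) > 0L && stats::runif(1) < paraphrase_rate) {
    sample(syn, 1L)
  } else {
    entry$canonical
  }
}

#' Generate a synthetic screening cohort with gold annotations
#'
#' Draws demographics, per-feature presence, evidence channels (text,
#' ICD-10 code or laboratory value), confounder vetoes, denial sentences
#' and distractor text for each patient, and records the exact ground truth
#' (mention spans/polarities, intended feature set after vetoes, intended
#' risk factor). A single RNG stream seeded from `spec$seed` determines the
#' output byte-for-byte; patients are drawn cases first, then controls, in
#' a fixed per-patient order (age, sex, features, channels, confounders,
#' denial, distractors, sentence arrangement).
#'
#' @param spec An `fd_cohort_spec`.
#' @param catalog An `fd_catalog`.
#' @param lexicon An `fd_lexicon`; every catalog feature must have at least
#'   one lexicon evidence term.
#' @return List with `records` (patient record lists) and `gold`
#'   (per-patient lists: `patient_id`, `mentions` data frame, `true_features`,
#'   `intended_risk_factor`, `true_label`).
#' @export
generate_cohort <- function(spec = cohort_spec(), catalog = default_catalog(),
                            lexicon = default_lexicon()) {
  term_by_feature <- feature_term_index(catalog, lexicon)
  set.seed(spec$seed)
  n <- spec$n_cases + spec$n_controls
  records <- vector("list", n)
  gold <- vector("list", n)
  for (i in seq_len(n)) {
    is_case <- i <= spec$n_cases
    pid <- if (is_case) sprintf("case_%04d", i) else sprintf("ctrl_%05d", i - spec$n_cases)
    ag <- if (is_case) spec$case_age else spec$control_age
    age <- round(rtnorm1(ag$mean, ag$sd, spec$age_bounds[1], spec$age_bounds[2]), 1)
    sex <- if (stats::runif(1) < (if (is_case) spec$case_female else spec$control_female)) "female" else "male"
    probs <- if (is_case) spec$case_feature_probs else spec$control_feature_probs
    present <- catalog$order[stats::runif(length(catalog$order)) < probs[catalog$order]]
    out <- realize_patient(pid, age, sex, present, spec, catalog, lexicon,
                           term_by_feature,
                           label = if (is_case) "FD-positive" else "control")
    records[[i]] <- out$record
    gold[[i]] <- out$gold
  }
  list(records = records, gold = gold)
}

feature_term_index <- function(catalog, lexicon) {
  idx <- list()
  for (fid in catalog$order) {
    terms <- intersect(catalog$features[[fid]]$evidence_terms, names(lexicon$entries))
    if (length(terms) == 0L) {
      stop("generate_cohort(): feature '", fid, "' has no lexicon evidence term")
    }
    idx[[fid]] <- terms
  }
  idx
}

realize_patient <- function(pid, age, sex, present, spec, catalog, lexicon,
                            term_by_feature, label) {
  sentences <- list()   # each: list(tokens, mentions df or NULL)
  icd_codes <- character()
  labs <- list()
  vetoed <- character()
  aff_templates <- affirmed_templates()
  for (fid in present) {
    f <- catalog$features[[fid]]
    ch <- sample(c("text", "icd", "lab"), 1L, prob = spec$channel_probs)
    if (ch == "icd" && length(f$icd10_prefixes) == 0L) ch <- "text"
    if (ch == "lab" && length(f$lab_findings) == 0L) ch <- "text"
    if (ch == "text") {
      term_id <- sample(term_by_feature[[fid]], 1L)
      entry <- lexicon$entries[[term_id]]
      surf <- term_surface(entry, spec$paraphrase_rate)
      tmpl <- aff_templates[[sample.int(length(aff_templates), 1L)]]
      ms <- mention_sentence(surf, tmpl)
      mentions <- data.frame(term_id = term_id, start = ms$start, end = ms$end,
                             polarity = "affirmed", stringsAsFactors = FALSE)
      noised <- plant_noise(ms$tokens, mentions, typo_rate = spec$typo_rate,
                            negation_rate = 0, lexicon = lexicon)
      sentences[[length(sentences) + 1L]] <- list(tokens = noised$tokens,
                                                  mentions = noised$mentions)
    } else if (ch == "icd") {
      icd_codes <- c(icd_codes, sample(f$icd10_prefixes, 1L))
    } else {
      labs <- c(labs, list(synth_lab(f$lab_findings[1L], catalog)))
    }
    # confounder veto for features carrying exclusion rules
    if (length(f$exclusion_conditions) > 0L && stats::runif(1) < spec$confounder_rate) {
      cid <- sample(f$exclusion_conditions, 1L)
      cond <- catalog$conditions[[cid]]
      cterms <- intersect(as.character(unlist(cond$terms %||% character())),
                          names(lexicon$entries))
      if (length(cterms) > 0L) {
        centry <- lexicon$entries[[sample(cterms, 1L)]]
        ms <- mention_sentence(centry$canonical, c("known", "history", "of"))
        sentences[[length(sentences) + 1L]] <-
          list(tokens = ms$tokens,
               mentions = data.frame(term_id = centry$term_id, start = ms$start,
                                     end = ms$end, polarity = "affirmed",
                                     stringsAsFactors = FALSE))
        vetoed <- c(vetoed, fid)
      } else if (length(cond$icd10_prefixes %||% character()) > 0L) {
        icd_codes <- c(icd_codes, sample(as.character(unlist(cond$icd10_prefixes)), 1L))
        vetoed <- c(vetoed, fid)
      }
    }
  }
  # denial sentence for one absent feature
  absent <- setdiff(catalog$order, present)
  if (length(absent) > 0L && stats::runif(1) < spec$negation_rate) {
    fid <- sample(absent, 1L)
    term_id <- sample(term_by_feature[[fid]], 1L)
    entry <- lexicon$entries[[term_id]]
    neg_templates <- negated_templates()
    tmpl <- neg_templates[[sample.int(length(neg_templates), 1L)]]
    ms <- mention_sentence(entry$canonical, tmpl)
    sentences[[length(sentences) + 1L]] <-
      list(tokens = ms$tokens,
           mentions = data.frame(term_id = term_id, start = ms$start, end = ms$end,
                                 polarity = "negated", stringsAsFactors = FALSE))
  }
  nd <- sample_range(spec$distractor_range[1], spec$distractor_range[2])
  pool <- distractor_pool()
  for (k in seq_len(nd)) {
    sentences[[length(sentences) + 1L]] <-
      list(tokens = tokenize(sample(pool, 1L)), mentions = NULL)
  }
  ord <- sample.int(length(sentences))
  sentences <- sentences[ord]
  texts <- vapply(sentences, function(s) detokenize(s$tokens), "")
  mention_rows <- list()
  for (si in seq_along(sentences)) {
    m <- sentences[[si]]$mentions
    if (!is.null(m) && nrow(m) > 0L) {
      m$note_index <- 0L
      m$sentence_index <- si - 1L
      mention_rows[[length(mention_rows) + 1L]] <- m
    }
  }
  mentions <- if (length(mention_rows) > 0L) {
    do.call(rbind, mention_rows)[, c("term_id", "note_index", "sentence_index",
                                     "start", "end", "polarity")]
  } else {
    data.frame(term_id = character(), note_index = integer(),
               sentence_index = integer(), start = integer(), end = integer(),
               polarity = character(), stringsAsFactors = FALSE)
  }
  rownames(mentions) <- NULL
  true_features <- setdiff(present, vetoed)
  irf <- sum(vapply(true_features, function(fid)
    score_feature(catalog$features[[fid]], TRUE, age), 0L))
  record <- list(patient_id = pid, age = age, sex = sex,
                 notes = paste(texts, collapse = " "),
                 icd10_codes = as.list(icd_codes), labs = labs,
                 true_label = label)
  goldrec <- list(patient_id = pid, mentions = mentions,
                  true_features = true_features,
                  intended_risk_factor = as.integer(irf), true_label = label)
  list(record = record, gold = goldrec)
}

synth_lab <- function(finding, catalog) {
  rule <- NULL
  for (r in catalog$lab_rules) if (r$finding == finding) { rule <- r; break }
  if (is.null(rule)) stop("synth_lab(): no lab rule produces finding ", finding)
  value <- switch(rule$op,
                  "<" = stats::runif(1, max(0, rule$threshold * 0.3), rule$threshold * 0.9),
                  "<=" = stats::runif(1, max(0, rule$threshold * 0.3), rule$threshold),
                  ">" = stats::runif(1, rule$threshold * 1.5, rule$threshold * 6),
                  ">=" = stats::runif(1, rule$threshold, rule$threshold * 6))
  list(analyte = rule$analyte, value = round(value, 1), unit = rule$unit,
       flag = "abnormal")
}

#' Generate an annotated audit corpus for precision testing
#'
#' For each requested term, builds `n_per_term` short descriptions, each
#' containing exactly one gold mention of the term (negated with
#' probability `negation_rate`, typo'd with probability `typo_rate`) plus
#' distractor sentences. With probability `near_miss_rate` a description
#' also carries a near-miss distractor: a single-character morphological
#' neighbour of a different single-token term, which the typo corrector
#' normalizes into that term and which therefore counts against that term's
#' precision (it has no gold mention).
#'
#' @param term_ids Terms to audit (default: all lexicon terms).
#' @param n_per_term Descriptions per term.
#' @param lexicon An `fd_lexicon`.
#' @param typo_rate,negation_rate,near_miss_rate Noise probabilities.
#' @param distractor_range Distractor sentences per description.
#' @param seed Integer seed.
#' @return List of annotated descriptions (`text` + `mentions` data frame),
#'   ready for [precision_audit()].
#' @export
generate_audit_corpus <- function(term_ids = NULL, n_per_term = 100L,
                                  lexicon = default_lexicon(),
                                  typo_rate = 0.15, negation_rate = 0.15,
                                  near_miss_rate = 0.06,
                                  distractor_range = c(1L, 2L),
                                  seed = 20230522L) {
  stopifnot(n_per_term >= 1L)
  if (is.null(term_ids)) term_ids <- lexicon$order
  set.seed(seed)
  single_token_terms <- lexicon$order[vapply(lexicon$order, function(id) {
    !grepl(" ", lexicon$entries[[id]]$canonical)
  }, TRUE)]
  pool <- distractor_pool()
  aff_templates <- affirmed_templates()
  corpus <- vector("list", length(term_ids) * n_per_term)
  k <- 0L
  for (tid in term_ids) {
    entry <- lexicon$entries[[tid]]
    if (is.null(entry)) stop("generate_audit_corpus(): unknown term ", tid)
    for (j in seq_len(n_per_term)) {
      tmpl <- aff_templates[[sample.int(length(aff_templates), 1L)]]
      ms <- mention_sentence(entry$canonical, tmpl)
      mentions <- data.frame(term_id = tid, start = ms$start, end = ms$end,
                             polarity = "affirmed", stringsAsFactors = FALSE)
      noised <- plant_noise(ms$tokens, mentions, typo_rate = typo_rate,
                            negation_rate = negation_rate, lexicon = lexicon)
      sents <- list(list(tokens = noised$tokens, mentions = noised$mentions))
      others <- setdiff(single_token_terms, tid)
      if (length(others) > 0L && stats::runif(1) < near_miss_rate) {
        other <- lexicon$entries[[sample(others, 1L)]]
        nm <- make_typo(other$canonical, lexicon$typo_vocabulary)
        sents[[length(sents) + 1L]] <-
          list(tokens = c("prior", "notes", "mention", nm, "."), mentions = NULL)
      }
      nd <- sample_range(distractor_range[1], distractor_range[2])
      for (d in seq_len(nd)) {
        sents[[length(sents) + 1L]] <- list(tokens = tokenize(sample(pool, 1L)),
                                            mentions = NULL)
      }
      ord <- sample.int(length(sents))
      sents <- sents[ord]
      mrows <- list()
      for (si in seq_along(sents)) {
        m <- sents[[si]]$mentions
        if (!is.null(m)) {
          m$sentence_index <- si - 1L
          mrows[[length(mrows) + 1L]] <- m
        }
      }
      k <- k + 1L
      corpus[[k]] <- list(
        text = paste(vapply(sents, function(s) detokenize(s$tokens), ""),
                     collapse = " "),
        mentions = do.call(rbind, mrows))
    }
  }
  corpus
}
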