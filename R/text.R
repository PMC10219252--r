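#' Split a note into sentences
#'
#' Rule-based splitter: a sentence ends at `.`, `!` or `?` followed by
#' whitespace. Terminal punctuation stays with its sentence, so the
#' concatenation of the returned sentences preserves all non-whitespace
#' content in order. Text without a terminal delimiter comes back as a
#' single sentence, verbatim.
#'
#' @param text Character scalar (a raw note).
#' @return Character vector of sentences (empty for empty input).
#' @export
split_sentences <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) || !nzchar(trimws(text))) {
    return(character(0))
  }
  parts <- strsplit(text, "(?<=[.!?])\\s+", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

# whitespace tokenizer with punctuation separated into its own tokens;
# intra-word hyphens and apostrophes are kept
tokenize <- function(sentence) {
  x <- gsub("([[:punct:]])", " \\1 ", sentence)
  x <- gsub("(\\w) ([-']) (\\w)", "\\1\\2\\3", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Normalize a sentence into matcher-ready tokens
#'
#' Tokenizes, lower-cases, corrects single-edit typos against the lexicon
#' vocabulary, and lemmatizes with the lexicon's ordered suffix rules.
#' Typo correction rewrites a token only when it is (a) not already in the
#' vocabulary, (b) at least 4 characters long, (c) not a negation cue or
#' adversative token, and (d) at Levenshtein distance 1 from a vocabulary
#' entry (first such entry in vocabulary order wins). The guards keep
#' short function words and the negation cues themselves from being
#' rewritten into look-alike medical terms.
#'
#' @param sentence Character scalar.
#' @param lexicon An `fd_lexicon`.
#' @param typo_correction Logical; disable to skip the edit-distance pass.
#' @return Character vector of normalized tokens.
#' @export
normalize_tokens <- function(sentence, lexicon, typo_correction = TRUE) {
  toks <- tolower(tokenize(sentence))
  if (length(toks) == 0L) return(character(0))
  if (typo_correction && length(lexicon$typo_vocabulary) > 0L) {
    protected <- c(lexicon$negation_cues, lexicon$adversative_tokens)
    candidate <- !(toks %in% lexicon$typo_vocabulary) & nchar(toks) >= 4L &
      !(toks %in% protected) & grepl("^[[:alpha:]-]+$", toks)
    if (any(candidate)) {
      uniq <- unique(toks[candidate])
      d <- utils::adist(uniq, lexicon$typo_vocabulary)
      repl <- vapply(seq_along(uniq), function(i) {
        j <- which(d[i, ] == 1L)
        if (length(j) > 0L) lexicon$typo_vocabulary[j[1L]] else uniq[i]
      }, "")
      names(repl) <- uniq
      toks[candidate] <- repl[toks[candidate]]
    }
  }
  vapply(toks, apply_lemma_rules, "", rules = lexicon$lemma_rules, USE.NAMES = FALSE)
}

#' Find lexicon pattern matches in a token sequence
#'
#' Scans the normalized token sequence for every compiled pattern of every
#' lexicon entry and resolves overlaps longest-match-first, ties by leftmost
#' start, then by lexicon order. Spans are 0-based, half-open.
#'
#' @param tokens Character vector of normalized tokens.
#' @param lexicon An `fd_lexicon`.
#' @return Data frame with columns `term_id`, `start`, `end` (0-based,
#'   half-open), ordered by `start`.
#' @export
match_patterns <- function(tokens, lexicon) {
  empty <- data.frame(term_id = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  n <- length(tokens)
  if (n == 0L || length(lexicon$entries) == 0L) return(empty)
  cand_term <- character(); cand_start <- integer(); cand_len <- integer(); cand_ord <- integer()
  for (ei in seq_along(lexicon$order)) {
    e <- lexicon$entries[[lexicon$order[ei]]]
    for (pat in e$patterns) {
      m <- length(pat)
      if (m > n) next
      if (isTRUE(attr(pat, "literal"))) {
        ptoks <- attr(pat, "tokens")
        starts <- which(tokens == ptoks[1L])
        starts <- starts[starts + m - 1L <= n]
        if (m > 1L) {
          ok <- vapply(starts, function(s) all(tokens[s:(s + m - 1L)] == ptoks), TRUE)
          starts <- starts[ok]
        }
      } else {
        starts <- integer(0)
        for (s in seq_len(n - m + 1L)) {
          hit <- TRUE
          for (k in seq_len(m)) {
            if (!grepl(pat[k], tokens[s + k - 1L], perl = TRUE)) { hit <- FALSE; break }
          }
          if (hit) starts <- c(starts, s)
        }
      }
      if (length(starts) > 0L) {
        cand_term <- c(cand_term, rep(e$term_id, length(starts)))
        cand_start <- c(cand_start, starts)
        cand_len <- c(cand_len, rep(m, length(starts)))
        cand_ord <- c(cand_ord, rep(ei, length(starts)))
      }
    }
  }
  if (length(cand_term) == 0L) return(empty)
  o <- order(-cand_len, cand_start, cand_ord)
  covered <- logical(n)
  keep <- logical(length(o))
  for (i in o) {
    idx <- cand_start[i]:(cand_start[i] + cand_len[i] - 1L)
    if (!any(covered[idx])) {
      covered[idx] <- TRUE
      keep[i] <- TRUE
    }
  }
  res <- data.frame(term_id = cand_term[keep],
                    start = cand_start[keep] - 1L,
                    end = cand_start[keep] + cand_len[keep] - 1L,
                    stringsAsFactors = FALSE)
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Decide whether a mention is negated
#'
#' A mention is negated when a negation cue occurs within `window` tokens
#' before the span start, inside the same sentence, with no adversative
#' token (e.g. "but") between the cue and the mention. Otherwise affirmed.
#'
#' @param tokens Tokens of one sentence.
#' @param span Integer vector `c(start, end)`, 0-based half-open.
#' @param cues Negation cue tokens; defaults taken from `lexicon`.
#' @param window Look-back distance in tokens.
#' @param adversative Polarity-resetting tokens.
#' @return `"negated"` or `"affirmed"`.
#' @export
detect_negation <- function(tokens, span, cues, window = 5L,
                            adversative = c("but", "however", "although", "though", "yet")) {
  start <- span[1L]; end <- span[2L]
  if (start < 0L || end > length(tokens) || start >= end) {
    stop("detect_negation(): span out of bounds")
  }
  if (start == 0L) return("affirmed")
  lo <- max(0L, start - window)
  for (i in seq(start - 1L, lo)) {         # walk backwards from the mention
    tok <- tokens[i + 1L]
    if (tok %in% adversative) return("affirmed")
    if (tok %in% cues) return("negated")
  }
  "affirmed"
}

#' Link an out-of-dictionary phrase to its nearest lexicon term
#'
#' Normalizes the query with the lexicon's lemma rules, embeds it, and
#' returns the lexicon entry with maximal cosine similarity, provided that
#' maximum reaches `threshold`; ties go to the earlier entry in lexicon
#' order (both sides of the comparison are lemmatized, so a query equal to
#' a canonical form always links at similarity 1). Returns `NULL` when the
#' lexicon is empty or no entry reaches the threshold.
#'
#' @param phrase Normalized token or phrase.
#' @param lexicon An `fd_lexicon`.
#' @param threshold Minimum cosine similarity in (0, 1].
#' @return `NULL`, or a list with `term_id` and `similarity`.
#' @export
similarity_link <- function(phrase, lexicon, threshold = 0.85) {
  stopifnot(threshold > 0, threshold <= 1)
  if (length(lexicon$entries) == 0L) return(NULL)
  phrase <- paste(normalize_phrase_tokens(phrase, lexicon$lemma_rules),
                  collapse = " ")
  if (!nzchar(phrase)) return(NULL)
  q <- lexicon$embedder(phrase, lexicon$embed_dim)
  sims <- as.numeric(lexicon$embeddings %*% q)
  best <- which.max(sims)
  if (sims[best] >= threshold) {
    list(term_id = lexicon$order[best], similarity = sims[best])
  } else {
    NULL
  }
}

#' Default matcher settings
#'
#' @param similarity_threshold Minimum cosine similarity for a similarity
#'   link (the dictionary states no value; 0.85 is the package default).
#' @param negation_window Look-back window for negation cues, in tokens.
#' @param typo_correction Enable edit-distance-1 typo correction.
#' @param use_similarity Enable similarity linking of unmatched tokens.
#' @return A list of matcher settings.
#' @export
matcher_config <- function(similarity_threshold = 0.85, negation_window = 5L,
                           typo_correction = TRUE, use_similarity = TRUE) {
  list(similarity_threshold = similarity_threshold,
       negation_window = as.integer(negation_window),
       typo_correction = isTRUE(typo_correction),
       use_similarity = isTRUE(use_similarity))
}

#' Extract affirmed and negated term mentions from a note
#'
#' Runs the full pipeline over one free-text note: sentence splitting,
#' normalization (typo correction + lemmatization), pattern matching,
#' similarity linking of leftover tokens, and negation detection. Pattern
#' matches take precedence over similarity links on the same tokens.
#'
#' @param note Raw note text.
#' @param lexicon An `fd_lexicon`.
#' @param config Matcher settings from [matcher_config()].
#' @return Data frame with columns `term_id`, `sentence_index` (0-based),
#'   `start`, `end` (0-based half-open token span), `polarity`
#'   (`affirmed`/`negated`), `link_method` (`pattern`/`similarity`),
#'   `similarity` (1.0 for pattern links), ordered by sentence then span
#'   start.
#' @export
extract_entities <- function(note, lexicon, config = matcher_config()) {
  empty <- data.frame(term_id = character(), sentence_index = integer(),
                      start = integer(), end = integer(), polarity = character(),
                      link_method = character(), similarity = numeric(),
                      stringsAsFactors = FALSE)
  sents <- split_sentences(note)
  if (length(sents) == 0L) return(empty)
  out <- vector("list", length(sents))
  sim_cache <- new.env(parent = emptyenv())
  for (si in seq_along(sents)) {
    toks <- normalize_tokens(sents[si], lexicon, typo_correction = config$typo_correction)
    if (length(toks) == 0L) next
    hits <- match_patterns(toks, lexicon)
    if (nrow(hits) > 0L) {
      hits$link_method <- "pattern"
      hits$similarity <- 1.0
    }
    if (config$use_similarity) {
      covered <- logical(length(toks))
      if (nrow(hits) > 0L) {
        for (r in seq_len(nrow(hits))) covered[(hits$start[r] + 1L):hits$end[r]] <- TRUE
      }
      linkable <- which(!covered & nchar(toks) >= 4L &
                          grepl("^[[:alpha:]-]+$", toks) &
                          !(toks %in% lexicon$typo_vocabulary) &
                          !(toks %in% lexicon$negation_cues))
      for (i in linkable) {
        tok <- toks[i]
        link <- if (exists(tok, envir = sim_cache, inherits = FALSE)) {
          get(tok, envir = sim_cache, inherits = FALSE)
        } else {
          l <- similarity_link(tok, lexicon, config$similarity_threshold)
          assign(tok, l, envir = sim_cache)
          l
        }
        if (!is.null(link)) {
          hits <- rbind(hits, data.frame(term_id = link$term_id, start = i - 1L,
                                         end = i, link_method = "similarity",
                                         similarity = link$similarity,
                                         stringsAsFactors = FALSE))
        }
      }
    }
    if (nrow(hits) == 0L) next
    hits$polarity <- vapply(seq_len(nrow(hits)), function(r) {
      detect_negation(toks, c(hits$start[r], hits$end[r]),
                      cues = lexicon$negation_cues,
                      window = config$negation_window,
                      adversative = lexicon$adversative_tokens)
    }, "")
    hits$sentence_index <- si - 1L
    out[[si]] <- hits[order(hits$start), c("term_id", "sentence_index", "start",
                                           "end", "polarity", "link_method",
                                           "similarity")]
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract entities from every note of a patient record
#'
#' @param record A patient record (list with a `notes` character vector).
#' @param lexicon An `fd_lexicon`.
#' @param config Matcher settings.
#' @return Entity data frame as in [extract_entities()] with an extra
#'   leading `note_index` column (0-based).
#' @export
extract_record_entities <- function(record, lexicon, config = matcher_config()) {
  notes <- record$notes
  if (is.null(notes) || length(notes) == 0L) {
    e <- extract_entities("", lexicon, config)
    return(cbind(note_index = integer(0), e))
  }
  parts <- lapply(seq_along(notes), function(i) {
    e <- extract_entities(notes[[i]], lexicon, config)
    if (nrow(e) > 0L) cbind(note_index = i - 1L, e) else NULL
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (length(parts) == 0L) {
    e <- extract_entities("", lexicon, config)
    return(cbind(note_index = integer(0), e))
  }
  res <- do.call(rbind, parts)
  rownames(res) <- NULL
  res
}

#' Audit extraction precision against gold annotations
#'
#' For each term, counts affirmed detections across an annotated corpus and
#' the fraction that coincide with a gold affirmed mention (same term, same
#' sentence, same token span). Terms with no affirmed detections are
#' reported with `precision = NA` and `undefined = TRUE`.
#'
#' @param gold List of annotated descriptions; each a list with `text` and
#'   `mentions` (data frame with `term_id`, `sentence_index`, `start`,
#'   `end`, `polarity`).
#' @param lexicon An `fd_lexicon`.
#' @param config Matcher settings.
#' @return Data frame with `term_id`, `n_detections`, `n_correct`,
#'   `precision`, `undefined`, one row per lexicon term.
#' @export
precision_audit <- function(gold, lexicon, config = matcher_config()) {
  terms <- lexicon$order
  det <- stats::setNames(integer(length(terms)), terms)
  cor <- det
  for (g in gold) {
    ents <- extract_entities(g$text, lexicon, config)
    ents <- ents[ents$polarity == "affirmed", , drop = FALSE]
    if (nrow(ents) == 0L) next
    gm <- g$mentions
    gm <- if (is.null(gm) || NROW(gm) == 0L) NULL else gm[gm$polarity == "affirmed", , drop = FALSE]
    for (r in seq_len(nrow(ents))) {
      tid <- ents$term_id[r]
      if (!tid %in% terms) next
      det[tid] <- det[tid] + 1L
      ok <- !is.null(gm) && any(gm$term_id == tid &
                                  gm$sentence_index == ents$sentence_index[r] &
                                  gm$start == ents$start[r] &
                                  gm$end == ents$end[r])
      if (ok) cor[tid] <- cor[tid] + 1L
    }
  }
  data.frame(term_id = terms,
             n_detections = as.integer(det),
             n_correct = as.integer(cor),
             precision = ifelse(det > 0L, cor / pmax(det, 1L), NA_real_),
             undefined = det == 0L,
             stringsAsFactors = FALSE, row.names = NULL)
}
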