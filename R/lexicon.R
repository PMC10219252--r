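#' Compile token-level match patterns for a medical term
#'
#' Builds one anchored token-sequence pattern for the canonical surface form
#' and one for each synonym. A pattern is a character vector of per-token
#' regular expressions, each anchored (`^...$`) so a token must match in
#' full — substrings inside longer words never match. Surface forms are
#' normalized (lower-cased, lemma rules applied) before compilation so that
#' patterns line up with the normalized token stream they are searched in.
#'
#' @param canonical Character scalar, the canonical surface form.
#' @param synonyms Character vector of alternate surface forms (may be empty).
#' @param lemma_rules Lemmatization rule table (see [build_lexicon()]) applied
#'   during normalization; `NULL` for none.
#' @return List of patterns; each pattern is a character vector of anchored
#'   per-token regexes with attribute `literal = TRUE` when every token is a
#'   plain literal.
#' @examples
#' compile_term_patterns("cornea verticillata")
#' @export
compile_term_patterns <- function(canonical, synonyms = character(), lemma_rules = NULL) {
  if (!is.character(canonical) || length(canonical) != 1L || is.na(canonical) ||
      !nzchar(trimws(canonical))) {
    stop("compile_term_patterns(): canonical form is empty")
  }
  forms <- unique(c(canonical, synonyms))
  forms <- forms[nzchar(trimws(forms))]
  lapply(forms, function(f) {
    toks <- normalize_phrase_tokens(f, lemma_rules)
    if (length(toks) == 0L) stop("compile_term_patterns(): form '", f, "' has no tokens")
    pat <- paste0("^", escape_regex(toks), "$")
    attr(pat, "literal") <- TRUE
    attr(pat, "tokens") <- toks
    pat
  })
}

escape_regex <- function(x) gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", x, perl = TRUE)

# lower-case, tokenize and lemmatize a phrase (no typo correction: lexicon
# surface forms are trusted)
normalize_phrase_tokens <- function(phrase, lemma_rules = NULL) {
  toks <- tokenize(tolower(phrase))
  toks <- toks[!grepl("^[[:punct:]]+$", toks)]
  if (!is.null(lemma_rules)) toks <- vapply(toks, apply_lemma_rules, "", rules = lemma_rules)
  unname(toks)
}

#' Build a lexicon from term definitions
#'
#' Assembles the dictionary driving entity extraction: compiled token
#' patterns, unit-norm term embeddings, the typo-correction vocabulary, the
#' negation cue list, and the lemmatization rule table.
#'
#' @param entries List of term definitions; each a list with `term_id`,
#'   `canonical`, optional `synonyms` (character vector), optional `patterns`
#'   (extra user-supplied token-regex vectors), and `feature_id` (the clinical
#'   feature or confounder condition the term is evidence for).
#' @param negation_cues Character vector of cue tokens marking denial.
#' @param adversative_tokens Tokens (e.g. "but") that reset negation scope.
#' @param lemma_rules Data frame or list of lists with columns/fields
#'   `suffix`, `replace`, and optional `min_length`; rules are tried in order
#'   and the first whose suffix matches (on a token at least `min_length`
#'   characters long) is applied.
#' @param typo_vocabulary Optional character vector of known-correct tokens;
#'   defaults to every token of every canonical form and synonym.
#' @param extra_vocabulary Tokens appended to the auto-derived vocabulary
#'   (common note words that must never be "corrected" into a term).
#' @param embed_dim Embedding dimension passed to [fd_embed()].
#' @param embedder Function `(phrase, dim) -> unit vector`; defaults to the
#'   hashed-trigram embedder so no model download is needed. A pretrained
#'   word-vector lookup can be plugged in here.
#' @return An object of class `fd_lexicon`.
#' @export
build_lexicon <- function(entries,
                          negation_cues = c("no", "not", "without", "denies", "denied", "never"),
                          adversative_tokens = c("but", "however", "although", "though", "yet"),
                          lemma_rules = default_lemma_rules(),
                          typo_vocabulary = NULL,
                          extra_vocabulary = character(),
                          embed_dim = 256L,
                          embedder = fd_embed) {
  lemma_rules <- as_lemma_rules(lemma_rules)
  cues <- tolower(negation_cues)
  cues <- unique(c(cues, vapply(cues, apply_lemma_rules, "", rules = lemma_rules,
                                USE.NAMES = FALSE)))
  lex <- structure(
    list(entries = list(), order = character(), canonical_index = character(),
         negation_cues = cues,
         adversative_tokens = tolower(adversative_tokens),
         lemma_rules = lemma_rules,
         typo_vocabulary = character(),
         auto_vocab = is.null(typo_vocabulary),
         embed_dim = as.integer(embed_dim),
         embedder = embedder,
         embeddings = matrix(numeric(0), nrow = 0, ncol = embed_dim)),
    class = "fd_lexicon")
  for (e in entries) lex <- add_to_lexicon(lex, e)
  if (!is.null(typo_vocabulary)) {
    lex$typo_vocabulary <- unique(tolower(typo_vocabulary))
  } else if (length(extra_vocabulary) > 0L) {
    lex$typo_vocabulary <- unique(c(lex$typo_vocabulary, tolower(extra_vocabulary)))
  }
  lex
}

as_lemma_rules <- function(rules) {
  if (is.null(rules)) return(data.frame(suffix = character(), replace = character(),
                                        min_length = integer()))
  if (is.data.frame(rules)) {
    if (is.null(rules$min_length)) rules$min_length <- nchar(rules$suffix) + 1L
    return(rules)
  }
  data.frame(
    suffix = vapply(rules, function(r) as.character(r$suffix), ""),
    replace = vapply(rules, function(r) if (is.null(r$replace)) "" else as.character(r$replace), ""),
    min_length = vapply(rules, function(r) {
      if (is.null(r$min_length)) nchar(r$suffix) + 1L else as.integer(r$min_length)
    }, 0L),
    stringsAsFactors = FALSE)
}

#' Default lemmatization rules
#'
#' A small ordered suffix-rewrite table for English clinical text: plural
#' "-omas" to "-oma", "-ies" to "-y", "-ses" to "-sis", an identity rule
#' keeping singular "-is" words (hypohidrosis, urolithiasis) intact, and a
#' generic final "-s" strip on longer tokens (never applied to "-ss"
#' endings). First matching rule wins.
#'
#' @return Data frame with columns `suffix`, `replace`, `min_length`.
#' @export
default_lemma_rules <- function() {
  data.frame(
    suffix = c("omas", "ies", "ses", "is", "s"),
    replace = c("oma", "y", "sis", "is", ""),
    min_length = c(5L, 5L, 6L, 4L, 5L),
    stringsAsFactors = FALSE)
}

apply_lemma_rules <- function(token, rules) {
  if (nrow(rules) == 0L || grepl("^[[:punct:]]+$", token)) return(token)
  for (i in seq_len(nrow(rules))) {
    suf <- rules$suffix[i]
    if (nchar(token) >= rules$min_length[i] && endsWith(token, suf)) {
      if (suf == "s" && endsWith(token, "ss")) next
      return(paste0(substr(token, 1L, nchar(token) - nchar(suf)), rules$replace[i]))
    }
  }
  token
}

#' Add an entry to a lexicon
#'
#' Compiles the entry's patterns, embeds its canonical form, extends the
#' typo vocabulary (when auto-derived) and indexes the entry by term id and
#' canonical form. Adding a second entry with the same canonical form is a
#' conflict.
#'
#' @param lexicon An `fd_lexicon`.
#' @param entry List with `term_id`, `canonical`, optional `synonyms`,
#'   optional `patterns`, `feature_id`.
#' @return The updated lexicon.
#' @export
add_to_lexicon <- function(lexicon, entry) {
  stopifnot(inherits(lexicon, "fd_lexicon"))
  if (is.null(entry$term_id) || !nzchar(entry$term_id)) stop("add_to_lexicon(): entry needs a term_id")
  canonical <- paste(normalize_phrase_tokens(entry$canonical, lexicon$lemma_rules), collapse = " ")
  if (!nzchar(canonical)) stop("add_to_lexicon(): canonical form is empty")
  if (entry$term_id %in% names(lexicon$entries)) {
    stop("add_to_lexicon(): duplicate term_id '", entry$term_id, "'")
  }
  if (canonical %in% names(lexicon$canonical_index)) {
    stop("add_to_lexicon(): canonical form '", canonical, "' already in lexicon")
  }
  synonyms <- if (is.null(entry$synonyms)) character() else unlist(entry$synonyms)
  patterns <- compile_term_patterns(entry$canonical, synonyms, lexicon$lemma_rules)
  if (!is.null(entry$patterns)) {
    extra <- lapply(entry$patterns, function(p) {
      p <- unlist(p)
      attr(p, "literal") <- FALSE
      p
    })
    patterns <- c(patterns, extra)
  }
  e <- list(term_id = entry$term_id, canonical = canonical,
            synonyms = vapply(synonyms, function(s) paste(normalize_phrase_tokens(s, lexicon$lemma_rules), collapse = " "), ""),
            patterns = patterns,
            feature_id = if (is.null(entry$feature_id)) NA_character_ else entry$feature_id,
            embedding = lexicon$embedder(canonical, lexicon$embed_dim))
  lexicon$entries[[e$term_id]] <- e
  lexicon$order <- c(lexicon$order, e$term_id)
  ci <- lexicon$canonical_index
  ci[canonical] <- e$term_id
  lexicon$canonical_index <- ci
  lexicon$embeddings <- rbind(lexicon$embeddings, e$embedding)
  rownames(lexicon$embeddings) <- lexicon$order
  if (isTRUE(lexicon$auto_vocab)) {
    toks <- unlist(lapply(e$patterns, function(p) attr(p, "tokens")))
    lexicon$typo_vocabulary <- unique(c(lexicon$typo_vocabulary, toks[!is.null(toks)]))
  }
  lexicon
}

#' @export
print.fd_lexicon <- function(x, ...) {
  cat("fd_lexicon:", length(x$entries), "entries,",
      length(x$negation_cues), "negation cues,",
      nrow(x$lemma_rules), "lemma rules\n")
  invisible(x)
}

#' Look up a lexicon entry by canonical form
#' @param lexicon An `fd_lexicon`.
#' @param canonical Canonical surface form (normalized internally).
#' @return The entry, or `NULL` if absent.
#' @export
lexicon_lookup <- function(lexicon, canonical) {
  key <- paste(normalize_phrase_tokens(canonical, lexicon$lemma_rules), collapse = " ")
  id <- lexicon$canonical_index[key]
  if (is.na(id)) NULL else lexicon$entries[[id]]
}

#' Read a lexicon from a YAML or JSON file
#'
#' The file mirrors the arguments of [build_lexicon()]: an `entries` list
#' plus `negation_cues`, `adversative_tokens`, `lemma_rules` and optional
#' `typo_vocabulary`.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or `.json`).
#' @return An `fd_lexicon`.
#' @export
read_lexicon <- function(path) {
  spec <- read_config_file(path)
  if (is.null(spec$entries)) stop("read_lexicon(): no 'entries' in ", path)
  build_lexicon(
    entries = spec$entries,
    negation_cues = spec$negation_cues %||% c("no", "not", "without", "denies", "denied", "never"),
    adversative_tokens = spec$adversative_tokens %||% c("but", "however", "although", "though", "yet"),
    lemma_rules = spec$lemma_rules %||% default_lemma_rules(),
    typo_vocabulary = spec$typo_vocabulary,
    extra_vocabulary = as.character(unlist(spec$extra_vocabulary %||% character())),
    embed_dim = spec$embed_dim %||% 256L)
}

#' The packaged default English lexicon
#'
#' Covers all 13 clinical features of the default catalog plus the
#' confounder conditions used by the exclusion rules. The terms are English;
#' the pipeline itself is language-agnostic and any lexicon file can be
#' substituted.
#'
#' @return An `fd_lexicon`.
#' @export
default_lexicon <- function() {
  read_lexicon(system.file("extdata", "lexicon.yaml", package = "fabryscreen",
                           mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_config_file <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext %in% c("json", "jsonl")) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    stop("unsupported config format: ", path)
  }
}
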