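test_that("sentence splitting preserves content and order", {
  expect_identical(split_sentences(""), character(0))
  expect_identical(split_sentences("No edema. Angiokeratoma present."),
                   c("No edema.", "Angiokeratoma present."))
  expect_identical(split_sentences("single sentence without terminal punctuation"),
                   "single sentence without terminal punctuation")
  cases <- c("One. Two! Three?", "Trailing tail", "A. B. C.")
  for (x in cases) {
    sents <- split_sentences(x)
    expect_identical(gsub("\\s", "", paste(sents, collapse = "")),
                     gsub("\\s", "", x))
  }
})

test_that("token normalization folds case and separates punctuation", {
  lex <- tiny_lexicon()
  expect_identical(normalize_tokens("Angiokeratoma.", lex),
                   c("angiokeratoma", "."))
  expect_identical(normalize_tokens("", lex), character(0))
})

test_that("pattern matching resolves overlaps longest-first", {
  lex <- tiny_lexicon()
  m <- match_patterns(c("no", "angiokeratoma"), lex)
  expect_equal(nrow(m), 1)
  expect_identical(m$term_id, "angiokeratoma")
  expect_equal(c(m$start, m$end), c(1L, 2L))

  expect_equal(nrow(match_patterns(character(0), lex)), 0)

  # "cornea" alone and "cornea verticillata" overlap: only the longer match
  m2 <- match_patterns(c("cornea", "verticillata"), lex)
  expect_identical(m2$term_id, "cornea_verticillata")
  m3 <- match_patterns(c("cornea", "stroke"), lex)
  expect_identical(sort(m3$term_id), c("cornea", "stroke"))
})

test_that("pattern matching equals the naive scan oracle on random sequences", {
  lex <- tiny_lexicon()
  vocab <- c("angiokeratoma", "proteinuria", "protein", "in", "urine",
             "cornea", "verticillata", "stroke", "filler", "word", "the")
  set.seed(42)
  for (rep in 1:60) {
    toks <- sample(vocab, sample(0:50, 1), replace = TRUE)
    expect_identical(match_patterns(toks, lex), naive_match_oracle(toks, lex))
  }
})

test_that("negation is cue-within-window, sentence-bounded, adversative-reset", {
  cues <- c("no", "not", "without", "denies")
  expect_identical(detect_negation(c("no", "angiokeratoma"), c(1L, 2L), cues, 5L),
                   "negated")
  expect_identical(detect_negation(c("angiokeratoma", "present"), c(0L, 1L), cues, 5L),
                   "affirmed")
  # cue exactly at the window edge is seen; one beyond is not
  toksw <- c("no", "a", "b", "term")
  expect_identical(detect_negation(toksw, c(3L, 4L), cues, 3L), "negated")
  expect_identical(detect_negation(toksw, c(3L, 4L), cues, 2L), "affirmed")
  # adversative conjunction between cue and mention resets polarity
  expect_identical(detect_negation(c("no", "edema", "but", "stroke"), c(3L, 4L),
                                   cues, 5L), "affirmed")
  expect_error(detect_negation(c("a", "b"), c(1L, 3L), cues, 5L), "out of bounds")
})

test_that("similarity linking is the thresholded argmax over the lexicon", {
  lex <- tiny_lexicon()
  hit <- similarity_link("angiokeratoma", lex, 0.85)
  expect_identical(hit$term_id, "angiokeratoma")
  expect_equal(hit$similarity, 1, tolerance = 1e-9)
  expect_null(similarity_link("angiokertomaz", lex, 1.0))
  empty <- build_lexicon(list())
  expect_null(similarity_link("anything", empty, 0.5))
  # brute-force argmax oracle on perturbed queries (queries lemmatized the
  # same way the linker lemmatizes them)
  set.seed(7)
  queries <- c("angiokeratomass", "proteinuriaa", "strokee", "verticillata",
               "corneas", "xyzzy")
  for (q in queries) {
    qn <- paste(fabryscreen:::normalize_phrase_tokens(q, lex$lemma_rules),
                collapse = " ")
    sims <- vapply(lex$order, function(id)
      cosine_similarity(fd_embed(qn), lex$entries[[id]]$embedding), 0)
    best <- which.max(sims)
    got <- similarity_link(q, lex, threshold = 0.2)
    if (max(sims) >= 0.2) {
      expect_identical(got$term_id, lex$order[best])
      expect_equal(got$similarity, max(sims), tolerance = 1e-9)
    } else {
      expect_null(got)
    }
  }
})

test_that("entity extraction composes the pipeline with correct polarity", {
  lex <- tiny_lexicon()
  e <- extract_entities("No angiokeratoma. Proteinuria found.", lex)
  expect_equal(nrow(e), 2)
  expect_identical(e$term_id, c("angiokeratoma", "proteinuria"))
  expect_identical(e$polarity, c("negated", "affirmed"))
  expect_identical(e$sentence_index, c(0L, 1L))
  expect_identical(e$link_method, c("pattern", "pattern"))

  expect_equal(nrow(extract_entities("", lex)), 0)

  # typo'd known term is recovered through edit-distance-1 correction
  e2 <- extract_entities("Patient has angiokertoma on exam.", lex)
  expect_equal(nrow(e2), 1)
  expect_identical(e2$term_id, "angiokeratoma")
  expect_identical(e2$polarity, "affirmed")
  expect_identical(e2$link_method, "pattern")
})

test_that("flipping a 'no ' prefix flips only the adjacent mention", {
  lex <- tiny_lexicon()
  a <- extract_entities("Angiokeratoma seen. Proteinuria found.", lex)
  b <- extract_entities("No angiokeratoma seen. Proteinuria found.", lex)
  expect_identical(a$polarity, c("affirmed", "affirmed"))
  expect_identical(b$polarity, c("negated", "affirmed"))
  expect_identical(a$term_id, b$term_id)
})

test_that("extraction is deterministic", {
  lex <- default_lexicon()
  note <- "No angiokeratoma. Examination revealed proteinuria and hearing loss. Known history of amyloidosis."
  expect_identical(extract_entities(note, lex), extract_entities(note, lex))
})

test_that("precision audit counts correct affirmed detections per term", {
  lex <- tiny_lexicon()
  gold_ok <- list(
    list(text = "Patient reports angiokeratoma.",
         mentions = data.frame(term_id = "angiokeratoma", sentence_index = 0L,
                               start = 2L, end = 3L, polarity = "affirmed",
                               stringsAsFactors = FALSE)),
    list(text = "Examination revealed proteinuria.",
         mentions = data.frame(term_id = "proteinuria", sentence_index = 0L,
                               start = 2L, end = 3L, polarity = "affirmed",
                               stringsAsFactors = FALSE)))
  res <- precision_audit(gold_ok, lex)
  expect_equal(res$precision[res$term_id == "angiokeratoma"], 1)
  expect_equal(res$precision[res$term_id == "proteinuria"], 1)
  expect_true(res$undefined[res$term_id == "stroke"])

  # a near-miss with no gold mention halves the precision: 1 of 2 detections
  gold_fp <- c(gold_ok[1], list(list(text = "Prior notes mention angiokertoma.",
                                     mentions = NULL)))
  res2 <- precision_audit(gold_fp, lex)
  expect_equal(res2$n_detections[res2$term_id == "angiokeratoma"], 2L)
  expect_equal(res2$n_correct[res2$term_id == "angiokeratoma"], 1L)
  expect_equal(res2$precision[res2$term_id == "angiokeratoma"], 0.5)
})
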