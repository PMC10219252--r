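#' Deterministic hashed character-trigram embedding
#'
#' Maps a normalized phrase to a unit vector by hashing its character
#' trigrams into a fixed number of signed buckets. The embedder is fully
#' deterministic (no model file, no randomness), so identical phrases always
#' produce identical vectors; it stands behind the same cosine-similarity
#' interface a pretrained word-vector model would, and can be swapped for one
#' via the `embedder` argument of [build_lexicon()].
#'
#' Trigrams are taken from the phrase padded with a leading and trailing
#' marker character, so that word boundaries contribute; phrases shorter than
#' three characters after padding still yield at least one trigram.
#'
#' @param phrase Character scalar, a normalized (lower-case) phrase.
#' @param dim Integer, embedding dimension (number of hash buckets).
#' @return Numeric vector of length `dim` with unit Euclidean norm.
#' @examples
#' v <- fd_embed("angiokeratoma")
#' sqrt(sum(v^2)) # 1
#' @export
fd_embed <- function(phrase, dim = 256L) {
  if (!is.character(phrase) || length(phrase) != 1L || is.na(phrase) ||
      !nzchar(trimws(phrase))) {
    stop("fd_embed(): 'phrase' must be a non-empty character scalar")
  }
  tri <- phrase_trigrams(phrase)
  v <- numeric(dim)
  for (g in tri) {
    h <- trigram_hash(g)
    idx <- (h %% dim) + 1L
    sgn <- if ((h %/% dim) %% 2L == 0L) 1 else -1
    v[idx] <- v[idx] + sgn
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) {
    # all buckets cancelled (only possible via sign collisions); fall back to
    # a deterministic single-bucket vector so the unit-norm contract holds
    v[(trigram_hash(phrase) %% dim) + 1L] <- 1
    nrm <- 1
  }
  v / nrm
}

#' Character trigrams of a padded phrase
#'
#' @param phrase Character scalar.
#' @return Character vector of trigrams (with multiplicity).
#' @keywords internal
phrase_trigrams <- function(phrase) {
  padded <- paste0("^", phrase, "$")
  n <- nchar(padded)
  if (n < 3L) padded <- paste0(padded, strrep("$", 3L - n))
  n <- nchar(padded)
  substring(padded, seq_len(n - 2L), seq(3L, n))
}

# Deterministic 31-ary polynomial rolling hash over code points, kept inside
# double precision (mod 2^26 keeps products exact).
trigram_hash <- function(s) {
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 67108864
  as.integer(h)
}

#' Cosine similarity between two vectors
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return The cosine of the angle between `u` and `v`, in \[-1, 1\].
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1)) # sqrt(2)/2
#' @export
cosine_similarity <- function(u, v) {
  if (!is.numeric(u) || !is.numeric(v) || length(u) != length(v)) {
    stop("cosine_similarity(): 'u' and 'v' must be numeric vectors of equal length")
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine_similarity(): zero vector")
  s <- sum(u * v) / (nu * nv)
  max(-1, min(1, s))
}
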