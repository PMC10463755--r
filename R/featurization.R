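#' Segment a token sequence into overlapping k-grams
#'
#' Sliding window of length `k` with stride 1: the output has
#' `max(0, length(tokens) - k + 1)` phrases; with `k = 1` the output is
#' the input itself.
#'
#' @param tokens Character vector of words or single characters.
#' @param k Positive window length.
#' @return Character vector of phrases (k-grams joined without separator).
#' @export
segment_kgrams <- function(tokens, k) {
  if (k < 1) stop_config("k must be >= 1")
  n <- length(tokens)
  if (n < k) return(character())
  if (k == 1L) return(as.character(tokens))
  vapply(seq_len(n - k + 1L),
         function(i) paste(tokens[i:(i + k - 1L)], collapse = ""),
         character(1))
}

#' Build a first-appearance k-gram vocabulary
#'
#' Indices 0 and 1 are reserved for PAD and UNK; phrases get indices from
#' 2 upward in the order of their first appearance across the corpus
#' (documents scanned in order). Build vocabularies on the training split
#' only; unseen phrases encode to UNK.
#'
#' @param corpus List of phrase vectors (each a document).
#' @param k The k-gram length the corpus was segmented with (recorded).
#' @return A `kgram_vocab`: list with `k`, `map` (named integer vector,
#'   phrase -> index), and reserved `pad = 0`, `unk = 1`.
#' @export
build_vocab <- function(corpus, k = 1L) {
  phrases <- unlist(corpus, use.names = FALSE)
  uniq <- unique(phrases)
  map <- if (length(uniq)) {
    stats::setNames(seq_along(uniq) + 1L, uniq)
  } else stats::setNames(integer(), character())
  structure(list(k = as.integer(k), map = map, pad = 0L, unk = 1L),
            class = "kgram_vocab")
}

#' @export
print.kgram_vocab <- function(x, ...) {
  cat("k-gram vocabulary: k =", x$k, ", size =", vocab_size(x),
      "(incl. PAD, UNK)\n")
  invisible(x)
}

#' Vocabulary size including reserved indices
#' @param vocab A `kgram_vocab`.
#' @return Integer, number of distinct indices (phrases + PAD + UNK).
#' @export
vocab_size <- function(vocab) length(vocab$map) + 2L

#' Save / load a vocabulary as JSON
#' @param vocab A `kgram_vocab`.
#' @param path File path.
#' @return `path` (save) or the vocabulary (load).
#' @export
save_vocab <- function(vocab, path) {
  jsonlite::write_json(list(k = vocab$k, phrases = names(vocab$map)),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_vocab
#' @export
load_vocab <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  build_vocab(list(as.character(x$phrases)), k = x$k)
}

#' Encode phrases as a fixed-length index sequence
#'
#' Phrases are mapped through the vocabulary (unknown phrases to UNK = 1),
#' truncated to length `L` and right-padded with PAD = 0.
#'
#' @param phrases Character vector of phrases.
#' @param vocab A `kgram_vocab`.
#' @param L Fixed output length.
#' @return A `token_seq`: list with `indices` (length `L`),
#'   `valid_length`, and `pad_mask` (`TRUE` exactly on padded positions).
#' @export
encode_tokens <- function(phrases, vocab, L) {
  if (L < 1) stop_config("L must be >= 1")
  idx <- unname(vocab$map[phrases])
  idx[is.na(idx)] <- vocab$unk
  v <- min(length(idx), L)
  out <- rep(vocab$pad, L)
  if (v > 0L) out[seq_len(v)] <- idx[seq_len(v)]
  structure(list(indices = as.integer(out), valid_length = as.integer(v),
                 pad_mask = seq_len(L) > v),
            class = "token_seq")
}

#' Featurize a protein sequence
#'
#' Uppercases the amino-acid string, segments it into character-level
#' k-grams and encodes against the protein vocabulary.
#'
#' @param sequence Amino-acid string (non-standard letters become their
#'   own tokens).
#' @param vocab Protein `kgram_vocab`.
#' @param k k-gram length (should match the vocabulary's).
#' @param L Fixed token length.
#' @return A `token_seq`.
#' @export
featurize_protein <- function(sequence, vocab, k = vocab$k, L) {
  if (!nzchar(sequence))
    stop_featurize("empty protein sequence")
  chars <- strsplit(toupper(sequence), "")[[1L]]
  encode_tokens(segment_kgrams(chars, k), vocab, L)
}

# Phrase list for one drug's text modality under a config.
drug_text_phrases <- function(smiles, cfg) {
  words <- if (cfg$text_source == "smiles") smiles_text(smiles)
  else chemical_text(smiles)
  segment_kgrams(words, cfg$k_drug)
}

# Phrase list for a protein under a config.
protein_phrases <- function(sequence, cfg) {
  segment_kgrams(strsplit(toupper(sequence), "")[[1L]], cfg$k_tgt)
}
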