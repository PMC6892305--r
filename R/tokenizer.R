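# Greedy WordPiece tokenization and sentence-pair encoding.
#
# A vocabulary maps piece strings to contiguous ids starting at 0 (the
# standard one-token-per-line file format). Words are segmented greedily,
# longest match first; non-initial pieces carry the "##" continuation
# prefix; a word with no matching prefix at any point becomes [UNK].

WP_SPECIALS <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]")

#' Construct a WordPiece vocabulary
#'
#' @param tokens character vector of piece strings; ids are assigned
#'   contiguously from 0 in the given order. All five special tokens
#'   (`[PAD] [UNK] [CLS] [SEP] [MASK]`) must be present and no token may be
#'   duplicated.
#' @return an object of class `wordpiece_vocab`.
#' @export
wordpiece_vocab <- function(tokens) {
  tokens <- as.character(tokens)
  if (anyDuplicated(tokens)) {
    stop("duplicate tokens in vocabulary: ",
         paste(unique(tokens[duplicated(tokens)]), collapse = ", "),
         call. = FALSE)
  }
  missing <- setdiff(WP_SPECIALS, tokens)
  if (length(missing)) {
    stop("vocabulary lacks special tokens: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  index <- seq_along(tokens) - 1L
  names(index) <- tokens
  structure(list(tokens = tokens, index = index, size = length(tokens)),
            class = "wordpiece_vocab")
}

#' @export
print.wordpiece_vocab <- function(x, ...) {
  cat(sprintf("<wordpiece_vocab: %d tokens>\n", x$size))
  invisible(x)
}

#' Token ids for piece strings
#' @param vocab a [wordpiece_vocab].
#' @param tokens character pieces.
#' @return integer ids (0-based); unknown pieces map to the `[UNK]` id.
#' @export
vocab_id <- function(vocab, tokens) {
  ids <- vocab$index[tokens]
  unk <- vocab$index[["[UNK]"]]
  ids[is.na(ids)] <- unk
  unname(ids)
}

#' Read/write a vocabulary file (one token per line; line number - 1 = id)
#' @param src file path or character lines.
#' @return a [wordpiece_vocab].
#' @export
read_vocab <- function(src) wordpiece_vocab(as_lines(src))

#' @rdname read_vocab
#' @param vocab a [wordpiece_vocab].
#' @param path output file path.
#' @export
write_vocab <- function(vocab, path) {
  writeLines(vocab$tokens, path, useBytes = TRUE)
  invisible(path)
}

#' Basic tokenization: lowercase, isolate punctuation and CJK characters
#'
#' The pre-WordPiece pass used by uncased models: lowercases, puts a space
#' around every punctuation character and every CJK ideograph (so Chinese
#' text tokenizes character-by-character), and splits on whitespace.
#'
#' @param text character scalar.
#' @param lowercase lowercase before splitting.
#' @return character vector of word tokens (possibly empty).
#' @export
basic_tokenize <- function(text, lowercase = TRUE) {
  if (lowercase) text <- tolower(text)
  text <- gsub("([\\p{P}\\p{S}])", " \\1 ", text, perl = TRUE)
  text <- gsub("([\\p{Han}])", " \\1 ", text, perl = TRUE)
  toks <- strsplit(trimws(text), "\\s+", perl = TRUE)[[1]]
  toks[toks != ""]
}

#' Greedy WordPiece segmentation of a single word
#'
#' Longest-match-first: repeatedly take the longest vocabulary piece that
#' prefixes the remaining characters ("##"-prefixed after the first piece).
#' If at any point no piece matches, the whole word maps to `[UNK]`. Words
#' longer than `max_chars` also map to `[UNK]`.
#'
#' @param word nonempty word without whitespace.
#' @param vocab a [wordpiece_vocab].
#' @param max_chars guard against pathological input (default 100).
#' @return character vector of pieces.
#' @export
wordpiece_tokenize <- function(word, vocab, max_chars = 100L) {
  n <- nchar(word)
  if (n == 0L) stop("cannot tokenize an empty word", call. = FALSE)
  if (n > max_chars) return("[UNK]")
  pieces <- character()
  start <- 1L
  while (start <= n) {
    end <- n
    found <- NA_character_
    while (end >= start) {
      cand <- substr(word, start, end)
      if (start > 1L) cand <- paste0("##", cand)
      if (!is.na(vocab$index[cand])) {
        found <- cand
        break
      }
      end <- end - 1L
    }
    if (is.na(found)) return("[UNK]")
    pieces <- c(pieces, found)
    start <- end + 1L
  }
  pieces
}

#' Tokenize running text into WordPiece pieces
#'
#' @param text character scalar.
#' @param vocab a [wordpiece_vocab].
#' @param lowercase lowercase during basic tokenization.
#' @return character vector of pieces.
#' @export
tokenize_text <- function(text, vocab, lowercase = TRUE) {
  words <- basic_tokenize(text, lowercase)
  if (!length(words)) return(character())
  unlist(lapply(words, wordpiece_tokenize, vocab = vocab), use.names = FALSE)
}

#' Encode a sentence pair as a fixed-length token sequence
#'
#' Layout `[CLS] A [SEP] B [SEP] [PAD]...`: segment 0 covers `[CLS]`
#' through the first `[SEP]`, segment 1 the rest up to the padding;
#' positions run 0..max_len-1; the attention mask is 0 exactly on `[PAD]`.
#' When the pair exceeds `max_len`, tokens are removed from the end of
#' whichever of A/B is currently longer until it fits (longest-first
#' truncation).
#'
#' @param sentence_a first sentence (the entity pair); must be nonempty.
#' @param sentence_b second sentence (the context document).
#' @param vocab a [wordpiece_vocab].
#' @param max_len total sequence length including specials (>= 5).
#' @param lowercase lowercase during basic tokenization.
#' @return an object of class `token_sequence` with equal-length fields
#'   `tokens`, `ids` (0-based), `segment_ids` (0/1), `positions`, `mask`,
#'   plus `n` (count of non-pad positions).
#' @export
encode_pair <- function(sentence_a, sentence_b, vocab, max_len,
                        lowercase = TRUE) {
  stopifnot(max_len >= 5L)
  a <- tokenize_text(sentence_a, vocab, lowercase)
  if (!length(a)) {
    stop("sentence_a is empty after tokenization; an instance always names two entities",
         call. = FALSE)
  }
  b <- tokenize_text(sentence_b, vocab, lowercase)
  budget <- max_len - 3L # [CLS] + 2x[SEP]
  while (length(a) + length(b) > budget) {
    if (length(a) >= length(b)) a <- a[-length(a)] else b <- b[-length(b)]
  }
  tokens <- c("[CLS]", a, "[SEP]", b, "[SEP]")
  n <- length(tokens)
  seg <- c(rep(0L, length(a) + 2L), rep(1L, length(b) + 1L))
  pad <- max_len - n
  tokens <- c(tokens, rep("[PAD]", pad))
  seg <- c(seg, rep(0L, pad))
  structure(list(tokens = tokens,
                 ids = vocab_id(vocab, tokens),
                 segment_ids = seg,
                 positions = seq_len(max_len) - 1L,
                 mask = c(rep(1L, n), rep(0L, pad)),
                 n = n),
            class = "token_sequence")
}

#' @export
print.token_sequence <- function(x, ...) {
  cat(sprintf("<token_sequence: %d tokens (%d padded)>\n",
              length(x$tokens), sum(x$mask == 0)))
  cat(" ", paste(utils::head(x$tokens[x$mask == 1], 16), collapse = " "),
      if (x$n > 16) "..." else "", "\n")
  invisible(x)
}

#' Build a WordPiece vocabulary from a corpus
#'
#' Miniature vocabulary induction sufficient for from-scratch pretraining:
#' the five specials, every single character seen (both as a word-initial
#' piece and as a "##" continuation, guaranteeing zero `[UNK]` on the
#' corpus itself), then whole words by descending frequency (ties broken
#' lexicographically) until `target_size` is reached.
#'
#' @param corpus character vector of text lines.
#' @param target_size maximum vocabulary size; must at least accommodate the
#'   specials and the character-level pieces.
#' @param lowercase lowercase during basic tokenization.
#' @return a [wordpiece_vocab].
#' @export
build_vocab <- function(corpus, target_size = 2000L, lowercase = TRUE) {
  words <- unlist(lapply(corpus, basic_tokenize, lowercase = lowercase),
                  use.names = FALSE)
  chars <- unique(unlist(strsplit(words, ""), use.names = FALSE))
  chars <- sort(chars)
  base <- c(WP_SPECIALS, chars, paste0("##", chars))
  if (target_size < length(base)) {
    stop(sprintf(
      "target_size %d too small: %d specials + %d character pieces require %d",
      target_size, length(WP_SPECIALS), 2L * length(chars), length(base)),
      call. = FALSE)
  }
  freq <- table(words)
  ord <- order(-as.integer(freq), names(freq)) # ties: lexicographic
  whole <- names(freq)[ord]
  whole <- setdiff(whole, base)
  room <- target_size - length(base)
  wordpiece_vocab(c(base, utils::head(whole, room)))
}

#' Detokenize pieces back to text
#'
#' Strips "##" continuation prefixes and joins pieces: continuations attach
#' to the previous piece, whole pieces are space-separated.
#'
#' @param pieces character vector of pieces.
#' @return character scalar.
#' @export
detokenize <- function(pieces) {
  if (!length(pieces)) return("")
  out <- character()
  for (p in pieces) {
    if (startsWith(p, "##") && length(out)) {
      out[length(out)] <- paste0(out[length(out)], substring(p, 3))
    } else {
      out <- c(out, p)
    }
  }
  paste(out, collapse = " ")
}
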