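test_that("the worked sub-word example splits into its five pieces", {
  v <- example_vocab()
  expect_identical(wordpiece_tokenize("suxamethonium", v),
                   c("su", "##xa", "##met", "##hon", "##ium"))
})

test_that("whole-vocabulary words stay single pieces and dead ends give [UNK]", {
  v <- example_vocab()
  expect_identical(wordpiece_tokenize("masseter", v), "masseter")
  expect_identical(wordpiece_tokenize("qqq", v), "[UNK]")
  expect_identical(wordpiece_tokenize(strrep("a", 101), tiny_vocab()), "[UNK]")
  expect_error(wordpiece_tokenize("", v), "empty")
})

# independent oracle: recursive greedy longest-prefix segmentation
oracle_wordpiece <- function(word, pieces, initial = TRUE) {
  if (nchar(word) == 0) return(character())
  for (len in nchar(word):1) {
    cand <- substr(word, 1, len)
    key <- if (initial) cand else paste0("##", cand)
    if (key %in% pieces) {
      rest <- oracle_wordpiece(substring(word, len + 1), pieces, FALSE)
      if (length(rest) == 1 && identical(rest, "[UNK]")) return("[UNK]")
      return(c(key, rest))
    }
  }
  "[UNK]"
}

test_that("greedy segmentation equals the recursive longest-prefix oracle", {
  set.seed(21)
  for (rep in 1:60) {
    alpha <- letters[1:4]
    frag <- replicate(12, paste(sample(alpha, sample(1:3, 1), TRUE), collapse = ""))
    pieces <- unique(c(frag, paste0("##", sample(frag))))
    vocab <- wordpiece_vocab(c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]",
                               unique(pieces)))
    word <- paste(sample(alpha, sample(1:12, 1), TRUE), collapse = "")
    expect_identical(wordpiece_tokenize(word, vocab),
                     oracle_wordpiece(word, vocab$tokens),
                     info = word)
  }
})

test_that("tokenization is pure and detokenization inverts in-vocabulary words", {
  v <- tiny_vocab(c("cocaine", "##ine"))
  set.seed(4)
  for (rep in 1:30) {
    w <- paste(sample(letters[1:6], sample(1:10, 1), TRUE), collapse = "")
    p1 <- wordpiece_tokenize(w, v)
    expect_identical(p1, wordpiece_tokenize(w, v))
    expect_gte(length(p1), 1)
    expect_lte(length(p1), nchar(w))
    if (!identical(p1, "[UNK]")) expect_identical(detokenize(p1), w)
  }
})

test_that("sentence pairs encode with the documented layout", {
  v <- tiny_vocab()
  s <- encode_pair("ab cd", "ef gh ij", v, max_len = 20)
  expect_identical(s$tokens[1], "[CLS]")
  expect_equal(sum(s$tokens == "[SEP]"), 2)
  first_sep <- which(s$tokens == "[SEP]")[1]
  expect_true(all(s$segment_ids[1:first_sep] == 0))
  expect_true(all(s$segment_ids[(first_sep + 1):s$n] == 1))
  expect_identical(s$positions, 0:19)
  expect_identical(s$mask, as.integer(s$tokens != "[PAD]"))
  expect_error(encode_pair("", "context", v, 20), "sentence_a")
})

test_that("an exact-length pair needs no padding", {
  v <- tiny_vocab()
  n_tokens <- length(wordpiece_tokenize("ab", v)) +
    length(wordpiece_tokenize("cd", v)) + 3
  s <- encode_pair("ab", "cd", v, max_len = n_tokens)
  expect_equal(sum(s$mask), n_tokens)
  expect_false("[PAD]" %in% s$tokens)
})

test_that("truncation removes from the end of the longer side", {
  v <- tiny_vocab()
  set.seed(9)
  for (rep in 1:25) {
    wa <- sample(letters[1:5], sample(1:6, 1), TRUE)
    wb <- sample(letters[1:5], sample(1:12, 1), TRUE)
    max_len <- sample(5:12, 1)
    s <- encode_pair(paste(wa, collapse = " "), paste(wb, collapse = " "),
                     v, max_len)
    # reference rule: drop from the longer side until it fits
    a <- wa; b <- wb
    while (length(a) + length(b) > max_len - 3) {
      if (length(a) >= length(b)) a <- a[-length(a)] else b <- b[-length(b)]
    }
    expect_identical(s$tokens[s$mask == 1],
                     c("[CLS]", a, "[SEP]", b, "[SEP]"))
    expect_equal(sum(s$mask), min(max_len, length(wa) + length(wb) + 3))
    # the initially shorter side never loses more tokens than the longer
    if (length(wa) < length(wb)) {
      expect_gte(length(wb) - length(b), length(wa) - length(a))
    }
  }
})

test_that("an induced vocabulary covers its own corpus with no [UNK]", {
  corpus <- c("the drug induced a rare disease", "a drug study",
              "rare disease course")
  v <- build_vocab(corpus, target_size = 80)
  expect_true(all(c("a", "drug", "the") %in% v$tokens))
  pieces <- unlist(lapply(corpus, tokenize_text, vocab = v))
  expect_false("[UNK]" %in% pieces)
  expect_error(build_vocab(corpus, target_size = 10), "too small")
})

test_that("frequency ties in vocabulary induction break lexicographically", {
  v1 <- build_vocab("zeta alpha zeta alpha", 40)
  v2 <- build_vocab("alpha zeta alpha zeta", 40)
  expect_identical(v1$tokens, v2$tokens)
  expect_lt(vocab_id(v1, "alpha"), vocab_id(v1, "zeta"))
})

test_that("vocabulary files round-trip with line number as id", {
  v <- tiny_vocab()
  path <- withr::local_tempfile(fileext = ".txt")
  write_vocab(v, path)
  v2 <- read_vocab(path)
  expect_identical(v2$tokens, v$tokens)
  expect_equal(vocab_id(v2, "[CLS]"), 2)
})

test_that("CJK characters tokenize one character at a time", {
  toks <- basic_tokenize("人参 treats")
  expect_identical(toks, c("人", "参", "treats"))
})
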