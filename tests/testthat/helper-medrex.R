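# Shared helpers: tiny fixtures built in code, and a lazily computed cache
# of the miniature benchmark (pretraining is the expensive step; every test
# that needs a pretrained encoder shares this one).

tiny_vocab <- function(extra = character()) {
  wordpiece_vocab(c("[PAD]", "[UNK]", "[CLS]", "[SEP]", "[MASK]",
                    letters, paste0("##", letters), extra))
}

# a deterministic miniature corpus for cheap IO/sampling tests
tiny_docs <- function(n = 6, seed = 42) {
  generate_relation_corpus(synth_config(n_docs = n, seed = seed))
}

# random canonical document records (for round-trip property tests)
random_document <- function(i) {
  words <- c("alpha", "beta", "gamma", "delta", "unit", "trial")
  title <- paste(sample(words, 3, TRUE), collapse = " ")
  abstract <- paste(sample(words, 8, TRUE), collapse = " ")
  txt <- paste(title, abstract)
  # pick two word occurrences as mentions
  starts <- c(0L, nchar(title) + 1L)
  surf <- c(substr(txt, 1, regexpr(" ", txt) - 1),
            sub(" .*", "", abstract))
  mentions <- data.frame(start = starts,
                         end = starts + nchar(surf),
                         surface = surf,
                         etype = c("Chemical", "Disease"),
                         concept_id = c("C001", "D001"),
                         stringsAsFactors = FALSE)
  relations <- data.frame(rtype = "CID", id1 = "C001", id2 = "D001",
                          stringsAsFactors = FALSE)
  document_record(sprintf("r%04d", i), title, abstract, mentions, relations)
}

bench_env <- new.env(parent = emptyenv())

# the miniature benchmark, computed once per test run
bench_cache <- function() {
  if (is.null(bench_env$data)) {
    cond <- miniature_conditions()
    data <- miniature_data(cond)
    bench_env$cond <- cond
    bench_env$data <- data
    bench_env$pt <- miniature_pretrain(data, cond)
  }
  list(cond = bench_env$cond, data = bench_env$data, pt = bench_env$pt)
}
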