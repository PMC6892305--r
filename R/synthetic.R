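# Synthetic corpora with the statistical structure the method assumes:
# abstract-level documents, typed entity mentions with exact character
# offsets, and relations carried by a planted lexical trigger signal, so a
# rule-based matcher (and a small encoder) can recover the labels.

SYN_SYLLABLES <- c("ba", "ce", "di", "fo", "gu", "ha", "ki", "lo", "mu",
                   "ne", "pa", "qui", "ro", "su", "ta", "ve", "wi", "xa",
                   "yo", "zu")

syn_name <- function(i, suffix) {
  s <- SYN_SYLLABLES
  paste0(s[(i - 1) %/% length(s) %% length(s) + 1],
         s[(i - 1) %% length(s) + 1], suffix)
}

#' Synthetic corpus settings
#'
#' Defaults emulate an easy BC5CDR-like regime: a few typed entities per
#' abstract, a relation for roughly half the chemical-disease pairs, and a
#' relation signalled by a trigger verb ("induced", "caused", ...) linking
#' the two names inside one sentence. Entities of an unrelated pair never
#' share a sentence, so a trigger-pattern matcher separates the classes
#' perfectly; `trigger_dropout` and `distractor_triggers` are difficulty
#' knobs (defaults off).
#'
#' @param n_docs number of documents.
#' @param chemicals_per_doc,diseases_per_doc entities sampled per document.
#' @param rel_prob overall probability a chemical-disease pair carries a
#'   relation (the density of the corpus fact table).
#' @param factored_facts when `TRUE` (default) the fact table factorizes:
#'   a pair is related iff the chemical belongs to the inducing subset and
#'   the disease to the inducible subset (each drawn with probability
#'   `sqrt(rel_prob)`). This is the easy regime a small encoder can learn
#'   quickly; `FALSE` draws every pair independently, so the classifier
#'   must memorize individual pairs (harder regime).
#' @param trigger_lexicon trigger words linking related pairs.
#' @param distractor_triggers trigger-like words planted in unrelated
#'   sentences (harder regime).
#' @param trigger_dropout probability a related pair's trigger is omitted
#'   (harder regime).
#' @param n_chemicals,n_diseases,n_filler lexicon sizes; the three lexicons
#'   are disjoint by construction.
#' @param sentence_len integer range of filler tokens per sentence.
#' @param seed integer seed.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(n_docs = 150L, chemicals_per_doc = 2L,
                         diseases_per_doc = 4L, rel_prob = 0.3,
                         factored_facts = TRUE,
                         trigger_lexicon = c("induced", "caused", "provoked"),
                         distractor_triggers = character(),
                         trigger_dropout = 0,
                         n_chemicals = 10L, n_diseases = 12L,
                         n_filler = 120L, sentence_len = c(3L, 6L),
                         seed = 1L) {
  stopifnot(rel_prob >= 0, rel_prob <= 1, trigger_dropout >= 0,
            trigger_dropout <= 1, n_docs >= 1)
  chem <- vapply(seq_len(n_chemicals), syn_name, character(1), suffix = "ine")
  dis <- vapply(seq_len(n_diseases), syn_name, character(1), suffix = "osis")
  filler <- vapply(seq_len(n_filler), syn_name, character(1), suffix = "")
  lex <- list(chemicals = chem, diseases = dis, filler = filler,
              triggers = trigger_lexicon)
  if (anyDuplicated(unlist(lex))) {
    stop("entity, filler and trigger lexicons must be disjoint", call. = FALSE)
  }
  structure(list(n_docs = as.integer(n_docs),
                 chemicals_per_doc = as.integer(chemicals_per_doc),
                 diseases_per_doc = as.integer(diseases_per_doc),
                 rel_prob = rel_prob, factored_facts = factored_facts,
                 trigger_lexicon = trigger_lexicon,
                 distractor_triggers = distractor_triggers,
                 trigger_dropout = trigger_dropout,
                 lexicon = lex, sentence_len = as.integer(sentence_len),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# p(rank) proportional to 1/rank over the filler vocabulary
zipf_sample <- function(n, filler) {
  p <- 1 / seq_along(filler)
  filler[sample.int(length(filler), n, replace = TRUE, prob = p / sum(p))]
}

sample1 <- function(x) if (length(x) == 1L) x else sample(x, 1L)

# one sentence as a token vector; `entities` is a data.frame of tokens that
# are entity mentions (token index filled in later)
syn_sentence <- function(cfg, entity_tokens = character(),
                         entity_meta = NULL, with_trigger = FALSE) {
  nf <- sample(seq(cfg$sentence_len[1], cfg$sentence_len[2]), 1L)
  filler <- zipf_sample(nf, cfg$lexicon$filler)
  if (length(cfg$distractor_triggers) && !with_trigger &&
      stats::runif(1) < 0.3) {
    filler[sample1(seq_along(filler))] <- sample1(cfg$distractor_triggers)
  }
  if (!length(entity_tokens)) {
    return(list(tokens = filler, meta = NULL))
  }
  if (with_trigger) {
    core <- c(entity_tokens[1], sample1(cfg$trigger_lexicon), entity_tokens[2])
    meta_at <- c(1L, 3L)
  } else {
    core <- entity_tokens
    meta_at <- seq_along(entity_tokens)
  }
  cut <- sample1(seq_len(length(filler) + 1L)) - 1L
  tokens <- c(filler[seq_len(cut)], core,
              filler[setdiff(seq_along(filler), seq_len(cut))])
  meta <- NULL
  if (!is.null(entity_meta)) {
    meta <- entity_meta
    meta$token_idx <- cut + meta_at
  }
  list(tokens = tokens, meta = meta)
}

#' Generate an annotated relation-extraction corpus
#'
#' Whether a chemical induces a disease is drawn once per corpus as a
#' global fact table (each pool pair related with probability `rel_prob`),
#' mirroring the fact-level consistency of real annotation corpora: the
#' same pair carries the same relation wherever it is reported. Every
#' document mentions each of its entities in an isolated sentence; every
#' related chemical-disease pair present in a document additionally
#' co-occurs in a sentence where a trigger word links the two names.
#' Unrelated pairs never share a sentence, so the gold labels are exactly
#' recoverable from the trigger pattern (at the default easy settings).
#' Mention offsets are exact against `title + " " + abstract`.
#' Deterministic given the configuration seed.
#'
#' @param cfg a [synth_config].
#' @return a list of [document_record]s with gold relations annotated; the
#'   corpus-level fact table is attached as the `facts` attribute.
#' @export
generate_relation_corpus <- function(cfg = synth_config()) {
  facts <- synth_facts(cfg)
  with_seed(derive_seed(cfg$seed, "relation-corpus"), {
    docs <- lapply(seq_len(cfg$n_docs), function(di) {
      synth_document(cfg, di, facts)
    })
    attr(docs, "facts") <- facts
    docs
  })
}

#' The corpus-level chemical-disease fact table
#'
#' Drawn once per configuration seed and shared by
#' [generate_relation_corpus] and [generate_pretrain_corpus], the way the
#' facts reported in a literature corpus and the facts its annotations
#' encode are the same facts.
#'
#' @param cfg a [synth_config].
#' @return a logical `n_chemicals x n_diseases` matrix.
#' @export
synth_facts <- function(cfg) {
  with_seed(derive_seed(cfg$seed, "facts"), {
    nc <- length(cfg$lexicon$chemicals)
    nd <- length(cfg$lexicon$diseases)
    if (cfg$factored_facts) {
      inducing <- stats::runif(nc) < sqrt(cfg$rel_prob)
      inducible <- stats::runif(nd) < sqrt(cfg$rel_prob)
      outer(inducing, inducible, `&`)
    } else {
      matrix(stats::runif(nc * nd) < cfg$rel_prob, nrow = nc)
    }
  })
}

synth_document <- function(cfg, di, facts) {
  chem_idx <- sample(seq_along(cfg$lexicon$chemicals), cfg$chemicals_per_doc)
  dis_idx <- sample(seq_along(cfg$lexicon$diseases), cfg$diseases_per_doc)
  chems <- data.frame(name = cfg$lexicon$chemicals[chem_idx],
                      id = sprintf("C%03d", chem_idx), etype = "Chemical",
                      stringsAsFactors = FALSE)
  diss <- data.frame(name = cfg$lexicon$diseases[dis_idx],
                     id = sprintf("D%03d", dis_idx), etype = "Disease",
                     stringsAsFactors = FALSE)
  pairs <- expand.grid(ci = seq_len(nrow(chems)), dj = seq_len(nrow(diss)),
                       KEEP.OUT.ATTRS = FALSE)
  pairs$related <- facts[cbind(chem_idx[pairs$ci], dis_idx[pairs$dj])]

  sentences <- list()
  add_sentence <- function(s) sentences[[length(sentences) + 1L]] <<- s
  ents <- rbind(chems, diss)
  for (i in seq_len(nrow(ents))) {
    add_sentence(syn_sentence(cfg, ents$name[i],
                              data.frame(surface = ents$name[i],
                                         etype = ents$etype[i],
                                         concept_id = ents$id[i],
                                         stringsAsFactors = FALSE)))
  }
  for (r in which(pairs$related)) {
    with_trig <- stats::runif(1) >= cfg$trigger_dropout
    meta <- data.frame(
      surface = c(chems$name[pairs$ci[r]], diss$name[pairs$dj[r]]),
      etype = c("Chemical", "Disease"),
      concept_id = c(chems$id[pairs$ci[r]], diss$id[pairs$dj[r]]),
      stringsAsFactors = FALSE)
    if (with_trig) {
      add_sentence(syn_sentence(cfg, meta$surface, meta, with_trigger = TRUE))
    } else {
      add_sentence(syn_sentence(cfg, meta$surface, meta))
    }
  }
  sentences <- sentences[sample.int(length(sentences))]

  title_tokens <- c(zipf_sample(2L + sample.int(3L, 1L), cfg$lexicon$filler))
  title <- paste0(paste(title_tokens, collapse = " "), ".")
  offset <- nchar(title) + 1L # single separator space
  abstract_parts <- character(length(sentences))
  mention_rows <- list()
  for (si in seq_along(sentences)) {
    s <- sentences[[si]]
    text <- paste0(paste(s$tokens, collapse = " "), ".")
    starts <- offset + c(0L, cumsum(nchar(s$tokens) + 1L))[seq_along(s$tokens)]
    if (!is.null(s$meta)) {
      for (mi in seq_len(nrow(s$meta))) {
        tk <- s$meta$token_idx[mi]
        mention_rows[[length(mention_rows) + 1L]] <- data.frame(
          start = starts[tk], end = starts[tk] + nchar(s$tokens[tk]),
          surface = s$meta$surface[mi], etype = s$meta$etype[mi],
          concept_id = s$meta$concept_id[mi], stringsAsFactors = FALSE)
      }
    }
    abstract_parts[si] <- text
    offset <- offset + nchar(text) + 1L
  }
  abstract <- paste(abstract_parts, collapse = " ")
  mentions <- rbind_df(mention_rows, empty_mentions())
  mentions <- mentions[order(mentions$start), , drop = FALSE]
  rownames(mentions) <- NULL
  rel <- pairs[pairs$related, , drop = FALSE]
  relations <- data.frame(rtype = rep("CID", nrow(rel)),
                          id1 = chems$id[rel$ci], id2 = diss$id[rel$dj],
                          stringsAsFactors = FALSE)
  document_record(sprintf("syn%05d", di), title, abstract, mentions, relations)
}

#' Rule-based trigger oracle
#'
#' Labels a chemical-disease id pair "1" iff some sentence of the document
#' contains both entity names and a trigger word. On corpora generated with
#' the default (easy) settings this recovers the gold relations exactly;
#' it is the separability guarantee behind the learnability tests.
#'
#' @param doc a [document_record].
#' @param id1,id2 concept identifiers.
#' @param triggers trigger lexicon.
#' @return `"1"` or `"0"`.
#' @export
trigger_oracle <- function(doc, id1, id2, triggers = c("induced", "caused", "provoked")) {
  n1 <- tolower(surface_form(doc, id1))
  n2 <- tolower(surface_form(doc, id2))
  sents <- strsplit(tolower(doc_text(doc)), "\\.\\s*")[[1]]
  for (s in sents) {
    words <- strsplit(s, "\\s+")[[1]]
    if (n1 %in% words && n2 %in% words && any(triggers %in% words)) {
      return("1")
    }
  }
  "0"
}

#' Generate a sentence-segmented pretraining corpus
#'
#' Multi-document text with Zipf-distributed filler frequencies,
#' document-specific topical vocabulary and discourse-style sentence
#' continuity (giving the next-sentence objective a learnable signal), and
#' entity-trigger sentences that report the corpus fact table
#' ([synth_facts]) — so, as with real literature, the unstructured text
#' carries the domain knowledge the downstream task asks about.
#'
#' @param cfg a [synth_config].
#' @param n_docs number of documents.
#' @param sentences_per_doc sentences per document.
#' @return a list of character vectors (one sentence per element).
#' @export
generate_pretrain_corpus <- function(cfg = synth_config(), n_docs = 30L,
                                     sentences_per_doc = 8L) {
  facts <- synth_facts(cfg)
  related <- which(facts, arr.ind = TRUE)
  with_seed(derive_seed(cfg$seed, "pretrain-corpus"), {
    filler <- cfg$lexicon$filler
    n_head <- min(20L, length(filler) %/% 3L)
    head_words <- filler[seq_len(n_head)]
    head_p <- 1 / seq_len(n_head)
    # the remaining (rarer) words are partitioned into topic buckets,
    # strided over the rank range so every bucket has a similar frequency
    # profile; each document writes mostly in its own bucket's vocabulary,
    # giving consecutive sentences the topical coherence the next-sentence
    # objective relies on while keeping overall frequencies Zipf-like
    tail_ranks <- seq.int(n_head + 1L, length(filler))
    n_buckets <- 10L
    buckets <- split(tail_ranks, (tail_ranks - n_head - 1L) %% n_buckets)
    lapply(seq_len(n_docs), function(d) {
      bucket <- buckets[[sample.int(n_buckets, 1L)]]
      bucket_p <- 1 / bucket
      # discourse-style continuity: each sentence opens with the previous
      # sentence's final content word, as running text tends to
      carry <- filler[bucket[sample.int(length(bucket), 1L, prob = bucket_p)]]
      out <- character(sentences_per_doc)
      for (s in seq_len(sentences_per_doc)) {
        nt <- sample(cfg$sentence_len[1]:cfg$sentence_len[2], 1L)
        from_head <- stats::runif(nt) < 0.5
        toks <- character(nt)
        if (any(from_head)) {
          toks[from_head] <- head_words[sample.int(n_head, sum(from_head),
                                                   replace = TRUE,
                                                   prob = head_p)]
        }
        if (any(!from_head)) {
          toks[!from_head] <- filler[bucket[sample.int(length(bucket),
                                                       sum(!from_head),
                                                       replace = TRUE,
                                                       prob = bucket_p)]]
        }
        toks <- c(carry, toks)
        if (nrow(related) && stats::runif(1) < 0.4) {
          # report a true fact from the corpus fact table
          r <- related[sample1(seq_len(nrow(related))), ]
          toks <- c(toks, cfg$lexicon$chemicals[r[1]],
                    sample1(cfg$trigger_lexicon),
                    cfg$lexicon$diseases[r[2]])
        }
        carry <- toks[length(toks)]
        out[s] <- paste(toks, collapse = " ")
      }
      out
    })
  })
}

#' The printed chemical-disease example record (PMID 1601297)
#'
#' The worked example distributed with the method: one abstract with nine
#' typed mentions (one chemical concept, five disease concepts) and two
#' chemical-induced-disease relations, <D003042, D009203> and
#' <D003042, D002037>. Offsets are 0-based, end-exclusive, against
#' `title + " " + abstract`.
#'
#' @return a [document_record].
#' @export
fixture_1601297 <- function() {
  title <- "Electrocardiographic evidence of myocardial injury in psychiatrically hospitalized cocaine abusers."
  abstract <- paste0(
    "The electrocardiograms (ECG) of 99 cocaine-abusing patients were ",
    "compared with the ECGs of 50 schizophrenic controls. Eleven of the ",
    "cocaine abusers and none of the controls had ECG evidence of ",
    "significant myocardial injury defined as myocardial infarction, ",
    "ischemia, and bundle branch block.")
  mentions <- data.frame(
    start = c(33L, 83L, 135L, 194L, 232L, 305L, 334L, 357L, 371L),
    end = c(50L, 90L, 142L, 207L, 239L, 322L, 355L, 365L, 390L),
    surface = c("Myocardial injury", "Cocaine", "Cocaine", "Schizophrenic",
                "Cocaine", "Myocardial injury", "Myocardial infarction",
                "Ischemia", "Bundle branch block"),
    etype = c("Disease", "Chemical", "Chemical", "Disease", "Chemical",
              "Disease", "Disease", "Disease", "Disease"),
    concept_id = c("D009202", "D003042", "D003042", "D012559", "D003042",
                   "D009202", "D009203", "D007511", "D002037"),
    stringsAsFactors = FALSE)
  relations <- data.frame(rtype = c("CID", "CID"),
                          id1 = c("D003042", "D003042"),
                          id2 = c("D009203", "D002037"),
                          stringsAsFactors = FALSE)
  document_record("1601297", title, abstract, mentions, relations)
}
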