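# Balanced sentence-pair sample generation from annotated documents.
#
# An instance for the classifier is a sentence pair: sentence A is the two
# entity names joined by one space, sentence B is the context document
# (title + abstract). Annotated pairs become positives; unannotated typed
# pairs are sampled uniformly without replacement as negatives, per document,
# at a configurable ratio (default 1:1).

#' Sample generation settings
#'
#' @param neg_per_pos negatives drawn per positive (default 1, i.e. a 1:1
#'   balanced corpus).
#' @param pair_rule length-2 character: the entity types paired when drawing
#'   negatives, e.g. `c("Chemical", "Disease")`.
#' @param lowercase lowercase entity surfaces (matches an uncased tokenizer).
#' @param seed integer seed for negative sampling.
#' @return a list of class `generation_config`.
#' @export
generation_config <- function(neg_per_pos = 1, pair_rule = c("Chemical", "Disease"),
                              lowercase = TRUE, seed = 1L) {
  stopifnot(neg_per_pos >= 0, length(pair_rule) == 2L)
  structure(list(neg_per_pos = neg_per_pos, pair_rule = pair_rule,
                 lowercase = lowercase, seed = as.integer(seed)),
            class = "generation_config")
}

#' Surface form of a concept in a document
#'
#' Returns the surface text of the concept's first mention in document order
#' (by start offset), lowercased when `lowercase` is `TRUE`. This is the
#' name that enters sentence A of a sample; when a concept has several
#' distinct surfaces the first-mention form is used throughout.
#'
#' @param doc a [document_record].
#' @param concept_id concept identifier (e.g. a MeSH ID).
#' @param lowercase lowercase the surface.
#' @return character scalar.
#' @export
surface_form <- function(doc, concept_id, lowercase = TRUE) {
  m <- doc$mentions[doc$mentions$concept_id == concept_id, , drop = FALSE]
  if (!nrow(m)) {
    stop(sprintf("document %s has no mention with concept id '%s'",
                 doc$doc_id, concept_id), call. = FALSE)
  }
  s <- m$surface[which.min(m$start)]
  if (lowercase) tolower(s) else s
}

new_samples <- function(instance_id = character(), sentence_a = character(),
                        sentence_b = character(), label = character(),
                        id1 = character(), id2 = character(),
                        doc_id = character()) {
  data.frame(instance_id = instance_id, sentence_a = sentence_a,
             sentence_b = sentence_b, label = label,
             id1 = id1, id2 = id2, doc_id = doc_id, stringsAsFactors = FALSE)
}

#' Positive samples from a document's relation annotations
#'
#' One sample per relation annotation, labeled "1": sentence A is
#' `surface_form(id1) + " " + surface_form(id2)`, sentence B is the context
#' document.
#'
#' @param doc a [document_record].
#' @param cfg a [generation_config].
#' @return a data.frame of sentence-pair samples.
#' @export
make_positive_samples <- function(doc, cfg = generation_config()) {
  r <- doc$relations
  if (!nrow(r)) return(new_samples())
  a <- vapply(seq_len(nrow(r)), function(i) {
    paste(surface_form(doc, r$id1[i], cfg$lowercase),
          surface_form(doc, r$id2[i], cfg$lowercase))
  }, character(1))
  new_samples(instance_id = sprintf("%s_p%d", doc$doc_id, seq_len(nrow(r))),
              sentence_a = a,
              sentence_b = rep(doc_text(doc), nrow(r)),
              label = rep("1", nrow(r)),
              id1 = r$id1, id2 = r$id2,
              doc_id = rep(doc$doc_id, nrow(r)))
}

# all unannotated typed concept-id pairs of a document (the negative pool);
# undirected: annotated pairs are matched regardless of order
negative_pool <- function(doc, pair_rule) {
  m <- doc$mentions
  ids1 <- unique(m$concept_id[m$etype == pair_rule[1]])
  ids2 <- unique(m$concept_id[m$etype == pair_rule[2]])
  if (!length(ids1) || !length(ids2)) {
    return(data.frame(id1 = character(), id2 = character(),
                      stringsAsFactors = FALSE))
  }
  pool <- expand.grid(id1 = ids1, id2 = ids2, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  annotated <- key(doc$relations$id1, doc$relations$id2)
  pool <- pool[!(key(pool$id1, pool$id2) %in% annotated), , drop = FALSE]
  pool <- pool[!duplicated(key(pool$id1, pool$id2)), , drop = FALSE]
  rownames(pool) <- NULL
  pool
}

#' Negative samples from unannotated typed entity pairs
#'
#' Draws `min(n_pos * neg_per_pos, pool size)` distinct unannotated
#' (type1, type2) concept pairs uniformly without replacement within the
#' document and labels them "0". Deterministic given the configuration seed.
#' When the pool is smaller than requested, all candidates are emitted with
#' a warning.
#'
#' @param doc a [document_record].
#' @param n_pos number of positives the negatives are balanced against.
#' @param cfg a [generation_config].
#' @return a data.frame of sentence-pair samples.
#' @export
make_negative_samples <- function(doc, n_pos, cfg = generation_config()) {
  pool <- negative_pool(doc, cfg$pair_rule)
  want <- floor(n_pos * cfg$neg_per_pos)
  if (want == 0 || !nrow(pool)) return(new_samples())
  if (nrow(pool) < want) {
    warning(sprintf(
      "document %s: negative pool (%d) smaller than requested (%d); emitting all candidates",
      doc$doc_id, nrow(pool), want), call. = FALSE)
    take <- seq_len(nrow(pool))
  } else {
    take <- with_seed(derive_seed(cfg$seed, paste0("neg:", doc$doc_id)),
                      sample.int(nrow(pool), want))
  }
  sel <- pool[take, , drop = FALSE]
  a <- vapply(seq_len(nrow(sel)), function(i) {
    paste(surface_form(doc, sel$id1[i], cfg$lowercase),
          surface_form(doc, sel$id2[i], cfg$lowercase))
  }, character(1))
  new_samples(instance_id = sprintf("%s_n%d", doc$doc_id, seq_len(nrow(sel))),
              sentence_a = a,
              sentence_b = rep(doc_text(doc), nrow(sel)),
              label = rep("0", nrow(sel)),
              id1 = sel$id1, id2 = sel$id2,
              doc_id = rep(doc$doc_id, nrow(sel)))
}

#' Balanced samples for a whole corpus
#'
#' Positives then negatives per document, concatenated in corpus order.
#'
#' @param docs list of [document_record]s.
#' @param cfg a [generation_config].
#' @return a data.frame of sentence-pair samples.
#' @export
generate_samples <- function(docs, cfg = generation_config()) {
  parts <- lapply(docs, function(d) {
    pos <- make_positive_samples(d, cfg)
    neg <- make_negative_samples(d, nrow(pos), cfg)
    rbind(pos, neg)
  })
  out <- do.call(rbind, c(parts, list(new_samples())))
  rownames(out) <- NULL
  out
}

#' Attach context to instances by entity co-occurrence
#'
#' For each instance, scans the literature (a vector of abstracts) for the
#' first abstract in file order in which both entity names occur
#' (case-insensitive exact substring match). Instances whose names never
#' co-occur are dropped; the number dropped is reported as a message and as
#' the `dropped` attribute of the result.
#'
#' @param instances relation instances with empty `context`.
#' @param literature character vector of abstracts.
#' @return the retained instances with `context` filled.
#' @export
attach_context_by_cooccurrence <- function(instances, literature) {
  lit_low <- tolower(literature)
  ctx <- character(nrow(instances))
  keep <- logical(nrow(instances))
  for (i in seq_len(nrow(instances))) {
    hits <- grepl(tolower(instances$name1[i]), lit_low, fixed = TRUE) &
      grepl(tolower(instances$name2[i]), lit_low, fixed = TRUE)
    j <- which(hits)[1]
    if (!is.na(j)) {
      keep[i] <- TRUE
      ctx[i] <- literature[j]
    }
  }
  out <- instances[keep, , drop = FALSE]
  out$context <- ctx[keep]
  rownames(out) <- NULL
  dropped <- sum(!keep)
  message(sprintf("co-occurrence filtering: kept %d of %d instances (%d dropped)",
                  nrow(out), nrow(instances), dropped))
  attr(out, "dropped") <- dropped
  out
}

#' Multi-class sentence-pair samples from labeled instances
#'
#' Pass-through mapping for corpora whose instances are already labeled with
#' one of a finite set of relation names (e.g. the eight clinical temporal
#' relations): sentence A is the two entity names, sentence B the context,
#' and the label is kept verbatim. The label set, in fixed sorted order, is
#' recorded as the `label_set` attribute.
#'
#' @param instances relation instances with nonempty context.
#' @param lowercase lowercase entity names.
#' @return a data.frame of sentence-pair samples.
#' @export
to_multiclass_instances <- function(instances, lowercase = TRUE) {
  nm1 <- if (lowercase) tolower(instances$name1) else instances$name1
  nm2 <- if (lowercase) tolower(instances$name2) else instances$name2
  out <- new_samples(instance_id = instances$instance_id,
                     sentence_a = paste(nm1, nm2),
                     sentence_b = instances$context,
                     label = instances$label,
                     id1 = instances$id1, id2 = instances$id2,
                     doc_id = instances$instance_id)
  attr(out, "label_set") <- sort(unique(instances$label))
  out
}
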