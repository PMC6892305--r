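test_that("surface forms come from the first mention, lowercased", {
  d <- fixture_1601297()
  expect_identical(surface_form(d, "D003042"), "cocaine")
  expect_identical(surface_form(d, "D009203"), "myocardial infarction")
  expect_identical(surface_form(d, "D003042", lowercase = FALSE), "Cocaine")
  expect_error(surface_form(d, "D999999"), "D999999")
})

test_that("positive samples mirror the relation annotations", {
  d <- fixture_1601297()
  pos <- make_positive_samples(d)
  expect_equal(nrow(pos), 2)
  expect_identical(pos$sentence_a[1], "cocaine myocardial infarction")
  expect_identical(pos$sentence_a[2], "cocaine bundle branch block")
  expect_identical(unique(pos$label), "1")
  expect_identical(unique(pos$sentence_b), doc_text(d))
  empty <- document_record("x", "a title.", "an abstract.")
  expect_equal(nrow(make_positive_samples(empty)), 0)
})

test_that("negatives come from the unannotated typed pool, without duplicates, deterministically", {
  d <- fixture_1601297()
  pool <- c("D009202", "D012559", "D007511") # the three unannotated diseases
  annotated <- c("D009203", "D002037")
  for (seed in 1:100) {
    neg <- make_negative_samples(d, 2, generation_config(seed = seed))
    expect_equal(nrow(neg), 2)
    expect_identical(unique(neg$id1), "D003042")
    expect_true(all(neg$id2 %in% pool))
    expect_false(any(neg$id2 %in% annotated))
    expect_false(any(duplicated(paste(neg$id1, neg$id2))))
    again <- make_negative_samples(d, 2, generation_config(seed = seed))
    expect_identical(neg, again)
  }
})

test_that("a zero negative ratio yields no negatives and a short pool warns", {
  d <- fixture_1601297()
  expect_equal(nrow(make_negative_samples(d, 2, generation_config(neg_per_pos = 0))), 0)
  expect_warning(
    neg <- make_negative_samples(d, 5, generation_config(neg_per_pos = 2)),
    "pool")
  expect_equal(nrow(neg), 3) # entire pool emitted
})

test_that("corpus-wide generation is balanced when pools suffice", {
  docs <- tiny_docs(n = 25, seed = 3)
  samples <- suppressWarnings(generate_samples(docs, generation_config(seed = 3)))
  per_doc <- split(samples$label, samples$doc_id)
  for (lb in per_doc) {
    # per-document balance whenever the pool was large enough
    if (sum(lb == "0") == sum(lb == "1")) succeed() else {
      expect_lt(sum(lb == "0"), sum(lb == "1"))
    }
  }
  # soundness: no emitted negative pair is annotated in its document
  by_id <- setNames(docs, vapply(docs, `[[`, "", "doc_id"))
  neg <- samples[samples$label == "0", ]
  for (i in seq_len(nrow(neg))) {
    rel <- by_id[[neg$doc_id[i]]]$relations
    key <- paste(pmin(rel$id1, rel$id2), pmax(rel$id1, rel$id2))
    expect_false(paste(pmin(neg$id1[i], neg$id2[i]),
                       pmax(neg$id1[i], neg$id2[i])) %in% key)
  }
})

test_that("co-occurrence filtering keeps exactly the planted subset with first-match context", {
  lit <- c("nothing to see here",
           "ginseng helps with diabetes in this study",
           "ginseng and diabetes appear again",
           "astragalus mentioned alone")
  inst <- relation_instances(
    instance_id = c("1", "2", "3"),
    name1 = c("ginseng", "astragalus", "Ginseng"),
    id1 = c("H1", "H2", "H1"),
    name2 = c("diabetes", "nephritis", "DIABETES"),
    id2 = c("D1", "D2", "D1"),
    label = c("1", "0", "1"),
    context = c("", "", ""))
  expect_message(out <- attach_context_by_cooccurrence(inst, lit), "kept 2 of 3")
  expect_equal(out$instance_id, c("1", "3"))
  # first matching abstract in file order supplies the context
  expect_identical(unique(out$context), lit[2])
  expect_equal(attr(out, "dropped"), 1)
})

test_that("multi-class instances pass through with a fixed sorted label set", {
  labs <- c("BEFORE", "AFTER", "SIMULTANEOUS", "OVERLAP", "BEGUN_BY",
            "ENDED_BY", "DURING", "BEFORE_OVERLAP")
  set.seed(5)
  n <- 80
  inst <- relation_instances(
    instance_id = sprintf("i%d", 1:n),
    name1 = "admission", id1 = sprintf("E%d", 1:n),
    name2 = "this morning", id2 = sprintf("T%d", 1:n),
    label = sample(labs, n, TRUE),
    context = "the patient was admitted this morning .")
  out <- to_multiclass_instances(inst)
  expect_equal(nrow(out), n)
  expect_identical(attr(out, "label_set"), sort(labs))
  expect_equal(table(out$label), table(inst$label))
  one <- to_multiclass_instances(inst[1, ])
  expect_equal(nrow(one), 1)
})
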