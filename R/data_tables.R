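# Published corpus summary tables shipped with the package.

#' Clinical temporal-relation corpus summary
#'
#' Per-category annotated temporal-relation counts of the 2012 i2b2
#' discharge-summary challenge corpus (training and test splits), including
#' the published totals row. Eight relation categories are defined
#' (BEFORE, AFTER, SIMULTANEOUS, OVERLAP, BEGUN_BY, ENDED_BY, DURING,
#' BEFORE_OVERLAP).
#'
#' @return data.frame with columns `relation_type`, `training`, `test`.
#' @export
i2b2_temporal_summary <- function() {
  path <- system.file("extdata", "i2b2_temporal_summary.tsv",
                      package = "medrex", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Mean labeled relations per category
#'
#' Total annotated training relations divided by the number of relation
#' categories — the corpus-size statistic used to argue that even the
#' largest of the three corpora falls short of the ~5000 labeled samples
#' per category a deep classifier typically needs.
#'
#' @param summary the table from [i2b2_temporal_summary].
#' @return numeric scalar.
#' @export
mean_relations_per_category <- function(summary = i2b2_temporal_summary()) {
  categories <- setdiff(summary$relation_type,
                        c("Temporal relations", "Unlabeled"))
  total <- summary$training[summary$relation_type == "Temporal relations"]
  total / length(categories)
}

#' The sub-word segmentation example vocabulary
#'
#' The miniature WordPiece vocabulary for the worked segmentation example:
#' the five specials plus the pieces needed to split "suxamethonium" into
#' su, ##xa, ##met, ##hon, ##ium.
#'
#' @return a [wordpiece_vocab].
#' @export
example_vocab <- function() {
  read_vocab(system.file("extdata", "example_vocab.txt", package = "medrex",
                         mustWork = TRUE))
}
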