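# Precision / recall / F1 evaluation with one-vs-rest confusion counts and
# micro averaging for multi-class tasks.

#' One-vs-rest confusion counts per class
#'
#' @param gold,pred equal-length label vectors drawn from `label_set`.
#' @param label_set the declared label set; defaults to the labels observed
#'   in `gold` and `pred`.
#' @return data.frame with columns `label`, `tp`, `fp`, `fn`, `support`.
#' @export
confusion <- function(gold, pred, label_set = NULL) {
  if (length(gold) != length(pred)) {
    stop(sprintf("gold (%d) and pred (%d) differ in length",
                 length(gold), length(pred)), call. = FALSE)
  }
  if (is.null(label_set)) label_set <- sort(unique(c(gold, pred)))
  bad <- setdiff(unique(c(gold, pred)), label_set)
  if (length(bad)) {
    stop("labels outside the declared label set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    label = label_set,
    tp = vapply(label_set, function(l) sum(gold == l & pred == l), numeric(1)),
    fp = vapply(label_set, function(l) sum(gold != l & pred == l), numeric(1)),
    fn = vapply(label_set, function(l) sum(gold == l & pred != l), numeric(1)),
    support = vapply(label_set, function(l) sum(gold == l), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

prf_one <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(precision = p, recall = r, f1 = f)
}

#' Per-class precision, recall and F1
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`, with
#' the 0/0 cases defined as 0.
#'
#' @param counts a confusion-count data.frame from [confusion].
#' @return the same data.frame with `precision`, `recall` and `f1` columns.
#' @export
prf <- function(counts) {
  m <- t(mapply(prf_one, counts$tp, counts$fp, counts$fn))
  cbind(counts, as.data.frame(m))
}

#' Micro-averaged precision, recall and F1
#'
#' Pools TP/FP/FN across classes before applying the formulas; for a binary
#' single-class view this reduces to the positive-class scores.
#'
#' @param counts a confusion-count data.frame from [confusion].
#' @return named numeric vector `precision`, `recall`, `f1`.
#' @export
micro_average <- function(counts) {
  stopifnot(nrow(counts) >= 1)
  prf_one(sum(counts$tp), sum(counts$fp), sum(counts$fn))
}

#' Write an evaluation report as TSV
#'
#' One row per class (`label, tp, fp, fn, support, precision, recall, f1`)
#' plus a `micro` summary row.
#'
#' @param counts a confusion-count data.frame from [confusion].
#' @param path optional output file.
#' @return the report data.frame, invisibly when `path` is given.
#' @export
eval_report <- function(counts, path = NULL) {
  per <- prf(counts)
  mi <- micro_average(counts)
  rep_ <- rbind(per, data.frame(label = "micro", tp = sum(per$tp),
                                fp = sum(per$fp), fn = sum(per$fn),
                                support = sum(per$support),
                                precision = mi[["precision"]],
                                recall = mi[["recall"]], f1 = mi[["f1"]]))
  if (!is.null(path)) {
    utils::write.table(rep_, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(rep_))
  }
  rep_
}
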