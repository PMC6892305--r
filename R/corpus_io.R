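# PubTator corpus IO, tab-delimited relation tables, and the canonical
# relation-instance interchange format.

#' Construct a document record
#'
#' A document record is one annotated abstract: a title, an abstract, typed
#' entity mentions anchored by character offsets, and abstract-level relation
#' annotations between concept identifiers (e.g. MeSH IDs). Offsets are
#' 0-based, end-exclusive, and are interpreted against
#' `paste(title, abstract)` (title and abstract joined by one space).
#'
#' @param doc_id document identifier (e.g. a PMID).
#' @param title title text.
#' @param abstract abstract text.
#' @param mentions data.frame with columns `start`, `end`, `surface`,
#'   `etype`, `concept_id`.
#' @param relations data.frame with columns `rtype`, `id1`, `id2`.
#' @param validate check mention offsets against the document text.
#' @return an object of class `document_record`.
#' @export
document_record <- function(doc_id, title, abstract,
                            mentions = empty_mentions(),
                            relations = empty_relations(),
                            validate = TRUE) {
  doc <- structure(
    list(doc_id = as.character(doc_id), title = title, abstract = abstract,
         mentions = mentions, relations = relations),
    class = "document_record"
  )
  if (validate) validate_document(doc)
  doc
}

empty_mentions <- function() {
  data.frame(start = integer(), end = integer(), surface = character(),
             etype = character(), concept_id = character(),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(rtype = character(), id1 = character(), id2 = character(),
             stringsAsFactors = FALSE)
}

#' Document context text
#'
#' The text a document's offsets refer to: title and abstract joined by a
#' single space. This is also the "second sentence" used when encoding an
#' entity pair against its context.
#'
#' @param doc a `document_record`.
#' @return character scalar.
#' @export
doc_text <- function(doc) paste(doc$title, doc$abstract)

#' Validate a document record
#'
#' Checks that every mention's span lies inside the document text, that
#' `end - start` equals the surface length, and that the text at the span
#' equals the recorded surface up to case folding (annotation tables
#' sometimes capitalize surfaces independently of the running text).
#' Relations must have nonempty types and identifiers.
#'
#' @param doc a `document_record`.
#' @return `doc`, invisibly; signals an error naming the offending mention.
#' @export
validate_document <- function(doc) {
  txt <- doc_text(doc)
  m <- doc$mentions
  if (nrow(m)) {
    if (any(bad <- !(m$start >= 0 & m$start < m$end))) {
      stop(sprintf("document %s: mention '%s' has invalid span [%d,%d)",
                   doc$doc_id, m$surface[bad][1], m$start[bad][1], m$end[bad][1]),
           call. = FALSE)
    }
    if (any(bad <- m$end > nchar(txt))) {
      stop(sprintf("document %s: mention '%s' ends at %d beyond text length %d",
                   doc$doc_id, m$surface[bad][1], m$end[bad][1], nchar(txt)),
           call. = FALSE)
    }
    if (any(bad <- (m$end - m$start) != nchar(m$surface))) {
      stop(sprintf("document %s: mention '%s' span [%d,%d) does not match its surface length",
                   doc$doc_id, m$surface[bad][1], m$start[bad][1], m$end[bad][1]),
           call. = FALSE)
    }
    at <- substring(txt, m$start + 1L, m$end)
    if (any(bad <- tolower(at) != tolower(m$surface))) {
      stop(sprintf(
        "document %s: mention '%s' at [%d,%d) disagrees with text '%s'",
        doc$doc_id, m$surface[bad][1], m$start[bad][1], m$end[bad][1], at[bad][1]),
        call. = FALSE)
    }
    if (any(m$etype == "")) {
      stop(sprintf("document %s: mention with empty entity type", doc$doc_id),
           call. = FALSE)
    }
  }
  r <- doc$relations
  if (nrow(r) && any(r$rtype == "" | r$id1 == "" | r$id2 == "")) {
    stop(sprintf("document %s: relation with empty field", doc$doc_id),
         call. = FALSE)
  }
  invisible(doc)
}

#' @export
print.document_record <- function(x, ...) {
  cat(sprintf("<document_record %s>\n", x$doc_id))
  cat(sprintf("  title:    %s\n", substr(x$title, 1, 70)))
  cat(sprintf("  abstract: %d chars\n", nchar(x$abstract)))
  cat(sprintf("  mentions: %d   relations: %d\n",
              nrow(x$mentions), nrow(x$relations)))
  invisible(x)
}

as_lines <- function(src) {
  if (is.character(src) && length(src) == 1L && !grepl("\n", src) &&
      file.exists(src)) {
    readLines(src, encoding = "UTF-8", warn = FALSE)
  } else if (is.character(src)) {
    if (any(grepl("\n", src, fixed = TRUE))) {
      # split embedded newlines while preserving blank lines
      strsplit(paste(src, collapse = "\n"), "\n", fixed = TRUE)[[1]]
    } else {
      src
    }
  } else if (inherits(src, "connection")) {
    readLines(src, encoding = "UTF-8", warn = FALSE)
  } else {
    stop("expected a file path, character lines, or a connection",
         call. = FALSE)
  }
}

#' Read a PubTator-format corpus
#'
#' PubTator is the tab-delimited interchange format used by the BioCreative
#' chemical-disease relation corpora: per document, a `pid|t|title` line, a
#' `pid|a|abstract` line, 6-field tab-delimited mention lines
#' (`pid, start, end, surface, type, concept id`) and 4-field relation lines
#' (`pid, type, id1, id2`), with a blank line between documents.
#'
#' @param src a file path, a character vector of lines, or a connection.
#' @param validate check mention offsets against the reconstructed text.
#' @return a list of [document_record]s, in input order.
#' @export
read_pubtator <- function(src, validate = TRUE) {
  lines <- as_lines(src)
  docs <- list()
  cur <- NULL
  flush_doc <- function(cur) {
    if (is.null(cur)) return(NULL)
    document_record(cur$pid, cur$title %||% "", cur$abstract %||% "",
                    do.call(rbind_df, list(cur$mentions, empty_mentions())),
                    do.call(rbind_df, list(cur$relations, empty_relations())),
                    validate = validate)
  }
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (line == "") {
      d <- flush_doc(cur)
      if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      cur <- NULL
      next
    }
    ta <- regmatches(line, regexec("^([^|\t]+)\\|([ta])\\|(.*)$", line))[[1]]
    if (length(ta) == 4L) {
      pid <- ta[2]
      if (is.null(cur)) cur <- list(pid = pid, mentions = list(), relations = list())
      if (pid != cur$pid) {
        stop_line(i, sprintf("document id %s differs from current document %s",
                             pid, cur$pid))
      }
      if (ta[3] == "t") cur$title <- ta[4] else cur$abstract <- ta[4]
      next
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    # the printed BC5CDR records carry trailing empty fields on relation
    # lines; drop them before deciding the line kind
    while (length(fields) > 4L && fields[length(fields)] == "") {
      fields <- fields[-length(fields)]
    }
    if (is.null(cur)) {
      stop_line(i, "annotation line before any title/abstract line")
    }
    if (length(fields) == 6L) {
      if (fields[1] != cur$pid) {
        stop_line(i, sprintf("mention document id %s differs from %s",
                             fields[1], cur$pid))
      }
      st <- suppressWarnings(as.integer(fields[2]))
      en <- suppressWarnings(as.integer(fields[3]))
      if (is.na(st) || is.na(en)) stop_line(i, "non-integer mention offsets")
      cur$mentions[[length(cur$mentions) + 1L]] <- data.frame(
        start = st, end = en, surface = fields[4], etype = fields[5],
        concept_id = fields[6], stringsAsFactors = FALSE)
    } else if (length(fields) == 4L) {
      if (fields[1] != cur$pid) {
        stop_line(i, sprintf("relation document id %s differs from %s",
                             fields[1], cur$pid))
      }
      cur$relations[[length(cur$relations) + 1L]] <- data.frame(
        rtype = fields[2], id1 = fields[3], id2 = fields[4],
        stringsAsFactors = FALSE)
    } else {
      stop_line(i, sprintf(
        "malformed annotation line with %d tab-separated fields (expected 6 for a mention or 4 for a relation)",
        length(fields)))
    }
  }
  d <- flush_doc(cur)
  if (!is.null(d)) docs[[length(docs) + 1L]] <- d
  docs
}

rbind_df <- function(parts, empty) {
  if (is.data.frame(parts)) return(parts)
  parts <- Filter(function(p) is.data.frame(p) && nrow(p) > 0, parts)
  if (!length(parts)) return(empty)
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Write documents in PubTator format
#'
#' The canonical serialization: title line, abstract line, mention lines
#' sorted by start offset, relation lines in stored order, one blank line
#' after each document. Records are validated before any output is produced.
#'
#' @param docs a list of [document_record]s (or a single one).
#' @param path optional output file; when `NULL` the lines are returned.
#' @return the character lines, invisibly when `path` is given.
#' @export
write_pubtator <- function(docs, path = NULL) {
  if (inherits(docs, "document_record")) docs <- list(docs)
  for (d in docs) validate_document(d)
  out <- character()
  for (d in docs) {
    lines <- c(sprintf("%s|t|%s", d$doc_id, d$title),
               sprintf("%s|a|%s", d$doc_id, d$abstract))
    m <- d$mentions
    if (nrow(m)) {
      m <- m[order(m$start, m$end), , drop = FALSE]
      lines <- c(lines, sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                                d$doc_id, m$start, m$end, m$surface,
                                m$etype, m$concept_id))
    }
    r <- d$relations
    if (nrow(r)) {
      lines <- c(lines, sprintf("%s\t%s\t%s\t%s", d$doc_id, r$rtype, r$id1, r$id2))
    }
    out <- c(out, lines, "")
  }
  if (is.null(path)) return(out)
  writeLines(out, path, useBytes = TRUE)
  invisible(out)
}

instance_columns <- c("instance_id", "name1", "id1", "name2", "id2",
                      "label", "context")

#' Construct a table of relation instances
#'
#' The canonical classification unit: two named, identified entities, a
#' label (binary "0"/"1" or a multi-class relation name), and the context
#' text the pair co-occurred in.
#'
#' @param instance_id,name1,id1,name2,id2,label,context column vectors.
#' @return a data.frame with the canonical seven columns.
#' @export
relation_instances <- function(instance_id = character(), name1 = character(),
                               id1 = character(), name2 = character(),
                               id2 = character(), label = character(),
                               context = character()) {
  data.frame(instance_id = as.character(instance_id),
             name1 = as.character(name1), id1 = as.character(id1),
             name2 = as.character(name2), id2 = as.character(id2),
             label = as.character(label), context = as.character(context),
             stringsAsFactors = FALSE)
}

#' Read/write the canonical relation-instance TSV
#'
#' Seven tab-separated columns with a header row:
#' `instance_id, name1, id1, name2, id2, label, context`. The context is the
#' last column; embedded tabs or newlines are forbidden so the format stays
#' a plain line-per-instance TSV.
#'
#' @param src file path, character lines, or a connection.
#' @return a data.frame of relation instances.
#' @export
read_instances_tsv <- function(src) {
  lines <- as_lines(src)
  if (!length(lines)) return(relation_instances())
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, instance_columns)) {
    stop(sprintf("expected header '%s'", paste(instance_columns, collapse = "\\t")),
         call. = FALSE)
  }
  body <- lines[-1]
  body <- body[body != ""]
  if (!length(body)) return(relation_instances())
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 7L)) {
    bad <- which(nf != 7L)[1]
    stop_line(bad + 1L, sprintf("expected 7 tab-separated fields, found %d", nf[bad]))
  }
  mat <- matrix(unlist(parts), ncol = 7L, byrow = TRUE)
  do.call(relation_instances, setNames(asplit(mat, 2), instance_columns))
}

#' @rdname read_instances_tsv
#' @param instances data.frame of relation instances.
#' @param path optional output file.
#' @export
write_instances_tsv <- function(instances, path = NULL) {
  stopifnot(all(instance_columns %in% names(instances)))
  instances <- instances[instance_columns]
  for (col in instance_columns) {
    v <- instances[[col]]
    if (any(grepl("[\t\n\r]", v))) {
      stop(sprintf(
        "column '%s' contains an embedded tab or newline; replace control characters (e.g. with a space) before writing",
        col), call. = FALSE)
    }
  }
  lines <- c(paste(instance_columns, collapse = "\t"),
             do.call(paste, c(unname(as.list(instances)), sep = "\t")))
  if (is.null(path)) return(lines)
  writeLines(lines, path, useBytes = TRUE)
  invisible(lines)
}

#' Read a tab-delimited relation table (TCM style)
#'
#' Six tab-separated fields per line, no header:
#' `ID, EntityID1, EntityName1, EntityID2, EntityName2, Label`. The
#' literature the relations were annotated against lives in a separate file
#' (see [read_tcm_literature]); the returned instances therefore carry an
#' empty context, to be filled by [attach_context_by_cooccurrence].
#'
#' @param src file path, character lines, or a connection.
#' @return a data.frame of relation instances with empty `context`.
#' @export
read_tcm_table <- function(src) {
  lines <- as_lines(src)
  lines <- lines[lines != ""]
  if (!length(lines)) return(relation_instances())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 6L)) {
    bad <- which(nf != 6L)[1]
    stop_line(bad, sprintf("expected 6 tab-separated fields, found %d", nf[bad]))
  }
  mat <- matrix(unlist(parts), ncol = 6L, byrow = TRUE)
  relation_instances(instance_id = mat[, 1], id1 = mat[, 2], name1 = mat[, 3],
                     id2 = mat[, 4], name2 = mat[, 5], label = mat[, 6],
                     context = rep("", nrow(mat)))
}

#' Read a literature file: one abstract per line
#'
#' @param src file path, character lines, or a connection.
#' @return character vector of abstracts, in file order.
#' @export
read_tcm_literature <- function(src) {
  lines <- as_lines(src)
  lines[lines != ""]
}
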