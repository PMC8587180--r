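# Labeled and unlabeled document corpora.
#
# A corpus is a data frame of documents bound to a taxonomy and a mode tag:
#   D      - category descriptions, exactly 1 label per document
#   E      - example questions, 1-3 labels per document
#   DplusE - fusion of a D and an E corpus (source tags retained)
#   query  - texts to classify; 0-3 gold labels (0 = unlabeled /
#            no corresponding category)

CORPUS_MODES <- c("D", "E", "DplusE", "query")

#' Construct a corpus
#'
#' @param doc_id Character vector of unique document ids.
#' @param text Character vector of document texts.
#' @param labels List of character vectors of category codes (0-3 each;
#'   order preserved as given).
#' @param taxonomy A `cpc_taxonomy`; every label must resolve in it.
#' @param mode One of `"D"`, `"E"`, `"DplusE"`, `"query"`.
#' @param source Character vector tagging each document `"description"` or
#'   `"example"` (defaults by mode; `NA` for queries).
#' @return A `cpc_corpus` data frame with columns `doc_id`, `text`, `labels`
#'   (list column), `source`, and attributes `taxonomy` and `mode`.
#' @export
corpus <- function(doc_id, text, labels, taxonomy, mode,
                   source = NULL) {
  mode <- match.arg(mode, CORPUS_MODES)
  doc_id <- as.character(doc_id)
  text <- as.character(text)
  stopifnot(length(doc_id) == length(text), length(labels) == length(text))
  if (anyDuplicated(doc_id)) {
    stop("duplicate doc_ids: ",
         paste(unique(doc_id[duplicated(doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  labels <- lapply(labels, function(l) {
    if (length(l) == 0) character() else normalize_code(l)
  })
  nlab <- lengths(labels)
  if (any(nlab > 3)) {
    stop("documents with more than 3 labels: ",
         paste(doc_id[nlab > 3], collapse = ", "), call. = FALSE)
  }
  if (mode != "query" && any(nlab < 1)) {
    stop("unlabeled documents are only allowed in query corpora: ",
         paste(doc_id[nlab < 1], collapse = ", "), call. = FALSE)
  }
  if (mode == "D" && any(nlab != 1)) {
    stop("description documents must carry exactly 1 label", call. = FALSE)
  }
  all_labels <- unique(unlist(labels, use.names = FALSE))
  unknown <- setdiff(all_labels, taxonomy$code)
  if (length(unknown)) {
    stop("labels not in taxonomy: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(source)) {
    source <- switch(mode,
                     D = rep("description", length(doc_id)),
                     E = rep("example", length(doc_id)),
                     rep(NA_character_, length(doc_id)))
  }
  out <- data.frame(doc_id = doc_id, text = text, stringsAsFactors = FALSE)
  out$labels <- labels
  out$source <- as.character(source)
  attr(out, "taxonomy") <- taxonomy
  attr(out, "mode") <- mode
  class(out) <- c("cpc_corpus", "data.frame")
  out
}

corpus_mode <- function(x) attr(x, "mode")
corpus_taxonomy <- function(x) attr(x, "taxonomy")

#' @export
print.cpc_corpus <- function(x, ...) {
  nlab <- lengths(x$labels)
  cat("<cpc_corpus> mode=", corpus_mode(x), ", ", nrow(x), " docs (",
      sum(nlab > 0), " labeled)\n", sep = "")
  if (nrow(x)) {
    show <- utils::head(data.frame(
      doc_id = x$doc_id,
      labels = vapply(x$labels, paste, character(1), collapse = ";"),
      text = substr(x$text, 1, 40)), 6)
    print.data.frame(show)
    if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more rows\n", sep = "")
  }
  invisible(x)
}

#' Subset a corpus, keeping its metadata
#'
#' @param x A `cpc_corpus`.
#' @param i Row index.
#' @return A `cpc_corpus` with the same taxonomy and mode.
#' @export
corpus_subset <- function(x, i) {
  out <- as.data.frame(x)[i, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "taxonomy") <- corpus_taxonomy(x)
  attr(out, "mode") <- corpus_mode(x)
  class(out) <- c("cpc_corpus", "data.frame")
  out
}

#' Read a corpus file
#'
#' TSV rows are `doc_id<TAB>labels<TAB>text` with labels ";"-separated
#' (possibly empty); JSONL rows are objects with keys `doc_id`, `labels`
#' (list), `text` and optionally `source`. Unlabeled rows are rejected unless
#' `mode = "query"`; more than 3 labels is always an error.
#'
#' @param path File path.
#' @param taxonomy A `cpc_taxonomy` that all labels must resolve in.
#' @param mode Corpus mode tag (see [corpus()]).
#' @param format `"tsv"` or `"jsonl"`.
#' @param header For TSV, whether the first row is a header.
#' @return A `cpc_corpus`.
#' @export
read_corpus <- function(path, taxonomy, mode = c("D", "E", "DplusE", "query"),
                        format = c("tsv", "jsonl"), header = FALSE) {
  mode <- match.arg(mode)
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  src <- NULL
  if (format == "tsv") {
    if (file.size(path) == 0) {
      return(corpus(character(), character(), list(), taxonomy, mode))
    }
    df <- utils::read.delim(path, header = header, sep = "\t", quote = "",
                            colClasses = "character", fileEncoding = "UTF-8")
    if (ncol(df) < 3) stop("corpus TSV needs (doc_id, labels, text): ", path,
                           call. = FALSE)
    ids <- df[[1]]
    labs <- lapply(strsplit(df[[2]], ";", fixed = TRUE),
                   function(l) l[nzchar(l)])
    texts <- df[[3]]
    if (ncol(df) >= 4) src <- df[[4]]
  } else {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      return(corpus(character(), character(), list(), taxonomy, mode))
    }
    recs <- lapply(lines, jsonlite::fromJSON)
    ids <- vapply(recs, function(r) as.character(r$doc_id), character(1))
    labs <- lapply(recs, function(r) as.character(unlist(r$labels)))
    texts <- vapply(recs, function(r) as.character(r$text), character(1))
    srcs <- vapply(recs, function(r) {
      if (is.null(r$source)) NA_character_ else as.character(r$source)
    }, character(1))
    if (!all(is.na(srcs))) src <- srcs
  }
  corpus(ids, texts, labs, taxonomy, mode, source = src)
}

#' Write a corpus file
#'
#' Inverse of [read_corpus()]; the canonical dialect (TSV, no header, no
#' trailing dots) round-trips byte-exactly.
#'
#' @param x A `cpc_corpus`.
#' @param path Output path.
#' @param format `"tsv"` or `"jsonl"`.
#' @param trailing_dot Emit label codes in the trailing-dot dialect.
#' @param source For TSV, write the source tag as a fourth column.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path, format = c("tsv", "jsonl"),
                         trailing_dot = FALSE, source = FALSE) {
  format <- match.arg(format)
  fmt_label <- function(l) {
    if (trailing_dot && length(l)) l <- paste0(l, ".")
    paste(l, collapse = ";")
  }
  if (format == "tsv") {
    labcol <- vapply(x$labels, fmt_label, character(1))
    lines <- paste(x$doc_id, labcol, x$text, sep = "\t")
    if (source) lines <- paste(lines, x$source, sep = "\t")
    writeLines(lines, path, useBytes = TRUE)
  } else {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      l <- x$labels[[i]]
      if (trailing_dot && length(l)) l <- paste0(l, ".")
      jsonlite::toJSON(list(doc_id = x$doc_id[i], labels = as.list(l),
                            text = x$text[i], source = x$source[i]),
                       auto_unbox = TRUE, null = "null", na = "null")
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Fuse a description corpus and an example corpus
#'
#' Concatenates a D corpus and an E corpus (D first) into a D+E reference
#' corpus, preserving document order, labels, and source tags. Colliding
#' doc_ids are disambiguated with a source prefix.
#'
#' @param d A `cpc_corpus` with mode `"D"`.
#' @param e A `cpc_corpus` with mode `"E"`.
#' @return A `cpc_corpus` with mode `"DplusE"` and `nrow(d) + nrow(e)` docs.
#' @export
fuse_corpora <- function(d, e) {
  if (corpus_mode(d) != "D" || corpus_mode(e) != "E") {
    stop("fuse_corpora() expects a D corpus and an E corpus", call. = FALSE)
  }
  if (!identical(corpus_taxonomy(d)$code, corpus_taxonomy(e)$code)) {
    stop("corpora are bound to different taxonomies", call. = FALSE)
  }
  ids_d <- d$doc_id
  ids_e <- e$doc_id
  clash <- intersect(ids_d, ids_e)
  if (length(clash)) {
    ids_d[ids_d %in% clash] <- paste0("D:", ids_d[ids_d %in% clash])
    ids_e[ids_e %in% clash] <- paste0("E:", ids_e[ids_e %in% clash])
  }
  corpus(c(ids_d, ids_e), c(d$text, e$text), c(d$labels, e$labels),
         corpus_taxonomy(d), "DplusE", source = c(d$source, e$source))
}
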