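# Cosine-similarity ranking against a reference index.
#
# STEP1: transform the query into a TF-IDF vector with the index's fitted
# model. STEP2: score every category as the maximum cosine over reference
# documents carrying that label, and return the top-k categories.

#' Cosine similarity between two weight vectors
#'
#' Vectors produced by [tfidf_transform()] are already unit-norm, so their
#' dot product is the cosine; this function nevertheless normalizes, so it is
#' safe on raw nonnegative weight vectors too. If either vector is zero the
#' similarity is 0.
#'
#' @param u,v Numeric (or sparse) vectors of equal length.
#' @return The cosine, in \[0, 1\] for nonnegative vectors.
#' @export
cosine_similarity <- function(u, v) {
  u <- as.numeric(u)
  v <- as.numeric(v)
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

#' Build a reference index
#'
#' Fits a TF-IDF model on the reference corpus (or reuses a supplied fitted
#' model) and stores the vectorized reference documents with their labels.
#'
#' @param reference A `cpc_corpus` with mode `"D"`, `"E"` or `"DplusE"`.
#' @param tokenizer Tokenizer contract used when fitting.
#' @param model Optional pre-fitted `tfidf_model`; when given, the index
#'   vectorizes with it instead of refitting (useful for comparing D / E /
#'   D+E scores in a shared vector space).
#' @return A `cpc_index`.
#' @export
build_index <- function(reference, tokenizer = default_tokenizer(),
                        model = NULL) {
  stopifnot(inherits(reference, "cpc_corpus"))
  if (corpus_mode(reference) == "query") {
    stop("cannot index a query corpus", call. = FALSE)
  }
  if (nrow(reference) == 0) stop("empty reference corpus", call. = FALSE)
  if (is.null(model)) model <- tfidf_fit(reference, tokenizer)
  X <- tfidf_transform(model, reference$text)
  nlab <- lengths(reference$labels)
  pairs <- data.frame(doc = rep(seq_len(nrow(reference)), nlab),
                      code = unlist(reference$labels, use.names = FALSE),
                      stringsAsFactors = FALSE)
  groups <- split(pairs$doc, pairs$code)
  codes <- names(groups)
  ord_key <- code_order_key(codes)
  structure(list(mode = corpus_mode(reference), X = X, model = model,
                 pairs = pairs, groups = groups, group_codes = codes,
                 group_order = ord_key, doc_ids = reference$doc_id,
                 labels = reference$labels,
                 taxonomy = corpus_taxonomy(reference)),
            class = "cpc_index")
}

#' @export
print.cpc_index <- function(x, ...) {
  cat("<cpc_index> mode=", x$mode, ", ", length(x$doc_ids), " reference docs, ",
      length(unique(x$pairs$code)), " categories, ",
      length(x$model$terms), " terms\n", sep = "")
  invisible(x)
}

# Rank categories for one precomputed similarity row. sims: numeric vector of
# per-reference-document cosines. Returns data.frame(code, score).
rank_from_sims <- function(index, sims, k, aggregate = "max") {
  agg <- if (aggregate == "mean") mean else max
  score <- vapply(index$groups, function(ix) agg(sims[ix]), numeric(1))
  pos <- score > 0
  if (!any(pos)) {
    return(data.frame(code = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  score <- score[pos]
  codes <- index$group_codes[pos]
  ord <- order(-score, index$group_order[pos])
  keep <- utils::head(ord, k)
  data.frame(code = codes[keep], score = unname(score[keep]),
             stringsAsFactors = FALSE)
}

# Integer rank of codes under the canonical code ordering (segment-numeric).
code_order_key <- function(codes) {
  u <- unique(codes)
  rank_u <- integer(length(u))
  rank_u[code_order(u)] <- seq_along(u)
  rank_u[match(codes, u)]
}

#' Rank categories for one query text
#'
#' Every category's score is the maximum cosine over reference documents
#' bearing that label (max-aggregation; see `aggregate = "mean"` for the
#' alternative). Ties are broken by ascending category code. A query that
#' vectorizes to zero — or overlaps no reference document — yields an empty
#' ranking rather than an arbitrary assignment.
#'
#' @param index A `cpc_index`.
#' @param text Query text (character scalar).
#' @param k Maximum ranking length (>= 1).
#' @param aggregate `"max"` (default) or `"mean"` cosine over a category's
#'   reference documents.
#' @return Data frame `(code, score)` with at most `k` rows, scores
#'   non-increasing.
#' @export
rank_categories <- function(index, text, k = 10L, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  q <- tfidf_transform(index$model, text)
  sims <- as.numeric(index$X %*% Matrix::t(q))
  rank_from_sims(index, sims, k, aggregate)
}

#' Classify a query corpus
#'
#' Applies [rank_categories()] to every query, in input order, with one
#' shared similarity computation. Deterministic: permuting the reference
#' corpus leaves every ranking unchanged.
#'
#' @param index A `cpc_index`.
#' @param queries A `cpc_corpus` with mode `"query"` (any corpus works; its
#'   texts are classified).
#' @param k Maximum ranking length per query.
#' @return A `cpc_predictions` object: long data frame
#'   `(query_id, rank, code, score)`; queries with empty rankings contribute
#'   no rows but are retained in `attr(, "query_ids")`.
#' @export
classify_corpus <- function(index, queries, k = 10L) {
  stopifnot(inherits(queries, "cpc_corpus"))
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  n <- nrow(queries)
  if (n == 0) {
    out <- data.frame(query_id = character(), rank = integer(),
                      code = character(), score = numeric(),
                      stringsAsFactors = FALSE)
    return(new_predictions(out, character(), index$mode, k))
  }
  Q <- tfidf_transform(index$model, queries$text)
  S <- as.matrix(Q %*% Matrix::t(index$X))   # n_queries x n_ref
  res <- vector("list", n)
  for (i in seq_len(n)) {
    r <- rank_from_sims(index, S[i, ], k)
    if (nrow(r)) {
      res[[i]] <- data.frame(query_id = queries$doc_id[i],
                             rank = seq_len(nrow(r)),
                             code = r$code, score = r$score,
                             stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(query_id = character(), rank = integer(),
                      code = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  new_predictions(out, queries$doc_id, index$mode, k)
}

new_predictions <- function(df, query_ids, mode, k) {
  attr(df, "query_ids") <- query_ids
  attr(df, "mode") <- mode
  attr(df, "k") <- k
  class(df) <- c("cpc_predictions", "data.frame")
  df
}

#' @export
print.cpc_predictions <- function(x, ...) {
  qids <- attr(x, "query_ids")
  cat("<cpc_predictions> ", length(qids), " queries (",
      length(unique(x$query_id)), " with nonempty rankings), k=",
      attr(x, "k"), ", mode=", attr(x, "mode"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat("... ", nrow(x) - 10, " more rows\n", sep = "")
  invisible(x)
}

#' Top-1 assignment per query
#'
#' @param predictions A `cpc_predictions`.
#' @return Named character vector, query_id -> top-1 code; queries with
#'   empty rankings are `NA`.
#' @export
top1_assignments <- function(predictions) {
  qids <- attr(predictions, "query_ids")
  top <- predictions[predictions$rank == 1L, ]
  out <- top$code[match(qids, top$query_id)]
  names(out) <- qids
  out
}

#' Write predictions to TSV or JSONL
#'
#' TSV: `query_id<TAB>rank<TAB>code<TAB>score`. JSONL: one object per query
#' with its full ranking. Scores are printed at full precision.
#'
#' @param predictions A `cpc_predictions`.
#' @param path Output path.
#' @param format `"tsv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, format = c("tsv", "jsonl")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- paste(predictions$query_id, predictions$rank, predictions$code,
                   format(predictions$score, digits = 17, trim = TRUE),
                   sep = "\t")
    writeLines(c("query_id\trank\tcode\tscore", lines), path, useBytes = TRUE)
  } else {
    qids <- attr(predictions, "query_ids")
    lines <- vapply(qids, function(q) {
      sub <- predictions[predictions$query_id == q, , drop = FALSE]
      jsonlite::toJSON(list(query_id = q,
                            ranking = lapply(seq_len(nrow(sub)), function(i) {
                              list(code = sub$code[i], score = sub$score[i])
                            })),
                       auto_unbox = TRUE, digits = NA)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Read predictions from the TSV written by [write_predictions()]
#'
#' @param path TSV path.
#' @param query_ids Optional full set of query ids (to retain queries with
#'   empty rankings); defaults to the ids present in the file.
#' @return A `cpc_predictions`.
#' @export
read_predictions <- function(path, query_ids = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = c("character", "integer", "character",
                                         "numeric"),
                          fileEncoding = "UTF-8")
  names(df) <- c("query_id", "rank", "code", "score")
  if (is.null(query_ids)) query_ids <- unique(df$query_id)
  new_predictions(df, query_ids, mode = NA_character_,
                  k = if (nrow(df)) max(df$rank) else 0L)
}
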