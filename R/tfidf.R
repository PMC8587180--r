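# TF-IDF vectorization.
#
# Conventions (the common "default" smooth-IDF setup):
#   tf(t, d)  = raw count of t in d
#   idf(t)    = ln((1 + N) / (1 + df(t))) + 1     (N = fitting-corpus size)
#   weight    = tf * idf, then L2-normalized per document
# The vocabulary keeps every term seen in >= 1 fitting document (no df
# pruning); column order is lexicographic (C locale) for determinism. A
# document whose tokens are all out-of-vocabulary maps to the zero vector.

#' Fit a TF-IDF model
#'
#' Learns the vocabulary, document frequencies and smoothed IDF weights from
#' a fitting corpus. Queries are later transformed with the fitted model;
#' they do not contribute to IDF statistics (see the package vignette for the
#' alternative) unless you refit on a fused corpus yourself.
#'
#' @param x A `cpc_corpus` or a character vector of texts.
#' @param tokenizer A tokenizer contract (default: [default_tokenizer()]).
#' @return A `tfidf_model`: list with `terms` (lexicographic), `df`, `idf`,
#'   `n_docs`, and the tokenizer.
#' @examples
#' m <- tfidf_fit(c("pain pain fever", "fever scan"))
#' m$idf  # pain 1.405465, fever 1, scan 1.405465
#' @export
tfidf_fit <- function(x, tokenizer = default_tokenizer()) {
  texts <- if (inherits(x, "cpc_corpus")) x$text else as.character(x)
  if (length(texts) == 0) stop("cannot fit on an empty corpus", call. = FALSE)
  toks <- lapply(texts, tokenizer$tokenize)
  if (all(lengths(toks) == 0)) {
    stop("every document tokenizes to nothing under tokenizer '",
         tokenizer$name, "'", call. = FALSE)
  }
  n_docs <- length(texts)
  per_doc_terms <- lapply(toks, unique)
  df_tab <- table(unlist(per_doc_terms, use.names = FALSE))
  terms <- sort(names(df_tab), method = "radix")
  df <- as.integer(df_tab[terms])
  idf <- log((1 + n_docs) / (1 + df)) + 1
  names(df) <- terms
  names(idf) <- terms
  structure(list(terms = terms, df = df, idf = idf, n_docs = n_docs,
                 tokenizer = tokenizer),
            class = "tfidf_model")
}

#' @export
print.tfidf_model <- function(x, ...) {
  cat("<tfidf_model> ", length(x$terms), " terms, fitted on ", x$n_docs,
      " docs (tokenizer: ", x$tokenizer$name, ")\n", sep = "")
  invisible(x)
}

#' Transform texts into L2-normalized TF-IDF vectors
#'
#' Out-of-vocabulary tokens are ignored. A document with no in-vocabulary
#' token (including the empty string and digit/symbol-only strings under the
#' default tokenizer) becomes a zero row.
#'
#' @param model A fitted `tfidf_model`.
#' @param texts Character vector, or a `cpc_corpus`.
#' @return A sparse `dgCMatrix`, one row per text, columns = `model$terms`;
#'   nonzero rows have unit L2 norm.
#' @export
tfidf_transform <- function(model, texts) {
  stopifnot(inherits(model, "tfidf_model"))
  if (inherits(texts, "cpc_corpus")) texts <- texts$text
  texts <- as.character(texts)
  n <- length(texts)
  V <- length(model$terms)
  ii <- vector("list", n)
  jj <- vector("list", n)
  xx <- vector("list", n)
  for (d in seq_len(n)) {
    toks <- model$tokenizer$tokenize(texts[d])
    j <- match(toks, model$terms)
    j <- j[!is.na(j)]
    if (!length(j)) next
    tf <- table(j)
    cols <- as.integer(names(tf))
    w <- as.numeric(tf) * model$idf[cols]
    w <- w / sqrt(sum(w^2))
    ii[[d]] <- rep.int(d, length(cols))
    jj[[d]] <- cols
    xx[[d]] <- w
  }
  Matrix::sparseMatrix(i = as.integer(unlist(ii)),
                       j = as.integer(unlist(jj)),
                       x = as.numeric(unlist(xx)),
                       dims = c(n, V),
                       dimnames = list(NULL, model$terms))
}

#' Serialize a fitted TF-IDF model to JSON
#'
#' Stores `n_docs`, the tokenizer name, and `(term, df, idf)` triples in
#' lexicographic order. [read_tfidf_model()] reproduces transforms
#' bit-identically provided the named tokenizer is registered.
#'
#' @param model A `tfidf_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tfidf_model <- function(model, path) {
  obj <- list(n_docs = model$n_docs,
              tokenizer = model$tokenizer$name,
              terms = data.frame(term = model$terms,
                                 df = unname(model$df),
                                 idf = unname(model$idf)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a serialized TF-IDF model
#'
#' @param path JSON path written by [write_tfidf_model()].
#' @return A `tfidf_model`; its tokenizer is resolved from the registry by
#'   name.
#' @export
read_tfidf_model <- function(path) {
  obj <- jsonlite::fromJSON(path)
  terms <- as.character(obj$terms$term)
  df <- as.integer(obj$terms$df)
  # recompute idf from the integer (N, df) rather than trusting decimal
  # serialization: guarantees bit-identical transforms after a round trip
  idf <- log((1 + as.integer(obj$n_docs)) / (1 + df)) + 1
  names(df) <- terms
  names(idf) <- terms
  structure(list(terms = terms, df = df, idf = idf,
                 n_docs = as.integer(obj$n_docs),
                 tokenizer = get_tokenizer(obj$tokenizer)),
            class = "tfidf_model")
}
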