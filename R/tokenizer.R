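# Tokenizer contract.
#
# A tokenizer is a named, deterministic function from text to an ordered token
# list. The default is language-agnostic: lowercase, split on non-word
# characters, drop tokens that carry no letter (pure digits, punctuation,
# symbols). Morphological analyzers (e.g. a Japanese part-of-speech tagger)
# plug in through `morphological_tokenizer()`, which enforces the
# content-word contract: only nouns, verbs and adjectives survive.

.tokenizer_registry <- new.env(parent = emptyenv())

#' Register a tokenizer
#'
#' @param name Registry key.
#' @param tokenize Function `character(1) -> character()` returning the
#'   ordered token list. Must be deterministic.
#' @return The tokenizer contract (list with `name`, `tokenize`), invisibly.
#' @export
register_tokenizer <- function(name, tokenize) {
  stopifnot(is.character(name), length(name) == 1, is.function(tokenize))
  tk <- list(name = name, tokenize = tokenize)
  class(tk) <- "cpc_tokenizer"
  assign(name, tk, envir = .tokenizer_registry)
  invisible(tk)
}

#' Fetch a registered tokenizer by name
#'
#' @param name Registry key (`"default"` is always available).
#' @return A tokenizer contract.
#' @export
get_tokenizer <- function(name = "default") {
  if (!exists(name, envir = .tokenizer_registry, inherits = FALSE)) {
    stop("no tokenizer registered under '", name, "'", call. = FALSE)
  }
  get(name, envir = .tokenizer_registry, inherits = FALSE)
}

#' The default language-agnostic tokenizer
#'
#' Lowercases, splits on runs of non-word characters, and drops tokens that
#' contain no letter — so digit strings, punctuation and symbols never reach
#' the vectorizer. Tokens mixing letters and digits ("w0001") are kept.
#'
#' @return A tokenizer contract.
#' @examples
#' default_tokenizer()$tokenize("Pain, 37.5 fever -- CT scan!")
#' @export
default_tokenizer <- function() get_tokenizer("default")

tokenize_default <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  toks <- strsplit(tolower(text), "[^\\p{L}\\p{N}_]+", perl = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  toks[grepl("\\p{L}", toks, perl = TRUE)]
}

#' Wrap a part-of-speech analyzer as a tokenizer
#'
#' Adapter for morphological analyzers. `analyze` must return, for one text, a
#' data frame with columns `token` and `pos`; only content-word classes
#' (`keep_pos`, default nouns/verbs/adjectives) are retained, in order.
#' Casing is owned by the plug-in: tokens are passed through untouched.
#'
#' @param name Registry key for the wrapped tokenizer.
#' @param analyze Function `character(1) -> data.frame(token, pos)`.
#' @param keep_pos Part-of-speech tags to keep.
#' @return The registered tokenizer contract, invisibly.
#' @export
morphological_tokenizer <- function(name, analyze,
                                    keep_pos = c("noun", "verb", "adjective")) {
  stopifnot(is.function(analyze))
  register_tokenizer(name, function(text) {
    df <- analyze(text)
    stopifnot(all(c("token", "pos") %in% names(df)))
    as.character(df$token[df$pos %in% keep_pos])
  })
}

.onLoad <- function(libname, pkgname) {
  register_tokenizer("default", tokenize_default)
}
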