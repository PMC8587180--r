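# Independent oracles and fixture builders, kept deliberately naive: dense
# matrices, explicit loops, no shared code with the package internals.

ws_tokenize <- function(text) {
  toks <- strsplit(text, "[ \t]+")[[1]]
  toks[nzchar(toks)]
}

# Dense reference TF-IDF: raw counts, idf = ln((1+N)/(1+df)) + 1, L2 rows.
# Returns list(terms, idf, weights) with weights a dense doc x term matrix.
oracle_tfidf <- function(texts, tokenize = ws_tokenize) {
  toks <- lapply(texts, tokenize)
  terms <- sort(unique(unlist(toks)), method = "radix")
  N <- length(texts)
  counts <- matrix(0, N, length(terms), dimnames = list(NULL, terms))
  for (d in seq_len(N)) {
    for (t in toks[[d]]) counts[d, t] <- counts[d, t] + 1
  }
  df <- colSums(counts > 0)
  idf <- log((1 + N) / (1 + df)) + 1
  w <- sweep(counts, 2, idf, `*`)
  nrm <- sqrt(rowSums(w^2))
  nrm[nrm == 0] <- 1
  list(terms = terms, idf = idf, weights = w / nrm)
}

# Transform one text with a fitted oracle model (OOV dropped, L2 norm).
oracle_vec <- function(text, model, tokenize = ws_tokenize) {
  v <- setNames(numeric(length(model$terms)), model$terms)
  for (t in tokenize(text)) {
    if (t %in% model$terms) v[t] <- v[t] + 1
  }
  v <- v * model$idf
  n <- sqrt(sum(v^2))
  if (n > 0) v / n else v
}

oracle_cosine <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) return(0)
  sum(u * v) / (nu * nv)
}

# Exhaustive category ranking: per category the max cosine over reference
# docs carrying the label; positive scores only; ties by ascending code
# (numeric by segment), computed without the package's helpers.
oracle_rank <- function(ref_texts, ref_labels, query_text, k,
                        tokenize = ws_tokenize) {
  model <- oracle_tfidf(ref_texts, tokenize)
  qv <- oracle_vec(query_text, model, tokenize)
  codes <- unique(unlist(ref_labels))
  scores <- sapply(codes, function(code) {
    docs <- which(vapply(ref_labels, function(l) code %in% l, logical(1)))
    max(vapply(docs, function(d) oracle_cosine(model$weights[d, ], qv),
               numeric(1)))
  })
  keep <- scores > 0
  if (!any(keep)) {
    return(data.frame(code = character(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  codes <- codes[keep]; scores <- scores[keep]
  pad <- vapply(strsplit(codes, ".", fixed = TRUE), function(s) {
    paste(sprintf("%06d", as.integer(c(s, rep(0, 4 - length(s))))),
          collapse = ".")
  }, character(1))
  ord <- order(-scores, pad)
  head(data.frame(code = codes[ord], score = unname(scores[ord]),
                  stringsAsFactors = FALSE), k)
}

# Random toy corpus over a small vocabulary; returns a character vector.
random_texts <- function(n_docs, vocab = sprintf("t%02d", 1:10),
                         max_len = 8) {
  vapply(seq_len(n_docs), function(i) {
    paste(sample(vocab, sample.int(max_len, 1), replace = TRUE),
          collapse = " ")
  }, character(1))
}

# Tiny taxonomy + corpora fixture with fully distinctive category wording.
toy_setup <- function() {
  tax <- taxonomy(
    c("1", "2", "3", "1.1.1.1", "1.1.1.2", "2.1.1.1", "3.1.1.1"),
    c("care access", "symptoms", "anxiety", "hospital choice",
      "information gaps", "pain and fever", "fear of recurrence"))
  d <- corpus(paste0("d", 1:4),
              c("choosing hospital doctor", "information knowledge gap",
                "pain fever symptom", "fear recurrence anxiety"),
              list("1.1.1.1", "1.1.1.2", "2.1.1.1", "3.1.1.1"),
              tax, "D")
  e <- corpus(paste0("e", 1:6),
              c("which hospital should i pick doctor",
                "no information about my illness knowledge",
                "strong pain and high fever",
                "afraid the cancer comes back recurrence",
                "pain fever and fear together",
                "doctor hospital information"),
              list("1.1.1.1", "1.1.1.2", "2.1.1.1", "3.1.1.1",
                   c("2.1.1.1", "3.1.1.1"), c("1.1.1.1", "1.1.1.2")),
              tax, "E")
  q <- corpus(paste0("q", 1:4),
              c("hospital doctor choice", "fever pain",
                "recurrence fear", "0477 12.5 !!"),
              list("1.1.1.1", "2.1.1.1", "3.1.1.1", character()),
              tax, "query")
  list(tax = tax, d = d, e = e, q = q)
}

# Whitespace tokenizer registered once for oracle-comparison tests.
register_tokenizer("ws", ws_tokenize)
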