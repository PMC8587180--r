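# Evaluation protocol: multi-label hit@k / Acc@k, k-fold cross-validation,
# and Jensen-Shannon divergence between category distributions.
#
# Hit rule: a prediction is correct at k if at least one of the query's (up
# to 3) gold categories appears among the k highest-scoring predicted
# categories. Acc@k is the fraction of labeled queries with a hit; queries
# with an empty gold set are excluded from the denominator.

#' Hit test at rank k
#'
#' @param predicted Character vector of predicted codes, best first.
#' @param gold Character vector of 1-3 gold codes.
#' @param k Cutoff rank.
#' @return `TRUE` iff the top-k predictions intersect the gold set.
#' @export
hit_at_k <- function(predicted, gold, k) {
  if (length(gold) < 1) {
    stop("empty gold set; filter unlabeled queries before scoring",
         call. = FALSE)
  }
  length(intersect(utils::head(predicted, k), gold)) > 0
}

# Acc@k for each k, from a predictions object and the gold labels of the
# labeled queries. Returns named numeric vector (one entry per k).
accuracy_from_predictions <- function(predictions, queries, ks) {
  labeled <- lengths(queries$labels) > 0
  if (!any(labeled)) stop("no labeled queries to evaluate", call. = FALSE)
  ids <- queries$doc_id[labeled]
  gold <- queries$labels[labeled]
  pred_by_q <- split(predictions$code[order(predictions$rank)],
                     predictions$query_id[order(predictions$rank)])
  out <- vapply(ks, function(k) {
    hits <- vapply(seq_along(ids), function(i) {
      p <- pred_by_q[[ids[i]]]
      if (is.null(p)) FALSE else hit_at_k(p, gold[[i]], k)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  names(out) <- paste0("acc@", ks)
  out
}

#' Top-k accuracy of an index on a labeled query corpus
#'
#' @param queries A `cpc_corpus` containing at least one labeled document;
#'   unlabeled documents are ignored.
#' @param index A `cpc_index`.
#' @param k Cutoff rank (scalar or vector).
#' @return Named numeric vector of Acc@k values in \[0, 1\].
#' @export
accuracy_at_k <- function(queries, index, k = c(1L, 10L)) {
  preds <- classify_corpus(index, queries, k = max(k))
  accuracy_from_predictions(preds, queries, ks = k)
}

#' Single-pass evaluation against a description index
#'
#' The description-based method needs no cross-validation: the full
#' description corpus is the index and every labeled query is scored once.
#' No SD or median is reported.
#'
#' @param queries Labeled `cpc_corpus`.
#' @param d Either a `cpc_index` or a `cpc_corpus` with mode `"D"` (indexed
#'   on the fly).
#' @param k Cutoff ranks.
#' @param tokenizer Tokenizer used when `d` is a corpus.
#' @return Named numeric vector of Acc@k values.
#' @export
evaluate_d_based <- function(queries, d, k = c(1L, 10L),
                             tokenizer = default_tokenizer()) {
  index <- if (inherits(d, "cpc_index")) d else build_index(d, tokenizer)
  accuracy_at_k(queries, index, k = k)
}

#' k-fold cross-validation of the example-based or fused classifier
#'
#' The labeled example corpus is shuffled with the given seed and split into
#' `folds` near-equal parts (sizes differ by at most 1). Per fold, the
#' reference index is fitted on the training folds — plus the full
#' description corpus when `mode = "DplusE"` — and Acc@k is computed on the
#' held-out fold. Per-fold accuracies are aggregated as mean, median and
#' unbiased (n-1) sample SD.
#'
#' @param labeled A `cpc_corpus` of labeled examples (mode `"E"`).
#' @param d_corpus A `cpc_corpus` with mode `"D"`, required when
#'   `mode = "DplusE"`.
#' @param folds Number of folds (>= 2; default 5).
#' @param mode `"E"` or `"DplusE"`.
#' @param seed Integer seed controlling the shuffle; fixed seed gives
#'   bit-identical reports.
#' @param k Cutoff ranks (default 1 and 10).
#' @param tokenizer Tokenizer contract.
#' @return A `cpc_eval_report`: list with `method`, `folds`, `seed`, `k`,
#'   `per_fold` (folds x length(k) matrix), `fold_assignment`, and `summary`
#'   (data frame k / mean / median / sd).
#' @export
cross_validate <- function(labeled, d_corpus = NULL, folds = 5L,
                           mode = c("E", "DplusE"), seed = 1L,
                           k = c(1L, 10L), tokenizer = default_tokenizer()) {
  mode <- match.arg(mode)
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  n <- nrow(labeled)
  if (n < folds) stop("need at least as many labeled docs as folds",
                      call. = FALSE)
  if (mode == "DplusE" && is.null(d_corpus)) {
    stop("mode 'DplusE' requires a description corpus", call. = FALSE)
  }
  perm <- withr::with_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep_len(seq_len(folds), n)
  per_fold <- matrix(NA_real_, nrow = folds, ncol = length(k),
                     dimnames = list(paste0("fold", seq_len(folds)),
                                     paste0("acc@", k)))
  for (f in seq_len(folds)) {
    train <- corpus_subset(labeled, fold_of != f)
    test <- corpus_subset(labeled, fold_of == f)
    ref <- if (mode == "DplusE") fuse_corpora(d_corpus, train) else train
    index <- build_index(ref, tokenizer)
    per_fold[f, ] <- accuracy_at_k(test, index, k = k)
  }
  summary <- data.frame(k = k,
                        mean = apply(per_fold, 2, mean),
                        median = apply(per_fold, 2, stats::median),
                        sd = if (folds > 1) apply(per_fold, 2, stats::sd)
                             else rep(NA_real_, length(k)),
                        row.names = NULL)
  structure(list(method = mode, folds = folds, seed = seed, k = k,
                 per_fold = per_fold, fold_assignment = fold_of,
                 summary = summary),
            class = "cpc_eval_report")
}

#' @export
print.cpc_eval_report <- function(x, ...) {
  cat("<cpc_eval_report> method=", x$method, ", ", x$folds,
      "-fold CV, seed=", x$seed, "\n", sep = "")
  print(x$summary, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Mirrors the usual accuracy-table layout: per method x Acc@k, the mean,
#' unbiased SD and median, plus the per-fold arrays and the seed.
#'
#' @param report A `cpc_eval_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  obj <- list(method = report$method, folds = report$folds,
              seed = report$seed,
              accuracy = lapply(seq_along(report$k), function(i) {
                list(k = report$k[i],
                     mean = report$summary$mean[i],
                     sd = report$summary$sd[i],
                     median = report$summary$median[i],
                     per_fold = unname(report$per_fold[, i]))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Relative category frequencies over a fixed support
#'
#' @param assignments Character vector of category codes (e.g. top-1
#'   assignments); each must belong to `support`.
#' @param support Ordered character vector of category codes.
#' @return Named numeric vector over `support` summing to 1 (all-zero for an
#'   empty assignment list).
#' @export
category_distribution <- function(assignments, support) {
  assignments <- assignments[!is.na(assignments)]
  bad <- setdiff(assignments, support)
  if (length(bad)) {
    stop("assignments outside the support: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  counts <- table(factor(assignments, levels = support))
  p <- as.numeric(counts)
  names(p) <- support
  if (sum(p) > 0) p <- p / sum(p)
  p
}

# Kullback-Leibler divergence with the 0 * log(0/x) == 0 convention.
kl_div <- function(p, q, log_fun) {
  nz <- p > 0
  sum(p[nz] * log_fun(p[nz] / q[nz]))
}

#' Jensen-Shannon divergence between two category distributions
#'
#' JSD(p, q) = KL(p || m)/2 + KL(q || m)/2 with m = (p + q)/2. Distributions
#' with different (named) supports are first zero-extended onto the union
#' support. Symmetric, zero iff p == q, bounded by log(2) in the chosen base.
#'
#' @param p,q Nonnegative numeric vectors summing to 1. If both are named
#'   they are aligned on the union of their names; unnamed vectors must have
#'   equal length.
#' @param log_base `"e"` (natural log, default) or `"2"`.
#' @return The divergence, in \[0, log 2\].
#' @export
js_divergence <- function(p, q, log_base = c("e", "2")) {
  log_base <- match.arg(log_base)
  if (!is.null(names(p)) && !is.null(names(q))) {
    support <- union(names(p), names(q))
    pp <- qq <- stats::setNames(numeric(length(support)), support)
    pp[names(p)] <- p
    qq[names(q)] <- q
    p <- pp
    q <- qq
  } else if (length(p) != length(q)) {
    stop("unnamed distributions must have equal length", call. = FALSE)
  }
  if (any(p < 0) || any(q < 0)) stop("negative probabilities", call. = FALSE)
  for (v in list(p, q)) {
    if (sum(v) > 0 && abs(sum(v) - 1) > 1e-8) {
      stop("distributions must sum to 1", call. = FALSE)
    }
  }
  log_fun <- if (log_base == "e") log else log2
  m <- (p + q) / 2
  0.5 * kl_div(p, m, log_fun) + 0.5 * kl_div(q, m, log_fun)
}
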