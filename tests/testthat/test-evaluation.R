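test_that("hit rule: any gold category in the top k counts", {
  expect_true(hit_at_k(c("A", "B", "C"), "C", 3))
  expect_false(hit_at_k(c("A", "B"), c("C", "D"), 2))
  expect_false(hit_at_k(c("A", "B", "C"), c("B", "Z"), 1))
  expect_true(hit_at_k(c("A", "B", "C"), c("B", "Z"), 2))
  expect_error(hit_at_k(c("A"), character(), 1), "empty gold")
})

test_that("accuracy_at_k matches manual enumeration and nests in k", {
  s <- toy_setup()
  idx <- build_index(s$e, get_tokenizer("ws"))
  labeled <- corpus_subset(s$q, lengths(s$q$labels) > 0)
  acc <- accuracy_at_k(labeled, idx, k = c(1, 2, 5))
  # manual: each labeled toy query shares distinctive words with its
  # category's examples only
  preds <- classify_corpus(idx, labeled, k = 5)
  hand <- mean(vapply(seq_len(nrow(labeled)), function(i) {
    p <- preds$code[preds$query_id == labeled$doc_id[i]]
    length(intersect(p[1], labeled$labels[[i]])) > 0
  }, logical(1)))
  expect_equal(unname(acc["acc@1"]), hand)
  expect_true(all(diff(acc) >= 0))  # Acc@k non-decreasing in k
  # degenerate: queries identical to reference docs with their own labels
  self_q <- corpus(paste0("sq", 1:4), s$e$text[1:4], s$e$labels[1:4],
                   s$tax, "query")
  expect_equal(unname(accuracy_at_k(self_q, idx, k = 1)), 1)
  # gold labels absent from every reference doc
  d_only <- corpus("dq", "choosing hospital doctor", list("3.1.1.1"),
                   s$tax, "query")
  idx_d1 <- build_index(corpus_subset(s$d, 1), get_tokenizer("ws"))
  expect_equal(unname(accuracy_at_k(d_only, idx_d1, k = 1)), 0)
  expect_error(accuracy_at_k(corpus_subset(s$q, 4), idx, 1), "no labeled")
})

test_that("d-based evaluation is single-pass with perfect self-recovery", {
  s <- toy_setup()
  self_q <- corpus(paste0("sq", seq_len(nrow(s$d))), s$d$text, s$d$labels,
                   s$tax, "query")
  acc <- evaluate_d_based(self_q, s$d, tokenizer = get_tokenizer("ws"))
  expect_equal(unname(acc[1]), 1)
  expect_named(acc, c("acc@1", "acc@10"))
})

test_that("cross-validation partitions exactly and is seed-reproducible", {
  s <- toy_setup()
  # folds=2 on 6 docs: every doc validates exactly once, sizes differ <= 1
  r <- cross_validate(s$e, folds = 2, mode = "E", seed = 5,
                      tokenizer = get_tokenizer("ws"))
  expect_identical(sort(unique(r$fold_assignment)), 1:2)
  expect_lte(diff(range(table(r$fold_assignment))), 1)
  expect_identical(length(r$fold_assignment), nrow(s$e))
  # bit-reproducible under the same seed; different under another
  r2 <- cross_validate(s$e, folds = 2, mode = "E", seed = 5,
                       tokenizer = get_tokenizer("ws"))
  expect_identical(r$per_fold, r2$per_fold)
  expect_identical(r$fold_assignment, r2$fold_assignment)
  r3 <- cross_validate(s$e, folds = 2, mode = "E", seed = 6,
                       tokenizer = get_tokenizer("ws"))
  expect_false(identical(r$fold_assignment, r3$fold_assignment))
  # summary aggregates with the unbiased (n-1) SD
  expect_equal(r$summary$sd[1], stats::sd(r$per_fold[, 1]))
  expect_equal(r$summary$mean[1], mean(r$per_fold[, 1]))
  # guards
  expect_error(cross_validate(s$e, folds = 1, mode = "E"), "folds")
  expect_error(cross_validate(s$e, folds = 7, mode = "E"), "at least")
  expect_error(cross_validate(s$e, mode = "DplusE", folds = 2),
               "description corpus")
})

test_that("duplicated-training degenerate CV reaches accuracy 1, SD 0", {
  tax <- taxonomy(c("1", "2", "1.1.1.1", "2.1.1.1"),
                  c("a", "b", "c", "d"))
  # every doc's text appears many times with the same label, so each
  # validation doc always duplicates a training doc
  texts <- rep(c("alpha beta gamma", "delta epsilon zeta"), each = 8)
  labels <- rep(list("1.1.1.1", "2.1.1.1"), each = 8)
  dup <- corpus(sprintf("x%02d", 1:16), texts, labels, tax, "E")
  r <- cross_validate(dup, folds = 2, mode = "E", seed = 1,
                      tokenizer = get_tokenizer("ws"))
  expect_true(all(r$per_fold[, "acc@1"] == 1))
  expect_equal(r$summary$mean, c(1, 1))
  expect_equal(r$summary$sd, c(0, 0))
})

test_that("eval report serializes with per-fold arrays", {
  s <- toy_setup()
  r <- cross_validate(s$e, folds = 3, mode = "E", seed = 2,
                      tokenizer = get_tokenizer("ws"))
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(r, f)
  obj <- jsonlite::fromJSON(f, simplifyVector = TRUE)
  expect_identical(obj$method, "E")
  expect_identical(obj$seed, 2L)
  expect_equal(obj$accuracy$mean, r$summary$mean)
  expect_equal(obj$accuracy$per_fold[[1]], unname(r$per_fold[, 1]))
})

test_that("category distributions normalize over the support", {
  p <- category_distribution(c("A", "A", "B"), c("A", "B", "C"))
  expect_equal(unname(p), c(2 / 3, 1 / 3, 0))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # permutation invariance
  p2 <- category_distribution(c("B", "A", "A"), c("A", "B", "C"))
  expect_identical(p, p2)
  # empty assignments give the zero distribution
  expect_equal(sum(category_distribution(character(), c("A", "B"))), 0)
  expect_error(category_distribution("Z", c("A", "B")), "outside")
})

test_that("jensen-shannon divergence: closed forms and properties", {
  expect_identical(js_divergence(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(js_divergence(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  expect_lt(abs(js_divergence(c(0.5, 0.5), c(1, 0)) - 0.215762), 1e-6)
  expect_equal(js_divergence(c(1, 0), c(0, 1), log_base = "2"), 1,
               tolerance = 1e-12)
  # symmetry and bounds on random distributions, incl. union-support
  withr::with_seed(21, {
    for (rep in 1:20) {
      p <- stats::runif(4); p <- p / sum(p)
      q <- stats::runif(4); q <- q / sum(q)
      expect_equal(js_divergence(p, q), js_divergence(q, p),
                   tolerance = 1e-14)
      expect_gte(js_divergence(p, q), 0)
      expect_lte(js_divergence(p, q), log(2) + 1e-12)
    }
  })
  # named supports are zero-extended onto the union
  p <- c(A = 0.5, B = 0.5)
  q <- c(B = 0.5, C = 0.5)
  byhand <- js_divergence(c(0.5, 0.5, 0), c(0, 0.5, 0.5))
  expect_equal(js_divergence(p, q), byhand, tolerance = 1e-14)
  expect_error(js_divergence(c(0.5, 0.5), c(1, 0, 0)), "equal length")
  expect_error(js_divergence(c(0.9, 0.9), c(0.5, 0.5)), "sum to 1")
})
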