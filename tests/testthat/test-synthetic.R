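small_cfg <- function(...) {
  defaults <- list(n_level1 = 5, n_level4 = 25, vocab_background = 300,
                   n_labeled_examples = 80, n_queries = 120,
                   doc_length = 25, seed = 17)
  do.call(synthetic_config, utils::modifyList(defaults, list(...)))
}

test_that("config validation rejects inconsistent settings", {
  expect_s3_class(synthetic_config(), "synthetic_config")
  expect_error(synthetic_config(signature_rate = 1.5))
  expect_error(synthetic_config(multi_label_probs = c(0.5, 0.5, 0.5)))
  expect_error(synthetic_config(out_of_taxonomy_rate = -0.1))
  expect_error(synthetic_config(n_level4 = 2, n_level1 = 5))
})

test_that("generation is deterministic and structurally valid", {
  g1 <- generate_synthetic(small_cfg())
  g2 <- generate_synthetic(small_cfg())
  expect_identical(g1$taxonomy, g2$taxonomy)
  expect_identical(g1$e_corpus$text, g2$e_corpus$text)
  expect_identical(g1$query_corpus$labels, g2$query_corpus$labels)
  # structure
  expect_identical(sum(g1$taxonomy$level == 4), 25L)
  expect_identical(sum(g1$taxonomy$level == 1), 5L)
  expect_identical(nrow(g1$d_corpus), 25L)
  expect_identical(nrow(g1$e_corpus), 80L)
  expect_identical(nrow(g1$query_corpus), 120L)
  expect_true(all(lengths(g1$e_corpus$labels) %in% 1:3))
  # a different seed changes the corpora
  g3 <- generate_synthetic(small_cfg(seed = 18))
  expect_false(identical(g1$e_corpus$text, g3$e_corpus$text))
})

test_that("out-of-taxonomy fraction tracks the configured rate", {
  cfg <- synthetic_config(n_level1 = 4, n_level4 = 16,
                          vocab_background = 300,
                          n_labeled_examples = 40, n_queries = 600,
                          out_of_taxonomy_rate = 0.546, seed = 3)
  g <- generate_synthetic(cfg)
  frac <- mean(lengths(g$query_corpus$labels) == 0)
  # binomial 3-sigma band around 0.546 at n = 600
  expect_lt(abs(frac - 0.546), 3 * sqrt(0.546 * 0.454 / 600))
})

test_that("gold-label marginal follows the configured Zipf law", {
  cfg <- synthetic_config(n_level1 = 4, n_level4 = 8, vocab_background = 100,
                          n_labeled_examples = 3000, n_queries = 0,
                          multi_label_probs = c(1, 0, 0),
                          zipf_exponent = 1, seed = 5)
  g <- generate_synthetic(cfg)
  prim <- vapply(g$e_corpus$labels, `[`, character(1), 1)
  codes4 <- g$taxonomy$code[g$taxonomy$level == 4]
  # generator assigns category i the weight i^-1 in topic order
  topic_order <- order(as.integer(sub(".*topic", "",
                                      taxonomy_name(g$taxonomy, codes4))))
  counts <- table(factor(prim, levels = codes4[topic_order]))
  expected <- (1 / seq_len(8)) / sum(1 / seq_len(8))
  gof <- stats::chisq.test(as.integer(counts), p = expected)
  expect_gt(gof$p.value, 0.001)
})

test_that("saturated signatures give perfect downstream accuracy", {
  g <- generate_synthetic(small_cfg(signature_rate = 1,
                                    multi_label_probs = c(1, 0, 0),
                                    colloquial_rate = 0,
                                    out_of_taxonomy_rate = 0))
  idx <- build_index(fuse_corpora(g$d_corpus, g$e_corpus))
  acc <- accuracy_at_k(g$query_corpus, idx, k = 1)
  expect_equal(unname(acc), 1)
})

test_that("generated files round-trip and keep the answer key separate", {
  dir <- withr::local_tempdir()
  g <- generate_synthetic(small_cfg())
  write_synthetic(g, dir)
  expect_true(all(file.exists(file.path(dir, c("taxonomy.tsv", "d.tsv",
                                               "e.tsv", "queries.tsv",
                                               "answer_key.tsv")))))
  tax <- read_taxonomy(file.path(dir, "taxonomy.tsv"))
  q <- read_corpus(file.path(dir, "queries.tsv"), tax, "query")
  expect_true(all(lengths(q$labels) == 0))  # blinded
  key <- utils::read.delim(file.path(dir, "answer_key.tsv"), header = FALSE)
  expect_identical(as.character(key[[1]]), g$query_corpus$doc_id)
})

test_that("benchmark rows nest acc@10 over acc@1 and jsd shrinks with s", {
  # single gold labels isolate signal recovery: at high s the predicted
  # top-1 distribution converges on the gold distribution itself
  cfg <- small_cfg(n_queries = 150, out_of_taxonomy_rate = 0.2,
                   multi_label_probs = c(1, 0, 0))
  bench <- benchmark_suite(c(0.3, 0.9), config = cfg, modes = c("E", "DplusE"),
                           folds = 3, seed = 9)
  expect_identical(nrow(bench), 4L)
  expect_true(all(bench$acc10 >= bench$acc1))
  expect_true(all(bench$jsd >= 0 & bench$jsd <= log(2) + 1e-12))
  # stronger signatures: higher accuracy, and closer predicted distribution
  # on average over paired generation seeds (one benchmark call per s pairs
  # the generated data). The contrast starts near s = 0 because above
  # moderate signal the divergence sits on a small-sample floor: residual
  # errors land on prevalent categories and preserve the distribution.
  paired <- lapply(c(9, 10, 11), function(master) {
    lo <- benchmark_suite(0.05, config = cfg, modes = "DplusE", folds = 3,
                          seed = master)
    hi <- benchmark_suite(0.9, config = cfg, modes = "DplusE", folds = 3,
                          seed = master)
    c(acc_lo = lo$acc1, acc_hi = hi$acc1, jsd_lo = lo$jsd, jsd_hi = hi$jsd)
  })
  paired <- do.call(rbind, paired)
  expect_gt(mean(paired[, "acc_hi"]), mean(paired[, "acc_lo"]))
  expect_lt(mean(paired[, "jsd_hi"]), mean(paired[, "jsd_lo"]))
})

test_that("null accuracy spread brackets a label-shuffled classifier", {
  g <- generate_synthetic(small_cfg(signature_rate = 0, n_queries = 200,
                                    out_of_taxonomy_rate = 0))
  idx <- build_index(g$e_corpus)
  nulls <- null_accuracy(g$query_corpus, idx, k = 1, n_shuffles = 15,
                         seed = 4)
  expect_identical(length(nulls), 15L)
  expect_true(all(nulls >= 0 & nulls <= 1))
  expect_gt(stats::sd(nulls), 0)
})
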