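# ROC/AUROC, F1, threshold calibration and ROUGE.

test_that("roc_auc matches its documented examples", {
  r <- roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0L, 0L, 1L, 1L))
  expect_equal(r$auroc, 0.75)
  expect_equal(roc_auc(c(0.9, 0.8, 0.1, 0.2), c(1L, 1L, 0L, 0L))$auroc, 1)
  expect_equal(roc_auc(rep(0.5, 6L), c(1L, 0L, 1L, 0L, 1L, 0L))$auroc, 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1L, 1L)), "both classes")
  # curve is monotone and anchored
  expect_true(all(diff(r$tpr) >= 0))
  expect_true(all(diff(r$fpr) >= 0))
  expect_equal(c(r$tpr[1L], r$fpr[1L]), c(0, 0))
  expect_equal(c(tail(r$tpr, 1L), tail(r$fpr, 1L)), c(1, 1))
})

test_that("roc_auc equals all-pairs Mann-Whitney counting (ties = 1/2)", {
  set.seed(80)
  for (i in 1:300) {
    n <- sample(4:40, 1L)
    labels <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(labels)) < 2L) labels[1:2] <- c(0L, 1L)
    # coarse grid forces plenty of ties
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    expect_equal(roc_auc(scores, labels)$auroc,
                 auroc_bruteforce(scores, labels), tolerance = 1e-12)
  }
})

test_that("f1_binary counts characters correctly", {
  same <- f1_binary(c(1L, 0L, 1L), c(1L, 0L, 1L))
  expect_equal(same$f1, 1)
  expect_equal(f1_binary(c(1L, 0L), c(0L, 1L))$f1, 0)
  half <- f1_binary(c(1L, 1L, 0L, 0L), c(1L, 0L, 1L, 0L))
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)
  expect_equal(half$f1, 0.5)
  zero <- f1_binary(c(0L, 0L), c(0L, 0L))
  expect_equal(c(zero$precision, zero$recall, zero$f1), c(0, 0, 0))
  expect_identical(f1_binary("10", "10")$f1, 1)
})

test_that("choose_threshold maximizes F1 and matches a dense sweep", {
  recs <- data.frame(text = "abc def", label = "1110000",
                     source = "synthetic_discharge")
  scorer <- function(text) c(0.9, 0.9, 0.9, 0.5, 0.2, 0.2, 0.2)
  th <- choose_threshold(scorer, recs)
  expect_equal(as.numeric(th), 0.9)
  expect_equal(attr(th, "f1"), 1)
  # random validation sets: compare against a brute-force threshold grid
  set.seed(81)
  for (i in 1:40) {
    recs <- tiny_corpus(3L, seed = 81L + i)
    scorer <- oracle_scorer(recs, flip = 0.3)
    set.seed(100L + i)
    th <- choose_threshold(scorer, recs)
    # recompute pooled probabilities deterministically for the oracle
    set.seed(100L + i)
    pool_p <- numeric(0); pool_y <- integer(0)
    for (j in seq_len(nrow(recs))) {
      p <- cleanup(predict_probabilities(scorer, recs$text[j]),
                   segment_units(recs$text[j]))
      pool_p <- c(pool_p, p)
      pool_y <- c(pool_y, .label_ints(recs$label[j]))
    }
    grid <- sort(unique(c(pool_p, pool_p - 1e-9, 0, 1)))
    brute <- vapply(grid, function(t) {
      f1_binary(as.integer(pool_p >= t), pool_y)$f1
    }, numeric(1))
    expect_equal(attr(th, "f1"), max(brute), tolerance = 1e-12)
    expect_equal(f1_binary(as.integer(pool_p >= as.numeric(th)), pool_y)$f1,
                 max(brute), tolerance = 1e-12)
    # maximality: at least as good as the conventional 0.5 cut
    expect_gte(attr(th, "f1"),
               f1_binary(as.integer(pool_p >= 0.5), pool_y)$f1 - 1e-12)
  }
})

test_that("tokenize_for_rouge lowercases, strips punctuation, splits", {
  expect_identical(tokenize_for_rouge("1.Bladder cancer with"),
                   c("1", "bladder", "cancer", "with"))
  expect_identical(tokenize_for_rouge("..."), character(0))
  expect_identical(tokenize_for_rouge(""), character(0))
  w <- tokenize_for_rouge("Status post R-CHOP, cycle 3")
  expect_identical(w, c("status", "post", "r", "chop", "cycle", "3"))
  expect_identical(tokenize_for_rouge(paste(w, collapse = " ")), w)
})

test_that("rouge_n scores clipped n-gram overlap", {
  expect_equal(rouge_n(c("a", "b"), c("a", "b"), 1L)$f1, 1)
  r2 <- rouge_n(c("a", "b", "c"), c("a", "b", "d"), 2L)
  expect_equal(c(r2$precision, r2$recall, r2$f1), c(0.5, 0.5, 0.5))
  expect_equal(rouge_n(c("x"), c("y"), 1L)$f1, 0)
  expect_equal(rouge_n(character(0), c("a"), 1L)$f1, 0)
  # clipping: candidate repetition cannot inflate overlap
  clip <- rouge_n(c("a", "a", "a"), c("a", "b"), 1L)
  expect_equal(clip$precision, 1 / 3)
  expect_equal(clip$recall, 1 / 2)
})

test_that("rouge_l matches exhaustive subsequence enumeration", {
  r <- rouge_l(c("bladder", "cancer"), c("bladder", "cancer", "with"))
  expect_equal(c(r$precision, r$recall, r$f1), c(1, 2 / 3, 0.8))
  expect_equal(rouge_l(c("a"), c("a"))$f1, 1)
  expect_equal(rouge_l(character(0), c("a"))$f1, 0)
  set.seed(82)
  vocab <- letters[1:5]
  for (i in 1:150) {
    a <- sample(vocab, sample(1:8, 1L), replace = TRUE)
    b <- sample(vocab, sample(1:8, 1L), replace = TRUE)
    lcs <- charsumm:::.lcs_length(a, b)
    expect_identical(lcs, lcs_bruteforce(a, b))
    got <- rouge_l(a, b)
    expect_equal(got$precision, lcs / length(a))
    expect_equal(got$recall, lcs / length(b))
    # swapping candidate and reference swaps P and R, F1 unchanged
    swapped <- rouge_l(b, a)
    expect_equal(swapped$precision, got$recall)
    expect_equal(swapped$f1, got$f1)
  }
})

test_that("evaluate_model reports perfect scores for an oracle scorer", {
  recs <- tiny_corpus(8L, seed = 83L)
  rep <- evaluate_model(oracle_scorer(recs), recs, threshold = 0.5)
  expect_equal(rep$auroc, 1)
  expect_equal(unname(rep$rouge["rougeL"]), 1)
  expect_equal(unname(rep$rouge["rouge1"]), 1)
  expect_identical(rep$n_records, 8L)
  # an uninformative scorer sits at chance
  flat <- function(text) rep(0.5, nchar(text))
  expect_equal(evaluate_model(flat, recs, 0.5)$auroc, 0.5)
  expect_error(evaluate_model(flat, recs[0L, ], 0.5), "empty")
})
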