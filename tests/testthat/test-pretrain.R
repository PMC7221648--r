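# Masked-character corruption, whole-word masking, the masked-LM loss and
# the pretraining loop.

test_that("corrupt_sequence hits the 15/80/10/10 design at moderate n", {
  tab <- build_symbol_table()
  set.seed(50)
  ids <- sample(0:99, 200000L, replace = TRUE)
  ex <- corrupt_sequence(ids, tab)
  sel_frac <- length(ex$mask_positions) / length(ids)
  expect_lt(abs(sel_frac - 0.15), 0.005)
  br <- table(factor(ex$branches, levels = c("mask", "random", "keep")))
  props <- br / sum(br)
  expect_lt(abs(props[["mask"]] - 0.80), 0.01)
  expect_lt(abs(props[["random"]] - 0.10), 0.01)
  expect_lt(abs(props[["keep"]] - 0.10), 0.01)
  # mask branch really writes '^'
  at <- ex$mask_positions[ex$branches == "mask"] + 1L
  expect_true(all(ex$corrupted_ids[at] == 56L))
})

test_that("corruption never alters unselected positions and preserves class", {
  tab <- build_symbol_table()
  info <- charsumm:::.class_info(tab)
  set.seed(51)
  for (i in 1:50) {
    ids <- sample(0:99, 500L, replace = TRUE)
    ex <- corrupt_sequence(ids, tab)
    expect_identical(ex$target_ids, ids)
    untouched <- setdiff(seq_along(ids), ex$mask_positions + 1L)
    expect_identical(ex$corrupted_ids[untouched], ids[untouched])
    # keep branch: unchanged; random branch: same class, different id
    # (spaces and '^' have no alternative and stay put)
    keep_at <- ex$mask_positions[ex$branches == "keep"] + 1L
    expect_identical(ex$corrupted_ids[keep_at], ids[keep_at])
    rnd_at <- ex$mask_positions[ex$branches == "random"] + 1L
    for (j in rnd_at) {
      g_orig <- info$group_of_id[ids[j] + 1L]
      g_new <- info$group_of_id[ex$corrupted_ids[j] + 1L]
      expect_identical(g_new, g_orig)
      if (!g_orig %in% c("space", "mask")) {
        expect_false(ex$corrupted_ids[j] == ids[j])
      }
    }
  }
})

test_that("a length-1 sequence can come through unselected", {
  set.seed(52)
  outcomes <- vapply(1:200, function(i) {
    length(corrupt_sequence(5L)$mask_positions)
  }, integer(1))
  expect_true(any(outcomes == 0L))
  expect_true(any(outcomes == 1L))
})

test_that("whole-word corruption is all-or-nothing per unit", {
  tab <- build_symbol_table()
  text <- "1.Bladder cancer with chemotherapy on 2019/05/21"
  ids <- encode_text(text, tab)
  units <- segment_units(text, tab)
  set.seed(53)
  seen_mask_word <- FALSE
  for (i in 1:100) {
    ex <- whole_word_corrupt(ids, units, tab, word_rate = 0.5)
    # masked positions align exactly with unit boundaries
    for (u in seq_len(nrow(units))) {
      span <- (units$start[u] + 1L):units$end[u]
      inside <- sum((span - 1L) %in% ex$mask_positions)
      expect_true(inside == 0L || inside == length(span))
      if (inside > 0L) {
        expect_true(units$kind[u] %in% c("letter_run", "digit_run"))
        if (all(ex$corrupted_ids[span] == 56L) && length(span) > 1L) {
          seen_mask_word <- TRUE
        }
      }
    }
  }
  expect_true(seen_mask_word)
  # rate 0 is the identity
  ex0 <- whole_word_corrupt(ids, units, tab, word_rate = 0)
  expect_identical(ex0$corrupted_ids, ids)
  expect_length(ex0$mask_positions, 0L)
})

test_that("mlm_loss matches closed forms and a brute-force oracle", {
  # uniform logits over 100 symbols -> ln(100) per masked character
  L <- 7L
  uni <- matrix(0, L, 100L)
  targets <- c(3L, 10L, 99L, 0L, 56L, 13L, 30L)
  expect_equal(mlm_loss(uni, targets, c(0L, 2L, 6L)), log(100),
               tolerance = 1e-9)
  # probability-1 logits on the target -> 0
  sharp <- matrix(-1e4, L, 100L)
  sharp[cbind(1:L, targets + 1L)] <- 1e4
  expect_equal(mlm_loss(sharp, targets, 0:(L - 1L)), 0, tolerance = 1e-9)
  # hand-built 3-position case vs direct per-position computation
  set.seed(54)
  logits <- matrix(rnorm(L * 100L), L, 100L)
  pos <- c(1L, 4L, 5L)
  direct <- mean(vapply(pos, function(i) {
    p <- exp(logits[i + 1L, ]) / sum(exp(logits[i + 1L, ]))
    -log(p[targets[i + 1L] + 1L])
  }, numeric(1)))
  expect_equal(mlm_loss(logits, targets, pos), direct, tolerance = 1e-10)
  expect_error(mlm_loss(uni, targets, integer(0)), "empty")
})

test_that("pretraining shows a learning signal and is seed-deterministic", {
  cfg <- tiny_config(n_layers = 2L, hidden = 16L, max_positions = 128L,
                     dropout = 0.1)
  corpus <- generate_corpus(50L, 10L, seed = 55L)
  m <- new_model(cfg)
  trained <- pretrain_loop(m, corpus, steps = 250L, seed = 56L,
                           hyper = list(lr_main = 3e-4, warmup_steps = 20L))
  lg <- trained$log
  expect_identical(nrow(lg), 250L)
  expect_lt(mean(lg$loss[226:250]), mean(lg$loss[1:25]))
  expect_true(all(is.finite(lg$loss)))
  expect_identical(lg$lr[1:20], rep(1e-5, 20L))
  expect_identical(lg$lr[21:250], rep(3e-4, 230L))
  # identical seed -> identical trajectory
  trained2 <- pretrain_loop(new_model(cfg), corpus, steps = 50L, seed = 57L)
  trained3 <- pretrain_loop(new_model(cfg), corpus, steps = 50L, seed = 57L)
  expect_identical(trained2$log, trained3$log)
  expect_identical(trained2$weights, trained3$weights)
})

test_that("the phase-2 trigger fires manually and switches corruption", {
  cfg <- tiny_config(hidden = 8L, max_positions = 64L)
  corpus <- tiny_corpus(8L)
  m <- pretrain_loop(new_model(cfg), corpus, steps = 30L, seed = 58L,
                     hyper = list(phase2_step = 10L))
  expect_identical(m$log$phase, c(rep(1L, 10L), rep(2L, 20L)))
})

test_that("a single short example is memorized by an overfit tiny model", {
  cfg <- tiny_config(n_layers = 2L, hidden = 16L, max_positions = 96L,
                     seed = 2L)
  rec <- tiny_corpus(1L, seed = 3L, max_chars = 96L)
  m <- pretrain_loop(new_model(cfg), rec, steps = 800L, seed = 4L,
                     hyper = list(augment = FALSE, warmup_steps = 20L,
                                  lr_main = 1e-3, phase2_step = .Machine$integer.max))
  expect_lt(mean(tail(m$log$loss, 50L)), 0.2)
  # decoder A restores the example's own ids from clean input
  ids <- encode_text(rec$text)
  PA <- decoder_A(m, encode_sequence(m, ids))
  expect_gte(mean(max.col(PA) - 1L == ids), 0.99)
})
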