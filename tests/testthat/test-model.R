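# Network architecture: shapes, determinism, parameter accounting and the
# analytic gradients (checked against central finite differences).

test_that("embedding output has the right shape and uses position", {
  cfg <- tiny_config(hidden = 64L, n_heads = 16L)
  m <- new_model(cfg)
  ids <- encode_text("1.Bladder cancer with")
  X <- embed(m, ids)
  expect_identical(dim(X), c(21L, 64L))
  m2 <- new_model(cfg)  # same seed -> same weights
  expect_identical(X, embed(m2, ids))
  # the repeated 'd' at offsets 5 and 6 gets different rows
  expect_false(isTRUE(all.equal(X[6L, ], X[7L, ])))
  expect_error(embed(m, rep(0L, cfg$max_positions + 1L)), "max_positions")
})

test_that("encoder forward pass is deterministic and shape-stable", {
  cfg <- tiny_config(n_layers = 2L)
  m <- new_model(cfg)
  ids <- encode_text("1.Bladder cancer with")
  H <- encode_sequence(m, ids)
  expect_identical(dim(H), c(21L, cfg$hidden))
  expect_identical(H, encode_sequence(m, ids))
  # shuffling the ids changes the output (position embeddings)
  set.seed(30)
  H2 <- encode_sequence(m, sample(ids))
  expect_false(isTRUE(all.equal(H, H2)))
  # boundary: a 1-layer hidden-8 model accepts a max-length input
  cfg_long <- model_config(n_layers = 1L, n_heads = 2L, hidden = 8L,
                           max_positions = 1350L, dropout = 0)
  m_long <- new_model(cfg_long)
  H_long <- encode_sequence(m_long, rep(c(57L, 0L, 14L), 450L))
  expect_identical(dim(H_long), c(1350L, 8L))
})

test_that("decoder heads emit normalized probability rows", {
  cfg <- tiny_config()
  m <- new_model(cfg)
  set.seed(31)
  ids <- sample(0:99, 17L, replace = TRUE)
  H <- encode_sequence(m, ids)
  PA <- decoder_A(m, H)
  PS <- decoder_S(m, H)
  expect_identical(dim(PA), c(17L, 100L))
  expect_identical(dim(PS), c(17L, 2L))
  expect_equal(rowSums(PA), rep(1, 17L), tolerance = 1e-6)
  expect_equal(rowSums(PS), rep(1, 17L), tolerance = 1e-6)
  expect_true(all(PA >= 0 & PA <= 1))
  expect_true(all(PS >= 0 & PS <= 1))
})

test_that("parameter count matches a hand-summed closed form", {
  # layers=1, heads=1, hidden=4, vocab=5, max_positions=6, ff=8:
  #   embeddings: 5*4 + 6*4                    = 44
  #   embedding layer norm: 4 + 4              = 8
  #   encoder: QKV+out (4*(4*4+4)=80), 2 layer norms (16),
  #            ff (4*8+8=40, 8*4+4=36)         = 172
  #   decoder A: 4*5+5                         = 25
  #   decoder S: 4*2+2                         = 10
  cfg <- model_config(n_layers = 1L, n_heads = 1L, hidden = 4L, vocab = 5L,
                      max_positions = 6L, ff_width = 8L, dropout = 0)
  total <- count_parameters(cfg)
  expect_identical(as.integer(total), 44L + 8L + 172L + 25L + 10L)
  bd <- attr(total, "breakdown")
  expect_equal(unname(bd), c(44, 8, 172, 25, 10))
  expect_equal(sum(bd), as.numeric(total))
  # doubling layers exactly doubles the encoder sub-count
  cfg2 <- model_config(n_layers = 2L, n_heads = 1L, hidden = 4L, vocab = 5L,
                       max_positions = 6L, ff_width = 8L, dropout = 0)
  expect_equal(attr(count_parameters(cfg2), "breakdown")[["encoder"]],
               2 * bd[["encoder"]])
  # the initialized model really allocates that many scalars
  m <- new_model(cfg)
  expect_identical(sum(vapply(m$weights, length, integer(1))),
                   as.integer(total))
})

test_that("analytic gradients agree with finite differences", {
  cfg <- model_config(n_layers = 2L, n_heads = 2L, hidden = 8L,
                      max_positions = 12L, ff_width = 16L, dropout = 0,
                      seed = 3L)
  w <- new_model(cfg)$weights
  ids <- c(14L, 11L, 31L, 68L, 57L, 60L, 0L, 79L)
  ex <- list(corrupted_ids = c(56L, 11L, 31L, 56L, 57L, 60L, 0L, 23L),
             target_ids = ids, mask_positions = c(0L, 3L, 7L))
  labels <- c(0L, 0L, 1L, 1L, 1L, 0L, 0L, 1L)
  cases <- list(
    mlm = function(w) charsumm:::.mlm_step(w, cfg, ex),
    sel = function(w) charsumm:::.sel_step(w, cfg, ids, labels)
  )
  set.seed(9)
  for (case in names(cases)) {
    res <- cases[[case]](w)
    for (nm in names(w)) {
      ana_tensor <- res$grads[[nm]]
      for (k in sample(length(w[[nm]]), min(2L, length(w[[nm]])))) {
        eps <- 1e-5
        wp <- w; wp[[nm]][k] <- wp[[nm]][k] + eps
        wm <- w; wm[[nm]][k] <- wm[[nm]][k] - eps
        num <- (cases[[case]](wp)$loss - cases[[case]](wm)$loss) / (2 * eps)
        ana <- if (is.null(ana_tensor)) 0 else ana_tensor[k]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
      }
    }
    # gradient reaches every component that participates in this head
    flowing <- names(Filter(function(g) any(g != 0), res$grads))
    expect_true(all(grepl("^l0|emb|dec", flowing)))
    expect_gte(length(flowing), length(w) - 2L)  # only the unused head is absent
  }
})

test_that("training-mode forward is RNG-driven but seed-reproducible", {
  cfg <- tiny_config(dropout = 0.3)
  m <- new_model(cfg)
  ids <- encode_text("Bladder cancer")
  set.seed(5)
  a <- charsumm:::.nn_forward(m$weights, cfg, ids, train = TRUE)$X
  set.seed(5)
  b <- charsumm:::.nn_forward(m$weights, cfg, ids, train = TRUE)$X
  set.seed(6)
  c3 <- charsumm:::.nn_forward(m$weights, cfg, ids, train = TRUE)$X
  expect_identical(a, b)
  expect_false(isTRUE(all.equal(a, c3)))
  # evaluation mode ignores dropout entirely
  expect_identical(encode_sequence(m, ids), encode_sequence(m, ids))
})

test_that("checkpoints round-trip through disk", {
  cfg <- tiny_config()
  m <- new_model(cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(back$weights, m$weights)
  expect_identical(unclass(back$config), unclass(cfg))
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(1, 2), bad)
  expect_error(load_checkpoint(bad), "not a recognized checkpoint")
})
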