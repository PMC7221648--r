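# Stage-1 pretraining: masked-character language modeling.
#
# Corruption follows the BERT cloze recipe adapted to character tokens:
# 15% of positions are selected; of those, 80% become the mask symbol '^',
# 10% are replaced by a random *different* symbol of the same class
# (letter -> letter, digit -> digit, punctuation -> punctuation -- dates,
# cycle counts and staging indexes are unrecoverable without such a
# constraint), and 10% are left unchanged. A second phase masks whole
# words (letter/digit runs) all-or-nothing.

# id-level lookup tables for class-preserving replacement.
.class_info <- function(table = build_symbol_table()) {
  grp <- vapply(table$symbols, function(ch) {
    switch(table$classes[[ch]],
           uppercase = "letter", lowercase = "letter",
           digit = "digit", punctuation = "punctuation",
           space = "space", mask = "mask")
  }, character(1))
  pools <- lapply(c(letter = "letter", digit = "digit",
                    punctuation = "punctuation"),
                  function(g) which(grp == g) - 1L)  # 0-based ids
  list(group_of_id = unname(grp), pools = pools,
       mask_id = unname(table$ids[["^"]]))
}

# Replace ids[i] by a uniform different id of the same class; ids with no
# replacement pool (space, mask symbol) are returned unchanged.
.replace_ids_same_class <- function(ids, info) {
  grp <- info$group_of_id[ids + 1L]
  out <- ids
  for (g in names(info$pools)) {
    sel <- which(grp == g)
    if (length(sel) == 0L) next
    pool <- info$pools[[g]]
    np <- length(pool)
    pos <- match(ids[sel], pool)
    j <- sample.int(np - 1L, length(sel), replace = TRUE)
    j <- j + (j >= pos)
    out[sel] <- pool[j]
  }
  out
}

#' Corrupt an id sequence for masked-character pretraining
#'
#' Each position is independently selected with probability `mask_rate`
#' (0.15). Selected positions are corrupted 80/10/10: replaced by the mask
#' symbol `^`, replaced by a random different symbol of the same character
#' class, or left unchanged. Spaces have no same-class alternative, so in
#' the random-replacement branch they stay as spaces (they can still be
#' masked by `^`).
#'
#' @param ids Integer symbol ids (0-based).
#' @param table A `symbol_table`.
#' @param mask_rate Per-position selection probability.
#' @param branch_probs Probabilities of the mask / random / keep branches.
#' @return A list of class `masked_example`: `corrupted_ids`,
#'   `target_ids`, `mask_positions` (0-based offsets of all selected
#'   positions) and `branches` (parallel to `mask_positions`, one of
#'   `"mask"`, `"random"`, `"keep"`).
#' @export
corrupt_sequence <- function(ids, table = build_symbol_table(),
                             mask_rate = 0.15,
                             branch_probs = c(0.8, 0.1, 0.1)) {
  stopifnot(length(ids) > 0L)
  info <- .class_info(table)
  sel <- which(stats::runif(length(ids)) < mask_rate)
  corrupted <- ids
  branches <- character(length(sel))
  if (length(sel) > 0L) {
    u <- stats::runif(length(sel))
    b_mask <- u < branch_probs[1]
    b_rand <- !b_mask & u < branch_probs[1] + branch_probs[2]
    branches[b_mask] <- "mask"
    branches[b_rand] <- "random"
    branches[!b_mask & !b_rand] <- "keep"
    corrupted[sel[b_mask]] <- info$mask_id
    if (any(b_rand)) {
      corrupted[sel[b_rand]] <-
        .replace_ids_same_class(ids[sel[b_rand]], info)
    }
  }
  structure(list(corrupted_ids = corrupted, target_ids = ids,
                 mask_positions = sel - 1L, branches = branches),
            class = "masked_example")
}

#' Whole-word corruption for the second pretraining phase
#'
#' Selects letter and digit runs (never spaces or punctuation) each with
#' probability `word_rate` and corrupts every character of a selected unit
#' under the same 80/10/10 policy, applied unit-wise: in the mask branch
#' the whole word becomes `^^^...^`; in the random branch each character
#' is replaced by a random same-class symbol; in the keep branch the word
#' is untouched but still counted as masked.
#'
#' @param ids Integer symbol ids.
#' @param units Word units from [segment_units()] tiling `ids`.
#' @param table A `symbol_table`.
#' @param word_rate Per-unit selection probability.
#' @param branch_probs Mask / random / keep branch probabilities.
#' @return A `masked_example` (branches recorded per selected unit,
#'   repeated over its characters).
#' @export
whole_word_corrupt <- function(ids, units, table = build_symbol_table(),
                               word_rate = 0.15,
                               branch_probs = c(0.8, 0.1, 0.1)) {
  stopifnot(length(ids) > 0L)
  if (nrow(units) == 0L || units$end[nrow(units)] != length(ids)) {
    stop("units must tile the id sequence")
  }
  info <- .class_info(table)
  eligible <- which(units$kind %in% c("letter_run", "digit_run"))
  sel_units <- eligible[stats::runif(length(eligible)) < word_rate]
  corrupted <- ids
  mask_positions <- integer(0)
  branches <- character(0)
  for (ui in sel_units) {
    span <- (units$start[ui] + 1L):units$end[ui]
    u <- stats::runif(1)
    br <- if (u < branch_probs[1]) "mask"
          else if (u < branch_probs[1] + branch_probs[2]) "random"
          else "keep"
    if (br == "mask") {
      corrupted[span] <- info$mask_id
    } else if (br == "random") {
      corrupted[span] <- .replace_ids_same_class(ids[span], info)
    }
    mask_positions <- c(mask_positions, span - 1L)
    branches <- c(branches, rep(br, length(span)))
  }
  ord <- order(mask_positions)
  structure(list(corrupted_ids = corrupted, target_ids = ids,
                 mask_positions = mask_positions[ord],
                 branches = branches[ord]),
            class = "masked_example")
}

#' Masked-language-model loss
#'
#' Mean cross-entropy over the masked positions only: the mean of
#' `-log p(target symbol)` where `p` is the row-wise softmax of `logits`.
#' Unmasked positions contribute nothing.
#'
#' @param logits `length x vocab` real matrix.
#' @param target_ids Original (uncorrupted) symbol ids.
#' @param mask_positions 0-based offsets of masked positions (non-empty).
#' @return Non-negative scalar.
#' @export
mlm_loss <- function(logits, target_ids, mask_positions) {
  if (length(mask_positions) == 0L) {
    stop("mask_positions is empty: masked-LM loss is undefined")
  }
  stopifnot(nrow(logits) == length(target_ids),
            all(mask_positions >= 0L), all(mask_positions < nrow(logits)))
  P <- .softmax_rows(logits)
  rows <- mask_positions + 1L
  -mean(log(pmax(P[cbind(rows, target_ids[rows] + 1L)], 1e-300)))
}

# Shared machinery of the two training loops: warmup schedule, minibatch
# gradient accumulation, Adam, loss logging and divergence checks.
# make_example(phase) must return list(loss, grads) for one batch item.
.train_loop <- function(model, steps, hyper, step_fn, phase_fn = NULL) {
  w <- model$weights
  cfg <- model$config
  opt <- .adam_init(w)
  log_step <- integer(steps)
  log_phase <- integer(steps)
  log_lr <- numeric(steps)
  log_loss <- numeric(steps)
  phase <- 1L
  smooth <- numeric(0)
  for (step in seq_len(steps)) {
    lr <- if (step <= hyper$warmup_steps) hyper$lr_warmup else hyper$lr_main
    grads <- list()
    loss <- 0
    for (b in seq_len(hyper$batch_size)) {
      res <- step_fn(w, phase)
      grads <- .grads_add(grads, res$grads)
      loss <- loss + res$loss
    }
    loss <- loss / hyper$batch_size
    grads <- .grads_scale(grads, 1 / hyper$batch_size)
    if (!is.finite(loss)) {
      stop(sprintf("training diverged at step %d (loss %s)", step, loss))
    }
    upd <- .adam_update(w, grads, opt, lr)
    w <- upd$w
    opt <- upd$state
    log_step[step] <- step
    log_phase[step] <- phase
    log_lr[step] <- lr
    log_loss[step] <- loss
    if (!is.null(phase_fn) && phase == 1L) {
      smooth <- c(smooth, loss)
      if (phase_fn(step, smooth)) phase <- 2L
    }
  }
  model$weights <- w
  model$step <- model$step + steps
  model$log <- data.frame(step = log_step, phase = log_phase,
                          lr = log_lr, loss = log_loss)
  model
}

.default_pretrain_hyper <- function(steps) {
  list(lr_warmup = 1e-5, lr_main = 1e-4, batch_size = 2L,
       warmup_steps = max(1L, round(0.1 * steps)),
       mask_rate = 0.15, word_rate = 0.15,
       phase2_step = NULL, phase2_window = 200L, phase2_tol = 0.01,
       k_max = 29L, augment = TRUE)
}

#' Pretrain a model with masked-character language modeling
#'
#' Adam optimization at learning rate 1e-5 during warmup and 1e-4
#' afterwards, minibatch size 2. Each batch item is built by stitching
#' random corpus records ([stitch_augment()]) and corrupting the result
#' with [corrupt_sequence()]; once the loss has converged (or at the
#' manual `phase2_step` override), corruption switches to whole-word
#' masking ([whole_word_corrupt()]). Fully deterministic for a given
#' `seed` on one device.
#'
#' @param model A `charsumm_model` (fresh or resumed).
#' @param corpus Corpus data.frame (`text`, `label`, `source`); labels are
#'   ignored at this stage.
#' @param steps Number of optimization steps.
#' @param seed Integer seed driving batching, corruption and dropout.
#' @param hyper Named list overriding the defaults: `lr_warmup` (1e-5),
#'   `lr_main` (1e-4), `batch_size` (2), `warmup_steps` (10% of `steps`),
#'   `mask_rate` (0.15), `word_rate` (0.15, phase 2), `phase2_step`
#'   (manual phase switch; `NULL` = automatic, triggered when the smoothed
#'   loss improves by less than `phase2_tol` over `phase2_window` steps),
#'   `k_max` (29, stitching bound), `augment` (set `FALSE` to train on raw
#'   records, e.g. for memorization checks).
#' @return The trained model; `model$log` holds a per-step data.frame
#'   (`step`, `phase`, `lr`, `loss`).
#' @export
pretrain_loop <- function(model, corpus, steps, seed = 1L, hyper = list()) {
  stopifnot(inherits(model, "charsumm_model"), nrow(corpus) > 0L, steps >= 1L)
  hyper <- utils::modifyList(.default_pretrain_hyper(steps), hyper)
  cfg <- model$config
  table <- build_symbol_table()
  max_chars <- min(1350L, cfg$max_positions)
  set.seed(seed)

  draw_item <- function() {
    if (hyper$augment) {
      rec <- stitch_augment(corpus, k_max = hyper$k_max,
                            max_chars = max_chars)
    } else {
      rec <- corpus[sample(nrow(corpus), 1L), , drop = FALSE]
      rec$text <- substr(rec$text, 1L, max_chars)
    }
    rec$text
  }

  step_fn <- function(w, phase) {
    repeat {
      text <- draw_item()
      ids <- encode_text(text, table)
      ex <- if (phase == 1L) {
        corrupt_sequence(ids, table, mask_rate = hyper$mask_rate)
      } else {
        whole_word_corrupt(ids, segment_units(text, table), table,
                           word_rate = hyper$word_rate)
      }
      if (length(ex$mask_positions) > 0L) break
    }
    .mlm_step(w, cfg, ex)
  }

  phase_fn <- function(step, losses) {
    if (!is.null(hyper$phase2_step)) return(step >= hyper$phase2_step)
    win <- hyper$phase2_window
    if (step < 2L * win) return(FALSE)
    recent <- mean(losses[(step - win + 1L):step])
    previous <- mean(losses[(step - 2L * win + 1L):(step - win)])
    (previous - recent) < hyper$phase2_tol * abs(previous)
  }

  .train_loop(model, steps, hyper, step_fn, phase_fn)
}
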