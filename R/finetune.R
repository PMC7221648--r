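# Stage-2 fine-tuning: supervised per-character selection. The selection
# head and the full encoder are trained jointly (no freezing) on highlight
# labels, with the same stitching augmentation as pretraining plus 0.1%
# class-preserving typo injection for robustness.

#' Build a 0/1 label mask from highlight spans
#'
#' Characters inside any span are labeled '1', all others '0'. Spans are
#' 0-based half-open intervals and must be in range and non-overlapping.
#'
#' @param text The diagnosis string.
#' @param highlight_spans List of `c(start, end)` integer pairs (possibly
#'   empty).
#' @return A string of '0'/'1' of the same length as `text`.
#' @examples
#' align_label("1.Bladder cancer with", list(c(2, 17)))
#' # "001111111111111110000"
#' @export
align_label <- function(text, highlight_spans = list()) {
  n <- nchar(text)
  mask <- rep(0L, n)
  if (length(highlight_spans) > 0L) {
    spans <- do.call(rbind, lapply(highlight_spans, function(s) {
      stopifnot(length(s) == 2L)
      c(s[1], s[2])
    }))
    if (any(spans[, 1] < 0L) || any(spans[, 2] > n) ||
        any(spans[, 1] >= spans[, 2])) {
      stop("spans must be non-empty 0-based half-open intervals within the text")
    }
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    if (nrow(spans) > 1L &&
        any(spans[-1L, 1] < spans[-nrow(spans), 2])) {
      stop("spans overlap")
    }
    for (i in seq_len(nrow(spans))) {
      mask[(spans[i, 1] + 1L):spans[i, 2]] <- 1L
    }
  }
  paste(mask, collapse = "")
}

# "0110" -> c(0L, 1L, 1L, 0L)
.label_to_int <- function(label) {
  v <- as.integer(.chars(label))
  if (anyNA(v) || any(v < 0L | v > 1L)) stop("label must contain only 0/1")
  v
}

#' Selection loss
#'
#' Mean cross-entropy over *all* character positions of the two-way
#' selection head: `-log p(true class)` averaged over the sequence, with
#' selected and unselected positions contributing alike (no class
#' weighting, despite the ~15% positive rate of real highlights).
#'
#' @param logits `length x 2` matrix (column 2 = selected class).
#' @param labels 0/1 integer vector of the same length.
#' @return Non-negative scalar.
#' @export
selection_loss <- function(logits, labels) {
  if (nrow(logits) != length(labels)) {
    stop("logits and labels have different lengths")
  }
  stopifnot(ncol(logits) == 2L, all(labels %in% c(0L, 1L)))
  P <- .softmax_rows(logits)
  -mean(log(pmax(P[cbind(seq_along(labels), labels + 1L)], 1e-300)))
}

.default_finetune_hyper <- function(steps) {
  list(lr_warmup = 1e-5, lr_main = 1e-4, batch_size = 2L,
       warmup_steps = max(1L, round(0.1 * steps)),
       typo_rate = 0.001, k_max = 29L, augment = TRUE)
}

#' Fine-tune a pretrained model on highlight labels
#'
#' Continues training from a (normally pretrained) checkpoint, optimizing
#' [selection_loss()] jointly over the whole network. Each batch item is
#' built by stitching labeled records ([stitch_augment()], labels
#' concatenated exactly as the texts are) and then injecting typos at rate
#' `typo_rate` ([inject_typos()]; labels untouched). Optimizer schedule as
#' in [pretrain_loop()]. Seed-deterministic.
#'
#' @param model A `charsumm_model`.
#' @param labeled_corpus Corpus data.frame; every record must carry a
#'   label of the same length as its text (checked before training).
#' @param steps Number of optimization steps.
#' @param seed Integer seed.
#' @param hyper Overrides: `lr_warmup`, `lr_main`, `batch_size`,
#'   `warmup_steps`, `typo_rate` (0.001), `k_max` (29), `augment`.
#' @return The trained model with `model$log` as in [pretrain_loop()].
#' @export
finetune_loop <- function(model, labeled_corpus, steps, seed = 1L,
                          hyper = list()) {
  stopifnot(inherits(model, "charsumm_model"), nrow(labeled_corpus) > 0L,
            steps >= 1L)
  bad <- which(is.na(labeled_corpus$label) |
                 nchar(labeled_corpus$label) != nchar(labeled_corpus$text))
  if (length(bad) > 0L) {
    stop("records without a valid text-length label: rows ",
         paste(bad, collapse = ", "))
  }
  hyper <- utils::modifyList(.default_finetune_hyper(steps), hyper)
  cfg <- model$config
  table <- build_symbol_table()
  max_chars <- min(1350L, cfg$max_positions)
  set.seed(seed)

  draw_item <- function() {
    if (hyper$augment) {
      rec <- stitch_augment(labeled_corpus, k_max = hyper$k_max,
                            max_chars = max_chars)
    } else {
      rec <- labeled_corpus[sample(nrow(labeled_corpus), 1L), , drop = FALSE]
      rec$text <- substr(rec$text, 1L, max_chars)
      rec$label <- substr(rec$label, 1L, max_chars)
    }
    if (hyper$typo_rate > 0) rec <- inject_typos(rec, hyper$typo_rate, table)
    rec
  }

  step_fn <- function(w, phase) {
    rec <- draw_item()
    ids <- encode_text(rec$text, table)
    .sel_step(w, cfg, ids, .label_to_int(rec$label))
  }

  .train_loop(model, steps, hyper, step_fn)
}
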