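# Metrics and threshold calibration: character-level ROC/AUROC and F1,
# validation-set threshold choice, and word-level ROUGE-1/2/L with
# punctuation filtering.

#' ROC curve and AUROC
#'
#' Builds the ROC curve over all distinct score thresholds (descending)
#' and computes the area under it. The AUROC equals the probability that a
#' randomly chosen positive outscores a randomly chosen negative, with
#' ties counting one half (the Mann-Whitney statistic); it is computed by
#' the rank formula, which is exact under that tie convention.
#'
#' @param scores Numeric vector of predicted probabilities or scores.
#' @param labels 0/1 integer vector of the same length; both classes must
#'   be present.
#' @return A list of class `roc_curve`: `thresholds` (descending),
#'   `tpr`, `fpr` (non-decreasing along the curve, starting at 0,0) and
#'   `auroc`.
#' @examples
#' roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))$auroc  # 0.75
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  # cumulative counts at each distinct threshold (score >= t predicts 1)
  last_of_tie <- c(s[-1L] != s[-length(s)], TRUE)
  tp <- cumsum(y == 1L)[last_of_tie]
  fp <- cumsum(y == 0L)[last_of_tie]
  thresholds <- s[last_of_tie]
  tpr <- c(0, tp / n_pos)
  fpr <- c(0, fp / n_neg)
  r <- rank(scores)  # average ranks resolve ties as 1/2
  auroc <- (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  structure(list(thresholds = thresholds, tpr = tpr, fpr = fpr,
                 auroc = auroc),
            class = "roc_curve")
}

#' Character-level precision, recall and F1
#'
#' Counts over positions: precision = TP/(TP+FP), recall = TP/(TP+FN), F1
#' their harmonic mean; 0/0 ratios are 0 by convention.
#'
#' @param pred_mask,true_mask 0/1 vectors (or '0'/'1' strings) of equal
#'   length.
#' @return A list with `precision`, `recall`, `f1`.
#' @export
f1_binary <- function(pred_mask, true_mask) {
  if (is.character(pred_mask)) pred_mask <- .label_to_int(pred_mask)
  if (is.character(true_mask)) true_mask <- .label_to_int(true_mask)
  stopifnot(length(pred_mask) == length(true_mask),
            all(pred_mask %in% c(0L, 1L)), all(true_mask %in% c(0L, 1L)))
  tp <- sum(pred_mask == 1L & true_mask == 1L)
  fp <- sum(pred_mask == 1L & true_mask == 0L)
  fn <- sum(pred_mask == 0L & true_mask == 1L)
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1)
}

# Records longer than a network model's position window are truncated
# (text and label together), mirroring the training-time cap.
.fit_to_window <- function(model, records) {
  if (!inherits(model, "charsumm_model")) return(records)
  win <- model$config$max_positions
  long <- !is.na(records$text) & nchar(records$text) > win
  records$text[long] <- substr(records$text[long], 1L, win)
  has_lab <- long & !is.na(records$label)
  records$label[has_lab] <- substr(records$label[has_lab], 1L, win)
  records
}

# Pooled cleaned probabilities and labels over a labeled corpus.
.pool_predictions <- function(model, records) {
  stopifnot(nrow(records) > 0L)
  records <- .fit_to_window(model, records)
  probs <- vector("list", nrow(records))
  labs <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    text <- records$text[i]
    raw <- predict_probabilities(model, text)
    probs[[i]] <- cleanup(raw, segment_units(text))
    labs[[i]] <- .label_to_int(records$label[i])
  }
  list(probs = unlist(probs), labels = unlist(labs),
       per_record_probs = probs, per_record_labels = labs)
}

#' Choose the selection threshold on a validation set
#'
#' Pools the cleaned per-character probabilities over the labeled
#' validation records, evaluates character-level F1 at every distinct
#' observed probability, and returns the maximizer (ties broken toward
#' the larger threshold).
#'
#' @param model A `charsumm_model` or scoring function.
#' @param validation_set Labeled corpus data.frame; both classes must be
#'   present in the pooled labels. Records longer than a network model's
#'   position window are truncated (with their labels) before scoring.
#' @return The chosen threshold, with attributes `f1` (its pooled F1) and
#'   `sweep` (data.frame of all candidate thresholds and F1 values).
#' @export
choose_threshold <- function(model, validation_set) {
  pool <- .pool_predictions(model, validation_set)
  y <- pool$labels
  p <- pool$probs
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L) {
    stop("validation set is degenerate: needs both selected and unselected characters")
  }
  candidates <- sort(unique(p), decreasing = TRUE)
  # predicting p >= t: sweep descending so TP/FP accumulate
  ord <- order(p, decreasing = TRUE)
  ps <- p[ord]
  ys <- y[ord]
  last_of_tie <- c(ps[-1L] != ps[-length(ps)], TRUE)
  tp <- cumsum(ys == 1L)[last_of_tie]
  fp <- cumsum(ys == 0L)[last_of_tie]
  n_pos <- sum(y == 1L)
  precision <- ifelse(tp + fp == 0L, 0, tp / (tp + fp))
  recall <- tp / n_pos
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  best <- which(f1 == max(f1))[1L]  # candidates descend: first = largest t
  structure(candidates[best], f1 = f1[best],
            sweep = data.frame(threshold = candidates, f1 = f1))
}

#' Tokenize text for ROUGE scoring
#'
#' Lowercases, replaces every punctuation character by a space, splits on
#' whitespace and drops empty tokens. Digit runs survive as tokens.
#'
#' @param text A string.
#' @return Character vector of words (possibly empty).
#' @examples
#' tokenize_for_rouge("1.Bladder cancer with")  # "1" "bladder" "cancer" "with"
#' @export
tokenize_for_rouge <- function(text) {
  t <- tolower(text)
  t <- gsub("[^a-z0-9]+", " ", t)
  w <- strsplit(trimws(t), "\\s+")[[1L]]
  w[nzchar(w)]
}

.pr_f1 <- function(precision, recall) {
  f1 <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1)
}

#' ROUGE-N: clipped n-gram overlap
#'
#' Precision = clipped overlap / candidate n-gram count, recall = clipped
#' overlap / reference n-gram count, F1 their harmonic mean; empty
#' candidate or reference scores 0.
#'
#' @param candidate_words,reference_words Character vectors of words (from
#'   [tokenize_for_rouge()]).
#' @param n N-gram order (1 = unigrams, 2 = bigrams).
#' @return A list with `precision`, `recall`, `f1`.
#' @export
rouge_n <- function(candidate_words, reference_words, n = 1L) {
  stopifnot(n >= 1L)
  ngrams <- function(w) {
    if (length(w) < n) return(character(0))
    vapply(seq_len(length(w) - n + 1L), function(i) {
      paste(w[i:(i + n - 1L)], collapse = "\u1f")
    }, character(1))
  }
  cand <- ngrams(candidate_words)
  ref <- ngrams(reference_words)
  if (length(cand) == 0L || length(ref) == 0L) return(.pr_f1(0, 0))
  ct <- table(cand)
  rt <- table(ref)
  shared <- intersect(names(ct), names(rt))
  overlap <- sum(pmin(ct[shared], rt[shared]))
  .pr_f1(overlap / length(cand), overlap / length(ref))
}

# Longest-common-subsequence length by dynamic programming.
.lcs_length <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  if (na == 0L || nb == 0L) return(0L)
  prev <- integer(nb + 1L)
  for (i in seq_len(na)) {
    cur <- integer(nb + 1L)
    match_row <- a[i] == b
    for (j in seq_len(nb)) {
      cur[j + 1L] <- if (match_row[j]) prev[j] + 1L else {
        max(cur[j], prev[j + 1L])
      }
    }
    prev <- cur
  }
  prev[nb + 1L]
}

#' ROUGE-L: longest common subsequence of words
#'
#' Precision = LCS/|candidate|, recall = LCS/|reference|, F1 their
#' harmonic mean.
#'
#' @inheritParams rouge_n
#' @return A list with `precision`, `recall`, `f1`.
#' @export
rouge_l <- function(candidate_words, reference_words) {
  if (length(candidate_words) == 0L || length(reference_words) == 0L) {
    return(.pr_f1(0, 0))
  }
  lcs <- .lcs_length(candidate_words, reference_words)
  .pr_f1(lcs / length(candidate_words), lcs / length(reference_words))
}

#' Evaluate a model on a labeled test set
#'
#' Computes the pooled character-level AUROC of the cleaned probabilities
#' over all test characters, and per-record ROUGE-1/2/L F1 of the
#' extracted summary against the reference summary derived from the label
#' mask (both rendered by [extract_summary()] and tokenized by
#' [tokenize_for_rouge()]).
#'
#' @param model A `charsumm_model` or scoring function.
#' @param test_set Labeled corpus data.frame (non-empty).
#' @param threshold Selection threshold for the extracted summaries.
#' @return A list of class `evaluation_report`: `auroc`, `threshold`,
#'   `rouge` (named means), `per_record` (data.frame), `n_records`.
#' @export
evaluate_model <- function(model, test_set, threshold = 0.5) {
  if (nrow(test_set) == 0L) stop("empty test set")
  test_set <- .fit_to_window(model, test_set)
  pool <- .pool_predictions(model, test_set)
  auroc <- roc_auc(pool$probs, pool$labels)$auroc
  per <- data.frame(record = seq_len(nrow(test_set)),
                    rouge1 = numeric(nrow(test_set)),
                    rouge2 = numeric(nrow(test_set)),
                    rougeL = numeric(nrow(test_set)))
  for (i in seq_len(nrow(test_set))) {
    text <- test_set$text[i]
    mask <- threshold_select(pool$per_record_probs[[i]], threshold)
    cand <- tokenize_for_rouge(extract_summary(text, mask))
    ref <- tokenize_for_rouge(extract_summary(text, test_set$label[i]))
    per$rouge1[i] <- rouge_n(cand, ref, 1L)$f1
    per$rouge2[i] <- rouge_n(cand, ref, 2L)$f1
    per$rougeL[i] <- rouge_l(cand, ref)$f1
  }
  structure(list(auroc = auroc, threshold = threshold,
                 rouge = c(rouge1 = mean(per$rouge1),
                           rouge2 = mean(per$rouge2),
                           rougeL = mean(per$rougeL)),
                 per_record = per, n_records = nrow(test_set)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(paste0("<evaluation_report> %d records | AUROC %.4f | ",
                     "ROUGE-1 %.4f ROUGE-2 %.4f ROUGE-L %.4f ",
                     "(threshold %.3f)\n"),
              x$n_records, x$auroc, x$rouge["rouge1"], x$rouge["rouge2"],
              x$rouge["rougeL"], x$threshold))
  invisible(x)
}
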