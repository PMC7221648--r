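# Inference: per-character selection probabilities, word-average cleanup,
# thresholding and summary rendering.
#
# Character-level prediction can select fragments of words; the cleanup
# step replaces every character's probability inside a word unit by the
# unit's mean, so thresholding afterwards selects words whole or not at
# all.

#' Per-character selection probabilities
#'
#' Runs the fine-tuned model over a preprocessed text and returns the
#' selected-class probability for each character (deterministic: dropout
#' off). `model` may also be a plain function `text -> probabilities`,
#' which lets oracle scorers stand in for a trained network during
#' evaluation.
#'
#' @param model A `charsumm_model` or a function of the text.
#' @param text A single preprocessed string, at most `max_positions`
#'   characters (callers truncate via [preprocess()]).
#' @return Numeric vector in `[0, 1]`, one value per character.
#' @export
predict_probabilities <- function(model, text) {
  UseMethod("predict_probabilities")
}

#' @export
predict_probabilities.charsumm_model <- function(model, text) {
  ids <- encode_text(text)
  if (length(ids) > model$config$max_positions) {
    stop("input longer than max_positions; truncate with preprocess()")
  }
  unname(decoder_S(model, encode_sequence(model, ids))[, 2L])
}

#' @export
predict_probabilities.function <- function(model, text) {
  p <- model(text)
  stopifnot(length(p) == nchar(text), all(p >= 0 & p <= 1))
  p
}

#' Word-average probability cleanup
#'
#' Replaces each raw per-character probability inside a letter run, digit
#' run or punctuation unit by the arithmetic mean over that unit; space
#' runs keep their own raw values. The result is constant within each
#' non-space unit, so subsequent thresholding never selects a fragment of
#' a word.
#'
#' @param raw_probs Numeric vector of per-character probabilities.
#' @param units Word units from [segment_units()], tiling the vector.
#' @return Numeric vector of cleaned probabilities, same length.
#' @export
cleanup <- function(raw_probs, units) {
  n <- length(raw_probs)
  if (nrow(units) == 0L) {
    if (n == 0L) return(raw_probs)
    stop("units do not tile the probability vector")
  }
  if (units$end[nrow(units)] != n || units$start[1L] != 0L ||
      any(units$start[-1L] != units$end[-nrow(units)])) {
    stop("units do not tile the probability vector")
  }
  out <- raw_probs
  for (i in seq_len(nrow(units))) {
    if (units$kind[i] == "space_run") next
    span <- (units$start[i] + 1L):units$end[i]
    out[span] <- mean(raw_probs[span])
  }
  out
}

#' Threshold cleaned probabilities into a selection mask
#'
#' `mask[i] = 1` iff `clean_probs[i] >= threshold` (inclusive, so a
#' threshold of 1 still selects probability-1 positions).
#'
#' @param clean_probs Numeric vector of probabilities.
#' @param threshold Scalar in `[0, 1]`.
#' @return Integer 0/1 vector.
#' @export
threshold_select <- function(clean_probs, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  as.integer(clean_probs >= threshold)
}

# Accept masks as integer vectors or '0'/'1' strings.
.as_mask_int <- function(mask, n) {
  if (is.character(mask) && length(mask) == 1L) mask <- .label_to_int(mask)
  stopifnot(length(mask) == n, all(mask %in% c(0L, 1L)))
  as.integer(mask)
}

#' Render the selected characters as a summary string
#'
#' Concatenates the selected characters; each maximal run of unselected
#' characters between selections collapses to a single space, and leading
#' and trailing whitespace is stripped.
#'
#' @param text Source string.
#' @param mask 0/1 selection mask (integer vector or '0'/'1' string) of
#'   the same length.
#' @return The extracted summary string.
#' @export
extract_summary <- function(text, mask) {
  mask <- .as_mask_int(mask, nchar(text))
  if (all(mask == 0L)) return("")
  ch <- .chars(text)
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pieces <- character(length(r$values))
  pieces[r$values == 1L] <- vapply(which(r$values == 1L), function(i) {
    paste(ch[starts[i]:ends[i]], collapse = "")
  }, character(1))
  pieces[r$values == 0L] <- " "
  out <- paste(pieces, collapse = "")
  out <- gsub("^\\s+|\\s+$", "", out)
  gsub("\\s+", " ", out)
}

#' Summarize a diagnosis end to end
#'
#' Preprocesses the text, predicts per-character selection probabilities,
#' applies the word-average cleanup, thresholds, and renders the summary.
#'
#' @param model A `charsumm_model` (or scoring function).
#' @param text Free-text diagnosis (preprocessed internally).
#' @param threshold Selection threshold, typically from
#'   [choose_threshold()].
#' @return A list of class `summary_proposal`: `text`, `raw_probs`,
#'   `clean_probs`, `threshold`, `selected_mask`, `summary`.
#' @export
summarize_diagnosis <- function(model, text, threshold = 0.5) {
  text <- preprocess(text)
  raw <- predict_probabilities(model, text)
  units <- segment_units(text)
  clean <- cleanup(raw, units)
  mask <- threshold_select(clean, threshold)
  structure(list(text = text, raw_probs = raw, clean_probs = clean,
                 threshold = threshold, selected_mask = mask,
                 summary = extract_summary(text, mask)),
            class = "summary_proposal")
}

#' @export
print.summary_proposal <- function(x, ...) {
  cat(sprintf("<summary_proposal> threshold %.3f, %d/%d characters kept\n",
              x$threshold, sum(x$selected_mask), length(x$selected_mask)))
  cat("summary: ", x$summary, "\n", sep = "")
  invisible(x)
}
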