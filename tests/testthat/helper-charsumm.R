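# Shared fixtures: tiny model configurations and corpora small enough for
# fast unit tests. Everything is generated in code under fixed seeds.

tiny_config <- function(..., dropout = 0) {
  defaults <- list(n_layers = 1L, n_heads = 2L, hidden = 8L,
                   max_positions = 64L, dropout = dropout, seed = 2L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

tiny_corpus <- function(n = 10L, seed = 3L, max_chars = 64L) {
  corpus <- generate_corpus(n, seed = seed)
  corpus$text <- substr(corpus$text, 1L, max_chars)
  corpus$label <- substr(corpus$label, 1L, max_chars)
  corpus
}

# A scoring "model" that returns per-character probabilities from a lookup
# of known labels, optionally with noise; stands in for a trained network
# in metric tests.
oracle_scorer <- function(records, flip = 0) {
  env <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(records))) {
    assign(records$text[i], .label_ints(records$label[i]), envir = env)
  }
  function(text) {
    p <- as.numeric(get(text, envir = env))
    if (flip > 0) {
      k <- which(stats::runif(length(p)) < flip)
      p[k] <- 1 - p[k]
    }
    # keep strictly inside (0, 1) so thresholds behave
    0.02 + 0.96 * p
  }
}

.label_ints <- function(label) as.integer(strsplit(label, "")[[1L]])

# All-pairs Mann-Whitney AUROC, the independent oracle for roc_auc().
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Exhaustive longest-common-subsequence by enumerating every subsequence
# of the candidate; only viable for lists of <= 8 words.
lcs_bruteforce <- function(a, b) {
  is_subseq <- function(x, y) {
    j <- 1L
    for (el in x) {
      while (j <= length(y) && y[j] != el) j <- j + 1L
      if (j > length(y)) return(FALSE)
      j <- j + 1L
    }
    TRUE
  }
  best <- 0L
  for (m in seq_len(2^length(a)) - 1L) {
    sub <- a[bitwAnd(m, 2^(seq_along(a) - 1L)) > 0L]
    if (length(sub) > best && is_subseq(sub, b)) best <- length(sub)
  }
  best
}

random_preprocessed_string <- function(len, table = build_symbol_table()) {
  paste(sample(table$symbols, len, replace = TRUE), collapse = "")
}
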