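# Model definition: a small BERT-style Transformer encoder over character
# ids, with two affine output heads -- decoder A (hidden -> 100 symbol
# logits, for masked-character pretraining) and decoder S (hidden -> 2
# selection logits, for per-character extractive labeling).

#' Encoder configuration
#'
#' The reference configuration is a 16-layer encoder with 16 self-attention
#' heads and hidden size 64 over the 100-symbol character vocabulary, with
#' position embeddings for up to 1350 characters -- roughly one million
#' trainable parameters (see [count_parameters()]). Smaller configurations
#' are used for testing and desk-scale training.
#'
#' @param n_layers Number of encoder layers.
#' @param n_heads Self-attention heads; must divide `hidden`.
#' @param hidden Hidden size (embedding and encoder width).
#' @param vocab Vocabulary size (100 symbols).
#' @param max_positions Maximum input length (position-embedding rows).
#' @param ff_width Feed-forward inner width; defaults to `4 * hidden`, the
#'   standard Transformer convention (the reference description does not
#'   state it).
#' @param dropout Dropout probability applied in training mode to the
#'   embedding output and each sublayer output.
#' @param seed Seed used by [new_model()] for weight initialization.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_layers = 16L, n_heads = 16L, hidden = 64L,
                         vocab = 100L, max_positions = 1350L,
                         ff_width = 4L * hidden, dropout = 0.1,
                         seed = 1L) {
  stopifnot(n_layers >= 1L, n_heads >= 1L, hidden >= 1L,
            hidden %% n_heads == 0L, vocab >= 1L, max_positions >= 1L,
            ff_width >= 1L, dropout >= 0, dropout < 1)
  structure(list(n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 hidden = as.integer(hidden),
                 vocab = as.integer(vocab),
                 max_positions = as.integer(max_positions),
                 ff_width = as.integer(ff_width),
                 dropout = dropout, seed = as.integer(seed)),
            class = "model_config")
}

# Shapes of every trainable tensor, as a named list c(nrow, ncol); vectors
# are c(1, n). Single source of truth for init and parameter counting.
.weight_shapes <- function(cfg) {
  h <- cfg$hidden
  shapes <- list(
    tok_emb = c(cfg$vocab, h),
    pos_emb = c(cfg$max_positions, h),
    ln_emb_g = c(1L, h), ln_emb_b = c(1L, h)
  )
  for (l in seq_len(cfg$n_layers)) {
    nm <- sprintf("l%02d_", l)
    shapes[[paste0(nm, "Wq")]] <- c(h, h)
    shapes[[paste0(nm, "bq")]] <- c(1L, h)
    shapes[[paste0(nm, "Wk")]] <- c(h, h)
    shapes[[paste0(nm, "bk")]] <- c(1L, h)
    shapes[[paste0(nm, "Wv")]] <- c(h, h)
    shapes[[paste0(nm, "bv")]] <- c(1L, h)
    shapes[[paste0(nm, "Wo")]] <- c(h, h)
    shapes[[paste0(nm, "bo")]] <- c(1L, h)
    shapes[[paste0(nm, "ln1_g")]] <- c(1L, h)
    shapes[[paste0(nm, "ln1_b")]] <- c(1L, h)
    shapes[[paste0(nm, "W1")]] <- c(h, cfg$ff_width)
    shapes[[paste0(nm, "b1")]] <- c(1L, cfg$ff_width)
    shapes[[paste0(nm, "W2")]] <- c(cfg$ff_width, h)
    shapes[[paste0(nm, "b2")]] <- c(1L, h)
    shapes[[paste0(nm, "ln2_g")]] <- c(1L, h)
    shapes[[paste0(nm, "ln2_b")]] <- c(1L, h)
  }
  shapes$decA_W <- c(h, cfg$vocab)
  shapes$decA_b <- c(1L, cfg$vocab)
  shapes$decS_W <- c(h, 2L)
  shapes$decS_b <- c(1L, 2L)
  shapes
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars, with a per-component breakdown
#' (embeddings, embedding layer norm, encoder stack, decoder A, decoder S)
#' attached as attribute `"breakdown"`. For the reference configuration
#' this is 899,302 -- under one million, and more than 100 times smaller
#' than the ~108.5M-parameter word-piece BERT base it replaces. The
#' published figure for this architecture (963,496) is not exactly
#' reconcilable with the stated layer/head/hidden sizes under standard
#' conventions; this package documents its own count rather than forcing a
#' match.
#'
#' @param config A `model_config`.
#' @return Integer count, with attribute `breakdown` (named numeric).
#' @export
count_parameters <- function(config) {
  shapes <- .weight_shapes(config)
  sizes <- vapply(shapes, prod, numeric(1))
  nm <- names(sizes)
  breakdown <- c(
    embeddings = sum(sizes[nm %in% c("tok_emb", "pos_emb")]),
    embedding_layernorm = sum(sizes[nm %in% c("ln_emb_g", "ln_emb_b")]),
    encoder = sum(sizes[grepl("^l[0-9]", nm)]),
    decoder_A = sum(sizes[nm %in% c("decA_W", "decA_b")]),
    decoder_S = sum(sizes[nm %in% c("decS_W", "decS_b")])
  )
  structure(as.integer(sum(sizes)), breakdown = breakdown)
}

# Truncated-normal init (sd 0.02, clipped at 2 sd), BERT-style; layer-norm
# gains start at 1, all biases and layer-norm shifts at 0.
.init_tensor <- function(name, shape) {
  n <- prod(shape)
  if (grepl("ln.*_g$", name)) return(matrix(1, shape[1], shape[2]))
  if (grepl("(_b|ln.*_b)$", name) || grepl("^l[0-9]+_b", name) ||
      name %in% c("decA_b", "decS_b", "ln_emb_b")) {
    return(matrix(0, shape[1], shape[2]))
  }
  x <- stats::rnorm(n, 0, 0.02)
  x <- pmin(pmax(x, -0.04), 0.04)
  matrix(x, shape[1], shape[2])
}

#' Create a freshly initialized model
#'
#' Allocates all trainable tensors for `config` with seed-controlled
#' truncated-normal initialization (scale 0.02).
#'
#' @param config A `model_config`.
#' @return A list of class `charsumm_model` with elements `config`,
#'   `weights` (named list of matrices), `step` (training steps taken) and
#'   `version`.
#' @export
new_model <- function(config = model_config()) {
  set.seed(config$seed)
  shapes <- .weight_shapes(config)
  weights <- lapply(seq_along(shapes), function(i) {
    .init_tensor(names(shapes)[i], shapes[[i]])
  })
  names(weights) <- names(shapes)
  structure(list(config = config, weights = weights, step = 0L,
                 version = "charsumm-ckpt-1"),
            class = "charsumm_model")
}

#' @export
print.charsumm_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<charsumm_model> %d layers, %d heads, hidden %d, ",
                     "%s parameters, %d training steps\n"),
              cfg$n_layers, cfg$n_heads, cfg$hidden,
              format(count_parameters(cfg), big.mark = ","), x$step))
  invisible(x)
}

#' Input embeddings for an id sequence
#'
#' Sum of the learned token embedding (one row per symbol id) and the
#' learned position embedding (one row per offset), followed by layer
#' normalization -- the encoder input.
#'
#' @param model A `charsumm_model`.
#' @param ids Integer symbol ids (0-based), length at most
#'   `config$max_positions`.
#' @return A `length(ids) x hidden` matrix.
#' @export
embed <- function(model, ids) {
  .check_ids(model$config, ids)
  w <- model$weights
  X <- w$tok_emb[ids + 1L, , drop = FALSE] +
    w$pos_emb[seq_along(ids), , drop = FALSE]
  .ln_fwd(X, w$ln_emb_g, w$ln_emb_b)$Y
}

.check_ids <- function(cfg, ids) {
  if (length(ids) == 0L) stop("empty id sequence")
  if (length(ids) > cfg$max_positions) {
    stop(sprintf("sequence length %d exceeds max_positions %d",
                 length(ids), cfg$max_positions))
  }
  if (any(ids < 0L | ids >= cfg$vocab)) stop("id out of vocabulary range")
  invisible(TRUE)
}

#' Run the Transformer encoder
#'
#' Evaluation-mode forward pass (no dropout): embeddings followed by
#' `n_layers` blocks of multi-head self-attention and a GELU feed-forward
#' network, each with a residual connection and layer normalization.
#'
#' @inheritParams embed
#' @return A `length(ids) x hidden` matrix of final hidden states.
#' @export
encode_sequence <- function(model, ids) {
  .nn_forward(model$weights, model$config, ids, train = FALSE)$X
}

#' Masked-language-model head (decoder A)
#'
#' Affine map from hidden states to the 100 symbol logits; softmax rows
#' give per-position symbol probabilities.
#'
#' @param model A `charsumm_model`.
#' @param hidden_states Matrix from [encode_sequence()].
#' @return A `length x vocab` matrix of probabilities (rows sum to 1).
#' @export
decoder_A <- function(model, hidden_states) {
  logits <- .affine(hidden_states, model$weights$decA_W, model$weights$decA_b)
  .softmax_rows(logits)
}

#' Selection head (decoder S)
#'
#' Affine map from hidden states to two logits per character (not
#' selected / selected); softmax rows give the selection probability in
#' column 2.
#'
#' @inheritParams decoder_A
#' @return A `length x 2` matrix of probabilities (rows sum to 1).
#' @export
decoder_S <- function(model, hidden_states) {
  logits <- .affine(hidden_states, model$weights$decS_W, model$weights$decS_b)
  .softmax_rows(logits)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single binary archive carrying a version tag, the
#' configuration, all weight tensors and the step counter; optimizer state
#' is included when saved from a training loop, so training can resume.
#'
#' @param model A `charsumm_model`.
#' @param path File path (conventionally `.rds`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the model.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "charsumm_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "charsumm_model") ||
      !identical(model$version, "charsumm-ckpt-1")) {
    stop("not a recognized checkpoint: ", path)
  }
  model
}
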