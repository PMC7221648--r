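# Character vocabulary, preprocessing and word-unit segmentation.
#
# The tokenizer works on single characters: a fixed table of 100 retained
# symbols maps characters to integer ids 0..99. Everything downstream
# (masking, the selection model, probability cleanup) is defined over these
# ids, so the table is the single source of truth for the vocabulary.

# The canonical 100-symbol inventory. The published worked example pins
# ' '->0, '.'->11, '1'->14, 'B'->31, 'a'->57 and the table size; the rest of
# the layout (which punctuation marks fill the remaining slots, and where)
# is this package's frozen choice:
#   0       space
#   1-12    punctuation ('.' at 11)
#   13-22   digits '0'-'9'
#   23-29   punctuation
#   30-55   'A'-'Z'
#   56      '^' (the mask symbol)
#   57-82   'a'-'z'
#   83-99   remaining punctuation and clinical symbols (degree, plus-minus,
#           micro, en dash, multiplication sign)
.SYMBOLS <- c(
  " ",
  "!", "\"", "#", "$", "%", "&", "'", "(", ")", "*", ".", "+",
  as.character(0:9),
  ",", "-", "/", ":", ";", "<", "=",
  LETTERS,
  "^",
  letters,
  ">", "?", "@", "[", "\\", "]", "_", "`", "{", "|", "}", "~",
  "\u00b0", "\u00b1", "\u00b5", "\u2013", "\u00d7"  # degree, +-, micro, en dash, times
)

.symbol_classes <- function(symbols) {
  cls <- rep("punctuation", length(symbols))
  cls[symbols == " "] <- "space"
  cls[symbols %in% as.character(0:9)] <- "digit"
  cls[symbols %in% LETTERS] <- "uppercase"
  cls[symbols %in% letters] <- "lowercase"
  cls[symbols == "^"] <- "mask"
  cls
}

#' Build the canonical 100-symbol table
#'
#' Returns the fixed character vocabulary used throughout the package: 100
#' distinct symbols (space, punctuation, digits, both letter cases, and the
#' mask character `^`) in bijection with integer ids 0..99. The table also
#' records a character class for every symbol, used by the class-preserving
#' corruption rules (letters are only ever replaced by letters, digits by
#' digits, punctuation by punctuation).
#'
#' @return An object of class `symbol_table`: a list with `symbols`
#'   (character vector of length 100, position `i` holds the symbol with id
#'   `i - 1`), `ids` (named integer vector mapping symbol to id) and
#'   `classes` (named character vector mapping symbol to one of `"space"`,
#'   `"punctuation"`, `"digit"`, `"uppercase"`, `"lowercase"`, `"mask"`).
#' @examples
#' tab <- build_symbol_table()
#' tab$ids[["B"]]  # 31
#' @export
build_symbol_table <- function() {
  symbols <- .SYMBOLS
  stopifnot(length(symbols) == 100L, !anyDuplicated(symbols))
  ids <- stats::setNames(seq_along(symbols) - 1L, symbols)
  classes <- stats::setNames(.symbol_classes(symbols), symbols)
  structure(list(symbols = symbols, ids = ids, classes = classes),
            class = "symbol_table")
}

#' @export
print.symbol_table <- function(x, ...) {
  cat("<symbol_table> 100 symbols;",
      sum(x$classes == "punctuation"), "punctuation,",
      "10 digits, 52 letters, 1 space, 1 mask ('^')\n")
  invisible(x)
}

# Split a string into single characters ("" -> character(0)).
.chars <- function(text) {
  if (nchar(text) == 0L) return(character(0))
  strsplit(text, "", fixed = TRUE)[[1L]]
}

#' Normalize free text to the retained symbol set
#'
#' Replaces every character outside the 100-symbol table with a space,
#' preserves letter case, and truncates the result to `max_chars`
#' characters (1350 by default, the model's maximum input length).
#'
#' @param text Character vector of free-text diagnoses.
#' @param table A `symbol_table`, from [build_symbol_table()].
#' @param max_chars Maximum retained length; longer inputs are cut.
#' @return Character vector of the same length as `text`.
#' @examples
#' preprocess("Ab\u00a9C")  # "Ab C"
#' @export
preprocess <- function(text, table = build_symbol_table(), max_chars = 1350L) {
  vapply(text, function(t) {
    ch <- .chars(t)
    ch[!(ch %in% table$symbols)] <- " "
    if (length(ch) > max_chars) ch <- ch[seq_len(max_chars)]
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Encode preprocessed text as symbol ids
#'
#' Maps each character of `text` to its integer id in the symbol table.
#' The text must already be preprocessed: a character outside the table is
#' an error (reported with its offset), not silently replaced.
#'
#' @param text A single preprocessed string.
#' @param table A `symbol_table`.
#' @return Integer vector of ids in 0..99, one per character.
#' @examples
#' encode_text("1.B")  # c(14, 11, 31)
#' @export
encode_text <- function(text, table = build_symbol_table()) {
  stopifnot(is.character(text), length(text) == 1L)
  ch <- .chars(text)
  if (length(ch) == 0L) return(integer(0))
  ids <- table$ids[ch]
  if (anyNA(ids)) {
    bad <- which(is.na(ids))[1L]
    stop(sprintf("character '%s' at offset %d is not in the symbol table",
                 ch[bad], bad - 1L))
  }
  unname(ids)
}

#' Decode symbol ids back to text
#'
#' Inverse of [encode_text()]: maps each id in 0..99 to its character.
#'
#' @param ids Integer vector of symbol ids.
#' @param table A `symbol_table`.
#' @return A single string.
#' @export
decode_ids <- function(ids, table = build_symbol_table()) {
  if (length(ids) == 0L) return("")
  if (any(ids < 0L | ids > 99L | ids != trunc(ids))) {
    stop("ids must be integers in [0, 99]")
  }
  paste(table$symbols[ids + 1L], collapse = "")
}

#' Segment preprocessed text into word units
#'
#' Tiles the text with non-overlapping units: maximal runs of letters
#' (`letter_run`), maximal runs of digits (`digit_run`), maximal runs of
#' spaces (`space_run`), and every other character (punctuation and the
#' mask symbol) as its own singleton `punct` unit. These units are the
#' "words" over which whole-word masking and probability cleanup operate.
#'
#' @param text A single preprocessed string.
#' @param table A `symbol_table`.
#' @return A data.frame with columns `start` and `end` (0-based, half-open)
#'   and `kind`; the units tile `[0, nchar(text))` in order.
#' @examples
#' segment_units("1.Bladder cancer")  # "1" "." "Bladder" " " "cancer"
#' @export
segment_units <- function(text, table = build_symbol_table()) {
  ch <- .chars(text)
  n <- length(ch)
  empty <- data.frame(start = integer(0), end = integer(0),
                      kind = character(0))
  if (n == 0L) return(empty)
  cls <- unname(table$classes[ch])
  if (anyNA(cls)) stop("text contains characters outside the symbol table")
  grp <- cls
  grp[grp %in% c("uppercase", "lowercase")] <- "letter"
  grp[grp == "mask"] <- "punctuation"
  kind <- c(letter = "letter_run", digit = "digit_run",
            punctuation = "punct", space = "space_run")[grp]
  # punctuation never merges into runs; give each char a distinct run key
  key <- ifelse(kind == "punct", paste0("p", seq_len(n)), kind)
  run <- cumsum(c(TRUE, key[-1L] != key[-n]))
  start <- which(!duplicated(run)) - 1L
  end <- c(start[-1L], n)
  data.frame(start = start, end = end,
             kind = unname(kind[start + 1L]))
}

#' Write / read a symbol table as TSV
#'
#' Serializes the symbol-to-id mapping as a two-column UTF-8 TSV
#' (`symbol`, `id`) for external audit, and reads it back.
#'
#' @param table A `symbol_table`.
#' @param path File path.
#' @return `write_symbol_table` returns `path` invisibly;
#'   `read_symbol_table` returns a `symbol_table`.
#' @export
write_symbol_table <- function(table, path) {
  # no symbol contains a tab or newline, so raw unquoted lines are
  # unambiguous (quoting would mangle the '"' symbol itself)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("symbol\tid",
               paste0(table$symbols, "\t", unname(table$ids))),
             con, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_symbol_table
#' @export
read_symbol_table <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  stopifnot(identical(lines[1L], "symbol\tid"))
  body <- lines[-1L]
  tab_at <- regexpr("\t", body, fixed = TRUE)
  symbols <- substr(body, 1L, tab_at - 1L)
  ids <- as.integer(substring(body, tab_at + 1L))
  stopifnot(length(symbols) == 100L, identical(sort(ids), 0:99),
            all(nchar(symbols) == 1L))
  symbols <- symbols[order(ids)]
  structure(list(symbols = symbols,
                 ids = stats::setNames(0:99, symbols),
                 classes = stats::setNames(.symbol_classes(symbols), symbols)),
            class = "symbol_table")
}
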