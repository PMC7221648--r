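# Corpus file codecs. Corpora are UTF-8 JSON-lines: one object per line
# with fields text, label (nullable string of '0'/'1') and source, in that
# order. Free clinical text is full of commas and quotes, which makes
# JSON-lines a safer interchange format than CSV.

#' Read a JSON-lines corpus
#'
#' Parses and validates one record per line. Validation: fields present,
#' label (when not null) is a '0'/'1' string of the same length as the
#' text, and the text is a fixed point of [preprocess()] (no out-of-table
#' characters, length at most 1350). Failures report the line number.
#'
#' @param path Path to a `.jsonl` file.
#' @return A corpus data.frame with columns `text`, `label`, `source`.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) {
                      stop(sprintf("line %d: malformed JSON (%s)",
                                   i, conditionMessage(e)), call. = FALSE)
                    })
    if (is.null(obj$text) || !is.character(obj$text)) {
      stop(sprintf("line %d: missing text field", i), call. = FALSE)
    }
    label <- if (is.null(obj$label)) NA_character_ else obj$label
    if (!is.na(label)) {
      if (nchar(label) != nchar(obj$text)) {
        stop(sprintf("line %d: label length %d != text length %d",
                     i, nchar(label), nchar(obj$text)), call. = FALSE)
      }
      if (grepl("[^01]", label)) {
        stop(sprintf("line %d: label contains characters other than 0/1", i),
             call. = FALSE)
      }
    }
    if (!identical(preprocess(obj$text), obj$text)) {
      stop(sprintf("line %d: text is not preprocessed (out-of-table characters or over-length)", i),
           call. = FALSE)
    }
    recs[[i]] <- data.frame(text = obj$text, label = label,
                            source = if (is.null(obj$source))
                              NA_character_ else obj$source,
                            stringsAsFactors = FALSE)
  }
  if (length(recs) == 0L) {
    return(data.frame(text = character(0), label = character(0),
                      source = character(0)))
  }
  do.call(rbind, recs)
}

#' Write a corpus as JSON-lines
#'
#' One UTF-8 JSON object per line, newline-terminated, with deterministic
#' field order (`text`, `label`, `source`); missing labels serialize as
#' `null`. Round-trips exactly through [read_corpus()].
#'
#' @param records A corpus data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(records, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    obj <- list(text = records$text[i],
                label = records$label[i],
                source = records$source[i])
    line <- jsonlite::toJSON(obj, auto_unbox = TRUE, na = "null")
    writeLines(as.character(line), con, useBytes = TRUE)
  }
  invisible(path)
}
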