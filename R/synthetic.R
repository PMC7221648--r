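# Synthetic discharge-diagnosis corpus.
#
# The real corpora (hospital discharge diagnoses and ICD-10 strings) are
# private, so this module generates structurally similar text: numbered
# multi-item diagnosis lists mixing disease phrases, treatment clauses,
# dates, chemotherapy cycle counts and abbreviations. Highlight labels are
# produced by a deterministic rule -- exactly the characters of each item's
# disease phrase (including the single spaces inside a multi-word phrase)
# are labeled 1 -- so supervised learning has a recoverable signal.

.DISEASES <- c(
  "bladder cancer", "hepatocellular carcinoma", "colon adenocarcinoma",
  "lung adenocarcinoma", "breast cancer", "gastric cancer",
  "pancreatic cancer", "prostate cancer", "nasopharyngeal carcinoma",
  "acute myeloid leukemia", "diffuse large B cell lymphoma",
  "type 2 diabetes mellitus", "hypertension", "hyperlipidemia",
  "atrial fibrillation", "congestive heart failure",
  "acute myocardial infarction", "coronary artery disease",
  "chronic kidney disease", "end stage renal disease",
  "liver cirrhosis", "chronic hepatitis B", "chronic hepatitis C",
  "community acquired pneumonia", "aspiration pneumonia",
  "urinary tract infection", "acute pyelonephritis", "cellulitis",
  "infective endocarditis", "septic shock", "ischemic stroke",
  "intracerebral hemorrhage", "epilepsy", "parkinsonism",
  "chronic obstructive pulmonary disease", "bronchial asthma",
  "pulmonary tuberculosis", "peptic ulcer disease",
  "acute pancreatitis", "acute cholecystitis", "gouty arthritis",
  "rheumatoid arthritis", "major depressive disorder", "schizophrenia",
  "iron deficiency anemia", "deep vein thrombosis"
)

.TREATMENTS <- c(
  "transurethral resection", "radical nephrectomy", "chemotherapy",
  "concurrent chemoradiotherapy", "target therapy", "immunotherapy",
  "antibiotic treatment", "ceftriaxone treatment", "insulin therapy",
  "hemodialysis", "percutaneous coronary intervention",
  "coronary artery bypass grafting", "radiofrequency ablation",
  "transarterial chemoembolization", "laparoscopic cholecystectomy",
  "mechanical ventilation", "anticoagulant therapy", "steroid pulse therapy",
  "radiotherapy", "supportive care"
)

.MODIFIERS <- c(
  "stable", "improving", "in remission", "under regular follow up",
  "with acute exacerbation", "poorly controlled", "recently diagnosed",
  "with recurrence", "post operation", "under medical control"
)

.ABBREVS <- c("COPD", "CKD", "ESRD", "CAD", "DM", "HTN", "CHF", "AF",
              "UTI", "HCC", "AMI", "TB", "DVT", "GERD")

#' Parameters for the synthetic diagnosis generator
#'
#' Bundles the phrase vocabularies and structural settings used by
#' [generate_diagnosis()], [generate_icd_entry()] and the augmentation
#' operations. Defaults emulate numbered discharge-diagnosis lists: 1-6
#' items per record, each a capitalized disease phrase followed (usually)
#' by a status/treatment clause that may carry a date (`2019/05/21` style)
#' or a chemotherapy cycle count, plus occasional abbreviations.
#'
#' @param diseases,treatments,modifiers,abbreviations Character vectors of
#'   phrases. Diseases are the highlighted (label 1) spans.
#' @param max_items Maximum number of numbered items in one record.
#' @param p_clause Probability an item carries a treatment/status clause.
#' @param p_date Probability a clause carries a date; `p_cycle` likewise a
#'   cycle count (evaluated if no date drawn).
#' @param p_abbrev Probability a clause mentions an abbreviation.
#' @param typo_rate Default character-replacement rate for
#'   [inject_typos()] during fine-tuning augmentation (0.001 = 0.1%).
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(diseases = .DISEASES,
                             treatments = .TREATMENTS,
                             modifiers = .MODIFIERS,
                             abbreviations = .ABBREVS,
                             max_items = 6L,
                             p_clause = 0.8,
                             p_date = 0.4,
                             p_cycle = 0.3,
                             p_abbrev = 0.15,
                             typo_rate = 0.001) {
  stopifnot(length(diseases) > 0L, length(treatments) > 0L,
            length(modifiers) > 0L, max_items >= 1L)
  structure(list(diseases = diseases, treatments = treatments,
                 modifiers = modifiers, abbreviations = abbreviations,
                 max_items = max_items, p_clause = p_clause,
                 p_date = p_date, p_cycle = p_cycle, p_abbrev = p_abbrev,
                 typo_rate = typo_rate),
            class = "generator_params")
}

.capitalize <- function(s) {
  paste0(toupper(substr(s, 1L, 1L)), substring(s, 2L))
}

.random_date <- function() {
  sprintf("%04d/%02d/%02d", sample(2010:2020, 1L), sample(1:12, 1L),
          sample(1:28, 1L))
}

# One numbered item: "<n>.<Disease>" + optional clause. Returns text and
# the disease span (0-based, half-open) within the item.
.make_item <- function(n, params) {
  disease <- .capitalize(sample(params$diseases, 1L))
  prefix <- paste0(n, ".")
  clause <- ""
  if (stats::runif(1) < params$p_clause) {
    treat <- sample(params$treatments, 1L)
    part <- switch(sample(4L, 1L),
      paste0(" status post ", treat),
      paste0(" under ", treat),
      paste0(" with ", treat),
      paste0(", ", sample(params$modifiers, 1L)))
    if (stats::runif(1) < params$p_date) {
      part <- paste0(part, " on ", .random_date())
    } else if (stats::runif(1) < params$p_cycle) {
      part <- paste0(part, " cycle ", sample(1:12, 1L))
    }
    if (stats::runif(1) < params$p_abbrev) {
      part <- paste0(part, " (", sample(params$abbreviations, 1L), ")")
    }
    clause <- part
  }
  text <- paste0(prefix, disease, clause)
  span <- c(nchar(prefix), nchar(prefix) + nchar(disease))
  list(text = text, span = span)
}

.record <- function(text, label, source) {
  data.frame(text = text, label = if (is.null(label)) NA_character_ else label,
             source = source, stringsAsFactors = FALSE)
}

#' Generate one synthetic discharge diagnosis with highlight labels
#'
#' Produces a numbered multi-item diagnosis record. The label string marks
#' exactly the characters of each item's disease phrase with '1' and
#' everything else (numbering, clauses, dates, separating spaces between
#' items) with '0'. The text is a fixed point of [preprocess()].
#'
#' @param params A `generator_params` object.
#' @param n_items Number of numbered items; by default drawn uniformly
#'   from 1..`params$max_items`. Uses the current RNG state.
#' @return A one-row data.frame with columns `text`, `label`, `source`.
#' @export
generate_diagnosis <- function(params = generator_params(), n_items = NULL) {
  if (is.null(n_items)) n_items <- sample(params$max_items, 1L)
  texts <- character(n_items)
  labels <- character(n_items)
  for (i in seq_len(n_items)) {
    it <- .make_item(i, params)
    lab <- rep("0", nchar(it$text))
    lab[(it$span[1] + 1L):it$span[2]] <- "1"
    texts[i] <- it$text
    labels[i] <- paste(lab, collapse = "")
  }
  .record(paste(texts, collapse = " "),
          paste(labels, collapse = "0"),
          "synthetic_discharge")
}

#' Generate one synthetic ICD-style short diagnosis
#'
#' A short single-phrase diagnosis string (2-8 words): a disease phrase,
#' optionally with a status modifier. No numbering and no label -- these
#' records emulate the coded-catalogue strings used only for pretraining.
#'
#' @param params A `generator_params` object.
#' @return A one-row data.frame with `label = NA`.
#' @export
generate_icd_entry <- function(params = generator_params()) {
  nw <- function(s) lengths(gregexpr("[^ ]+", s))
  disease <- .capitalize(sample(params$diseases, 1L))
  phrase <- disease
  # keep the phrase at 2-8 words: single-word diseases always get a
  # modifier, longer ones only a modifier that still fits
  fits <- params$modifiers[nw(params$modifiers) <= 8L - nw(disease)]
  if (length(fits) > 0L && (nw(disease) < 2L || stats::runif(1) < 0.5)) {
    phrase <- paste0(disease, ", ", sample(fits, 1L))
  }
  .record(phrase, NULL, "synthetic_icd")
}

#' Generate a synthetic corpus
#'
#' Convenience wrapper drawing `n_discharge` labeled discharge-style
#' records and `n_icd` unlabeled ICD-style records under one seed.
#'
#' @param n_discharge,n_icd Record counts.
#' @param params A `generator_params` object.
#' @param seed Integer seed fixing the whole corpus.
#' @return A data.frame with columns `text`, `label`, `source`.
#' @export
generate_corpus <- function(n_discharge, n_icd = 0L,
                            params = generator_params(), seed = 1L) {
  set.seed(seed)
  recs <- c(
    lapply(seq_len(n_discharge), function(i) generate_diagnosis(params)),
    lapply(seq_len(n_icd), function(i) generate_icd_entry(params))
  )
  do.call(rbind, recs)
}

# Strip a leading "<digits>." numbering from a record's text/label.
.strip_numbering <- function(text, label) {
  m <- regmatches(text, regexpr("^[0-9]+\\.", text))
  if (length(m) == 1L && nchar(m) > 0L) {
    text <- substring(text, nchar(m) + 1L)
    if (!is.na(label)) label <- substring(label, nchar(m) + 1L)
  }
  list(text = text, label = label)
}

#' Stitch several diagnoses into one longer record
#'
#' The augmentation used for both training stages: draws `k` uniformly
#' from 1..`k_max` (29 by default), samples `k` records from `pool` with
#' replacement, renumbers their items sequentially ("1.", "2.", ...),
#' joins them with single spaces and truncates text and label together to
#' `max_chars`. If any constituent is labeled, unlabeled constituents
#' contribute all-zero labels; if none is, the result is unlabeled.
#'
#' Each sampled record is treated as one item: any existing leading
#' numbering is stripped before the new index is prefixed. Multi-item
#' constituents therefore keep their internal numbering; pools intended
#' for stitching are normally built from single-item records.
#'
#' @param pool A corpus data.frame (columns `text`, `label`, `source`).
#' @param k_max Upper bound of the uniform constituent-count draw.
#' @param max_chars Truncation length (1350, the model's input cap).
#' @param k Fix the constituent count instead of drawing it.
#' @return A one-row data.frame; attribute `k` records the constituent
#'   count drawn.
#' @export
stitch_augment <- function(pool, k_max = 29L, max_chars = 1350L, k = NULL) {
  stopifnot(nrow(pool) > 0L)
  if (is.null(k)) k <- sample(k_max, 1L)
  idx <- sample(nrow(pool), k, replace = TRUE)
  any_label <- any(!is.na(pool$label[idx]))
  texts <- character(k)
  labels <- character(k)
  for (j in seq_len(k)) {
    r <- .strip_numbering(pool$text[idx[j]], pool$label[idx[j]])
    prefix <- paste0(j, ".")
    texts[j] <- paste0(prefix, r$text)
    if (any_label) {
      lab <- if (is.na(r$label)) strrep("0", nchar(r$text)) else r$label
      labels[j] <- paste0(strrep("0", nchar(prefix)), lab)
    }
  }
  text <- paste(texts, collapse = " ")
  label <- if (any_label) paste(labels, collapse = "0") else NA_character_
  if (nchar(text) > max_chars) {
    text <- substr(text, 1L, max_chars)
    if (!is.na(label)) label <- substr(label, 1L, max_chars)
  }
  out <- .record(text, if (is.na(label)) NULL else label, "stitched")
  attr(out, "k") <- k
  out
}

#' Inject random typos, preserving character class
#'
#' Replaces each character independently with probability `rate` by a
#' uniformly chosen *different* symbol of the same replacement class
#' (letter to letter, digit to digit, punctuation to punctuation); spaces
#' and the mask symbol are never altered. Labels are untouched -- typo
#' robustness is trained by corrupting inputs, not targets.
#'
#' @param records A corpus data.frame (any number of rows).
#' @param rate Per-character replacement probability (default 0.001,
#'   i.e. 0.1% of characters).
#' @param table A `symbol_table`.
#' @return The records with corrupted `text`.
#' @export
inject_typos <- function(records, rate = 0.001, table = build_symbol_table()) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(records)
  pools <- .replacement_pools(table)
  records$text <- vapply(records$text, function(t) {
    ch <- .chars(t)
    if (length(ch) == 0L) return(t)
    hit <- which(stats::runif(length(ch)) < rate)
    for (i in hit) ch[i] <- .replace_same_class(ch[i], pools, table)
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  records
}

# Replacement classes: letters (both cases) / digits / punctuation.
# Spaces and '^' have no replacement pool and are returned unchanged.
.replacement_pools <- function(table) {
  cls <- table$classes
  list(letter = table$symbols[cls %in% c("uppercase", "lowercase")],
       digit = table$symbols[cls == "digit"],
       punctuation = table$symbols[cls == "punctuation"])
}

.replacement_class <- function(ch, table) {
  switch(table$classes[[ch]],
         uppercase = "letter", lowercase = "letter",
         digit = "digit", punctuation = "punctuation",
         NA_character_)
}

.replace_same_class <- function(ch, pools, table) {
  grp <- .replacement_class(ch, table)
  if (is.na(grp)) return(ch)
  pool <- setdiff(pools[[grp]], ch)
  sample(pool, 1L)
}

#' Split a corpus into training and validation sets
#'
#' Deterministic shuffled partition: `round(train_fraction * N)` records
#' go to training, the rest to validation; no record is lost or
#' duplicated.
#'
#' @param records A corpus data.frame.
#' @param train_fraction Fraction assigned to training (default 0.95, the
#'   pretraining split used for the reference corpus).
#' @param seed Integer seed for the shuffle.
#' @return A list with elements `train` and `validation`.
#' @export
split_corpus <- function(records, train_fraction = 0.95, seed = 1L) {
  n <- nrow(records)
  if (n < 2L) stop("need at least 2 records to split")
  stopifnot(train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  perm <- sample(n)
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  list(train = records[perm[seq_len(n_train)], , drop = FALSE],
       validation = records[perm[(n_train + 1L):n], , drop = FALSE])
}
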