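# End-to-end pipeline: synthesize -> split -> pretrain -> finetune ->
# calibrate threshold -> evaluate, with every intermediate artifact and a
# manifest written to an output directory. One global seed expands
# deterministically into per-stage seeds so a single knob reproduces the
# whole run.

#' Pipeline run configuration
#'
#' @param out_dir Output directory (created if missing).
#' @param config A `model_config` (use a small one for desk-scale runs).
#' @param params A `generator_params`.
#' @param n_discharge,n_icd Synthetic corpus sizes.
#' @param train_fraction Train share of the labeled records (0.95).
#' @param pretrain_steps,finetune_steps Optimization steps per stage.
#' @param pretrain_hyper,finetune_hyper Hyperparameter overrides passed to
#'   [pretrain_loop()] / [finetune_loop()].
#' @param seed Global seed; per-stage seeds are derived from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir,
                       config = model_config(n_layers = 2L, n_heads = 4L,
                                             hidden = 32L,
                                             max_positions = 320L),
                       params = generator_params(),
                       n_discharge = 500L, n_icd = 100L,
                       train_fraction = 0.95,
                       pretrain_steps = 2000L, finetune_steps = 2000L,
                       pretrain_hyper = list(), finetune_hyper = list(),
                       seed = 1L) {
  structure(list(out_dir = out_dir, config = config, params = params,
                 n_discharge = as.integer(n_discharge),
                 n_icd = as.integer(n_icd),
                 train_fraction = train_fraction,
                 pretrain_steps = as.integer(pretrain_steps),
                 finetune_steps = as.integer(finetune_steps),
                 pretrain_hyper = pretrain_hyper,
                 finetune_hyper = finetune_hyper,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Derived per-stage seeds, kept below 2^31.
.stage_seeds <- function(seed) {
  base <- as.double(seed)
  s <- ((base * 7919 + seq_len(6L) * 104729) %% 2147483629) + 1
  stats::setNames(as.integer(s),
                  c("synth", "split", "pretrain", "finetune",
                    "threshold", "evaluate"))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes the selected stages in order, reading each stage's inputs from
#' files under `rc$out_dir` written by its predecessors, so a run can be
#' resumed stage by stage. Artifacts: `corpus.jsonl` (all records),
#' `train.jsonl` / `validation.jsonl` (labeled split), `pretrained.rds`,
#' `finetuned.rds`, `threshold.json`, `report.json` and `manifest.json`.
#'
#' @param rc A `run_config`.
#' @param stages Character vector, a subset (in order) of
#'   `c("synth", "split", "pretrain", "finetune", "threshold",
#'   "evaluate")`.
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(rc, stages = c("synth", "split", "pretrain",
                                        "finetune", "threshold",
                                        "evaluate")) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(rc$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- .stage_seeds(rc$seed)
  p <- function(f) file.path(rc$out_dir, f)

  if ("synth" %in% stages) {
    .stage("synth", {
      corpus <- generate_corpus(rc$n_discharge, rc$n_icd, rc$params,
                                seed = seeds[["synth"]])
      write_corpus(corpus, p("corpus.jsonl"))
    })
  }
  if ("split" %in% stages) {
    .stage("split", {
      corpus <- read_corpus(p("corpus.jsonl"))
      labeled <- corpus[!is.na(corpus$label), , drop = FALSE]
      sp <- split_corpus(labeled, rc$train_fraction,
                         seed = seeds[["split"]])
      write_corpus(sp$train, p("train.jsonl"))
      write_corpus(sp$validation, p("validation.jsonl"))
    })
  }
  if ("pretrain" %in% stages) {
    .stage("pretrain", {
      corpus <- read_corpus(p("corpus.jsonl"))
      model <- new_model(rc$config)
      model <- pretrain_loop(model, corpus, rc$pretrain_steps,
                             seed = seeds[["pretrain"]],
                             hyper = rc$pretrain_hyper)
      save_checkpoint(model, p("pretrained.rds"))
    })
  }
  if ("finetune" %in% stages) {
    .stage("finetune", {
      model <- load_checkpoint(p("pretrained.rds"))
      train <- read_corpus(p("train.jsonl"))
      model <- finetune_loop(model, train, rc$finetune_steps,
                             seed = seeds[["finetune"]],
                             hyper = rc$finetune_hyper)
      save_checkpoint(model, p("finetuned.rds"))
    })
  }
  threshold <- NULL
  if ("threshold" %in% stages) {
    threshold <- .stage("threshold", {
      model <- load_checkpoint(p("finetuned.rds"))
      val <- read_corpus(p("validation.jsonl"))
      th <- choose_threshold(model, val)
      jsonlite::write_json(list(threshold = as.numeric(th),
                                f1 = attr(th, "f1")),
                           p("threshold.json"), auto_unbox = TRUE,
                           digits = NA)
      as.numeric(th)
    })
  }
  report <- NULL
  if ("evaluate" %in% stages) {
    report <- .stage("evaluate", {
      model <- load_checkpoint(p("finetuned.rds"))
      val <- read_corpus(p("validation.jsonl"))
      if (is.null(threshold)) {
        threshold <- jsonlite::fromJSON(p("threshold.json"))$threshold
      }
      rep <- evaluate_model(model, val, threshold)
      jsonlite::write_json(list(auroc = rep$auroc,
                                rouge = as.list(rep$rouge),
                                threshold = rep$threshold,
                                n_records = rep$n_records),
                           p("report.json"), auto_unbox = TRUE, digits = NA)
      rep
    })
  }

  cfg_json <- jsonlite::toJSON(unclass(rc$config), auto_unbox = TRUE)
  cfg_file <- p("config.json")
  writeLines(as.character(cfg_json), cfg_file)
  manifest <- list(
    seed = rc$seed,
    stage_seeds = as.list(seeds),
    config_md5 = unname(tools::md5sum(cfg_file)),
    stages = stages,
    metrics = if (is.null(report)) NULL else
      list(auroc = report$auroc, rouge = as.list(report$rouge),
           threshold = report$threshold),
    artifacts = list(corpus = "corpus.jsonl", train = "train.jsonl",
                     validation = "validation.jsonl",
                     pretrained = "pretrained.rds",
                     finetuned = "finetuned.rds",
                     threshold = "threshold.json", report = "report.json")
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
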