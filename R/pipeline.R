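#' Read a run configuration
#'
#' Run configurations are flat YAML documents holding every pipeline tunable
#' (simulation preset or input paths, association thresholds, embedding and
#' classifier parameters, output directory, master seed). Unknown keys are
#' rejected so typos fail fast.
#'
#' @param path YAML file, or a named list already in memory.
#' @return list of class `adr_run_config` with defaults filled in.
#' @export
read_run_config <- function(path) {
  raw <- if (is.list(path)) path else {
    if (!file.exists(path))
      abort_adr(sprintf("config file not found: %s", path), "adr_io_error")
    yaml::read_yaml(path)
  }
  defaults <- list(
    preset = NULL, corpus = NULL, drug_lexicon = NULL, adr_lexicon = NULL,
    stop_lexicon = NULL, out_dir = NULL, seed = 1,
    min_support = 0.01, min_confidence = 0.6,
    embedding_dim = 300, embedding_window = 5, embedding_min_count = 1,
    embedding_epochs = 5,
    architecture = "bilstm", hidden_units = 256, learning_rate = 0.001,
    batch_size = 64, epochs = 50, threshold = 0.5, split_ratio = 0.7,
    early_stopping = FALSE, freeze_embeddings = FALSE, dropout = 0,
    n_posts = NULL)
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0)
    abort_adr(sprintf("unknown config keys: %s", paste(unknown, collapse = ", ")),
              "adr_validation_error")
  cfg <- utils::modifyList(defaults, raw[!vapply(raw, is.null, logical(1))])
  if (is.null(cfg$preset) &&
      (is.null(cfg$corpus) || is.null(cfg$drug_lexicon) ||
       is.null(cfg$adr_lexicon) || is.null(cfg$stop_lexicon)))
    abort_adr(paste("config must give either a simulation preset or paths to",
                    "a corpus and all three lexicons"),
              "adr_validation_error")
  structure(cfg, class = c("adr_run_config", "list"))
}

#' Run the full ADR post-detection pipeline
#'
#' Executes the fixed stage order: acquire (simulate a preset or read the
#' configured corpus and lexicons), preprocess, build transactions, mine
#' drug-to-ADR rules, filter posts to those containing a significant pair,
#' train skip-gram embeddings on the filtered posts, train the recurrent
#' classifier on the labeled filtered posts (7:3 stratified split), and
#' evaluate on the held-out test set. All stage artifacts are written under
#' `out_dir` and a run report with internally consistent counts is returned
#' and saved as JSON. All randomness is derived from the single master seed.
#'
#' @param config path to a YAML run configuration, or a named list
#'   (see [read_run_config()]).
#' @return list of class `adr_run_report`; see Details for fields.
#' @export
run_pipeline <- function(config) {
  cfg <- read_run_config(config)
  out_dir <- cfg$out_dir %||% tempfile("adr_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(config = unclass(cfg), seed = cfg$seed, stages = list(),
                 timings = list())
  t_stage <- function(expr, name) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) abort_adr(
      sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
      "adr_stage_error"))
    report$timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }

  # 1. acquire
  acq <- t_stage({
    if (!is.null(cfg$preset)) {
      gcfg <- preset_config(cfg$preset, seed = derive_seed(cfg$seed, 1L))
      if (!is.null(cfg$n_posts)) {
        prev <- if (cfg$preset == "geworin_like") 0.2796 else 0.424
        gcfg <- generator_config(n_posts = cfg$n_posts, adr_prevalence = prev,
                                 seed = derive_seed(cfg$seed, 1L))
      }
      bundle <- generate(gcfg)
      write_bundle(bundle, file.path(out_dir, "simulate"))
      list(corpus = bundle$corpus, drug = bundle$drug_lexicon,
           adr = bundle$adr_lexicon, stop = bundle$stop_lexicon,
           annotators = bundle$annotator_labels)
    } else {
      list(corpus = read_corpus(cfg$corpus),
           drug = load_lexicon(cfg$drug_lexicon, "drug"),
           adr = load_lexicon(cfg$adr_lexicon, "adr"),
           stop = load_lexicon(cfg$stop_lexicon, "stopword"),
           annotators = NULL)
    }
  }, "acquire")
  report$stages$posts_read <- length(acq$corpus)

  # 2. preprocess
  toks <- t_stage(preprocess_corpus(acq$corpus, acq$drug, acq$adr, acq$stop),
                  "preprocess")
  report$stages$excluded_empty <- attr(toks, "n_excluded_empty")
  write_tokens(toks, file.path(out_dir, "tokens.jsonl"))

  # 3-4. association mining and filtering
  trans <- t_stage(build_transactions(toks), "transactions")
  report$stages$transactions <- length(trans)
  report$stages$untagged_posts <- attr(trans, "n_omitted")
  rules <- t_stage(mine_rules(trans, cfg$min_support, cfg$min_confidence),
                   "mine")
  report$stages$rules_found <- nrow(rules)
  write_rules(rules, file.path(out_dir, "rules.tsv"))
  filtered <- t_stage(filter_posts(toks, rules), "filter")
  report$stages$posts_retained <- attr(filtered, "n_retained")
  report$stages$posts_dropped <- attr(filtered, "n_dropped")
  write_tokens(filtered, file.path(out_dir, "filtered.jsonl"))

  # 5. embeddings on the filtered posts
  emb <- t_stage(train_embeddings(filtered, dim = cfg$embedding_dim,
                                  window = cfg$embedding_window,
                                  min_count = cfg$embedding_min_count,
                                  epochs = cfg$embedding_epochs,
                                  seed = derive_seed(cfg$seed, 3L)),
                 "embed")
  write_embeddings(emb, file.path(out_dir, "vectors.txt"))

  # 6. classifier on the labeled filtered posts
  labeled <- structure(Filter(function(tp) !is.na(tp$label), filtered),
                       class = "adr_tokens_list")
  report$stages$labeled_posts <- length(labeled)
  mcfg <- model_config(architecture = cfg$architecture,
                       hidden_units = cfg$hidden_units,
                       embedding_dim = cfg$embedding_dim,
                       learning_rate = cfg$learning_rate,
                       batch_size = cfg$batch_size, epochs = cfg$epochs,
                       threshold = cfg$threshold, split_ratio = cfg$split_ratio,
                       seed = derive_seed(cfg$seed, 4L),
                       early_stopping = cfg$early_stopping,
                       freeze_embeddings = cfg$freeze_embeddings,
                       dropout = cfg$dropout)
  res <- t_stage({
    enc <- build_vocabulary(labeled)
    encoded <- encode_and_pad(labeled, enc)
    parts <- split_train_test(encoded, ratio = cfg$split_ratio,
                              seed = derive_seed(cfg$seed, 5L))
    model <- train_classifier(parts$train, mcfg, init_vectors = emb)
    scores <- predict_proba(model, parts$test)
    list(model = model, parts = parts, scores = scores)
  }, "train")
  report$stages$train_size <- length(res$parts$train$label)
  report$stages$test_size <- length(res$parts$test$label)
  utils::write.csv(res$model$training_log,
                   file.path(out_dir, "training_log.csv"), row.names = FALSE)

  # 7. evaluate
  ev <- t_stage(evaluate_scores(res$parts$test$label, res$scores,
                                threshold = cfg$threshold),
                "evaluate")
  report$evaluation <- list(
    confusion = ev$confusion[c("tp", "fp", "fn", "tn")],
    metrics = ev$metrics, auc = ev$auc,
    accuracy_by_threshold = ev$roc$accuracy_by_threshold)
  if (!is.null(acq$annotators))
    report$evaluation$annotator_kappa <-
      cohens_kappa(acq$annotators[, 1], acq$annotators[, 2])

  validate_report_counts(report)
  class(report) <- "adr_run_report"
  jsonlite::write_json(unclass(report)[setdiff(names(report), "config")],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report$out_dir <- out_dir
  invisible(report)
}

validate_report_counts <- function(report) {
  s <- report$stages
  if (s$posts_retained + s$posts_dropped !=
      s$posts_read - s$excluded_empty)
    abort_adr("run report counts inconsistent at the filtering stage",
              "adr_internal_error")
  invisible(TRUE)
}

#' @export
print.adr_run_report <- function(x, ...) {
  s <- x$stages
  cat("<adr_run_report>\n")
  cat(sprintf("  posts read       %d (%d excluded empty)\n",
              s$posts_read, s$excluded_empty))
  cat(sprintf("  transactions     %d, rules %d\n", s$transactions, s$rules_found))
  cat(sprintf("  filter           %d retained / %d dropped\n",
              s$posts_retained, s$posts_dropped))
  cat(sprintf("  split            %d train / %d test\n", s$train_size, s$test_size))
  m <- x$evaluation$metrics
  cat(sprintf("  test accuracy    %.3f  (AUC %.3f)\n", m$accuracy,
              x$evaluation$auc))
  invisible(x)
}
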