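# Orchestration: stratified five-fold cross-validation, end-to-end
# experiment runs, structured logging.

# continuous round-robin fold assignment across classes: folds stay
# balanced overall (sizes differ by at most 1) and per class
stratified_folds <- function(y, k = 5, seed = 1L) {
  y <- as.character(y)
  classes <- sort(unique(y))
  too_small <- classes[vapply(classes, function(cl) sum(y == cl), 0L) < k]
  if (length(too_small)) {
    tn_stop("data_error", "class '%s' has fewer than %d records", too_small[1], k)
  }
  fold <- integer(length(y))
  withr::with_seed(seed, {
    counter <- 0L
    for (cl in classes) {
      idx <- sample(which(y == cl))
      fold[idx] <- ((counter + seq_along(idx) - 1L) %% k) + 1L
      counter <- counter + length(idx)
    }
  })
  fold
}

#' Stratified five-fold cross-validation of the deep RBF classifier
#'
#' Partitions the training data into five label-stratified folds (sizes
#' differing by at most one, seeded assignment); in each of the five
#' iterations four parts train a fresh network and the held-out part is
#' scored, giving a per-fold [classification_metrics()] report plus the
#' across-fold mean and standard deviation of every metric.
#'
#' @param x Feature matrix.
#' @param y Labels (two classes, each with at least 5 members).
#' @param config An [rbf_config()]; fold fits derive their seeds from
#'   `seed`.
#' @param k Number of folds (default 5).
#' @param seed Seed for fold assignment and fold-fit seeds.
#' @return List with `folds` (per-fold metric reports), `fold_ids`
#'   (fold membership of every record), `summary` (data.frame of mean and
#'   sd per metric) and `accuracies`.
#' @export
fivefold_cv <- function(x, y, config = rbf_config(), k = 5, seed = 1L) {
  if (is.null(dim(x))) x <- as.matrix(x)
  y <- as.character(y)
  fold <- stratified_folds(y, k, seed)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    cfg <- config
    cfg$seed <- derive_seed(seed, f)
    fit <- deep_rbfnn(x[fold != f, , drop = FALSE], y[fold != f], cfg)
    pred <- predict(fit, x[fold == f, , drop = FALSE])
    reports[[f]] <- classification_metrics(confusion_matrix(pred, y[fold == f]))
  }
  metric_names <- names(reports[[1]])
  tab <- vapply(reports, function(r) unlist(r[metric_names]), numeric(length(metric_names)))
  summary <- data.frame(
    metric = metric_names,
    mean = rowMeans(tab),
    sd = apply(tab, 1, stats::sd)
  )
  list(folds = reports, fold_ids = fold, summary = summary,
       accuracies = unname(tab["accuracy", ]))
}

# ---- run configuration -----------------------------------------------------

#' Read an experiment run configuration
#'
#' Parses a JSON (or YAML, by extension) run configuration with the
#' sections: `cohort` (either `path` to a feature table or `spec` fields
#' for [cohort_spec()] — `effects` may name one of
#' `"default"/"null"/"strong"` or give a per-feature offset map),
#' `network` ([rbf_config()] fields), `train_fraction`, `encoding`
#' (`"ordinal"`/`"severity"`), `crossval` (logical),
#' `compare_hidden_layers` (optional alternative architecture for a 5x2 CV
#' comparison), `seed`, `out_dir` and `log_level` (`"info"`/`"debug"`).
#' Missing fields take the reference defaults.
#'
#' @param path Configuration file (`.json`, `.yaml` or `.yml`).
#' @return A validated `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) tn_stop("config_error", "no such config file: %s", path)
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      tn_stop("config_error", "YAML configs need the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  as_run_config(raw)
}

#' @rdname read_run_config
#' @param config A plain list with the fields above (e.g. parsed by hand).
#' @export
as_run_config <- function(config) {
  cfg <- config %||% list()
  seed <- as.integer(cfg$seed %||% 1L)
  net_fields <- cfg$network %||% list()
  net_args <- net_fields[intersect(names(net_fields), names(formals(rbf_config)))]
  network <- do.call(rbf_config, net_args)
  if (is.null(net_fields$seed)) network$seed <- derive_seed(seed, 7L)
  structure(list(
    cohort = cfg$cohort %||% list(),
    network = network,
    train_fraction = cfg$train_fraction %||% 0.7,
    encoding = match.arg(cfg$encoding %||% "ordinal", c("ordinal", "severity")),
    crossval = isTRUE(cfg$crossval %||% TRUE),
    compare_hidden_layers = cfg$compare_hidden_layers,
    seed = seed,
    out_dir = cfg$out_dir %||% "tonguenet-run",
    log_level = match.arg(cfg$log_level %||% "info", c("info", "debug"))
  ), class = "run_config")
}

resolve_effects <- function(effects) {
  if (is.null(effects)) return(effect_model_default())
  if (is.character(effects) && length(effects) == 1) {
    return(switch(effects,
                  default = effect_model_default(),
                  null = effect_model_null(),
                  strong = effect_model_strong(),
                  tn_stop("config_error", "unknown effect model '%s'", effects)))
  }
  lapply(effects, unlist)
}

cohort_spec_from_config <- function(spec_cfg, seed) {
  args <- list(
    n_total = spec_cfg$n_total %||% 2675,
    n_dm = spec_cfg$n_dm %||% 1658,
    effects = resolve_effects(spec_cfg$effects),
    sampling = spec_cfg$sampling %||% "quota",
    include_phase = isTRUE(spec_cfg$include_phase),
    seed = spec_cfg$seed %||% seed
  )
  if (!is.null(spec_cfg$marginals)) args$marginals <- lapply(spec_cfg$marginals, unlist)
  do.call(cohort_spec, args)
}

# short stable config fingerprint for error messages and the run log
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

make_logger <- function(path, level = "info") {
  threshold <- if (level == "debug") 2L else 1L
  function(lvl, ...) {
    pri <- if (lvl == "debug") 2L else 1L
    if (pri <= threshold) {
      kv <- paste(vapply(list(...), as.character, ""), collapse = " ")
      cat(sprintf("%s level=%s %s\n", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  lvl, kv), file = path, append = TRUE)
    }
    invisible(NULL)
  }
}

run_stage <- function(stage, hash, expr) {
  tryCatch(expr, tonguenet_error = function(e) {
    e$message <- sprintf("[stage %s, config %s] %s", stage, hash, e$message)
    stop(e)
  }, error = function(e) {
    tn_stop("stage_error", "[stage %s, config %s] %s", stage, hash,
            conditionMessage(e))
  })
}

#' Run a full tongue-diagnosis experiment
#'
#' Executes the pipeline described by a run configuration: simulate the
#' cohort (or load one from file), encode the records, make the stratified
#' 70/30 train/test split, pretrain and fine-tune the deep RBF network,
#' evaluate on the held-out test set, trace the ROC curve, optionally run
#' stratified five-fold cross-validation on the training portion and an
#' optional 5x2 CV comparison against an alternative architecture. Every
#' artifact is written to the output directory:
#' `config.json`, `cohort.csv` (if simulated), `split.json`, `model.json`,
#' `metrics.json` / `metrics.tsv`, `roc.csv`, `epochs.tsv` (per-epoch MSE
#' trace), `folds.json` (if cross-validating), `comparison.json` (if
#' comparing) and a structured `run.log`. Reruns with the same
#' configuration produce identical numbers.
#'
#' @param config A `run_config` (see [read_run_config()] /
#'   [as_run_config()]).
#' @return The output directory path, invisibly; the in-memory results are
#'   attached as attribute `"results"`.
#' @export
run_experiment <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  hash <- config_hash(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- make_logger(file.path(out, "run.log"), config$log_level)
  log("info", paste0("event=start config_hash=", hash))
  jsonlite::write_json(unclass(config), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  cohort <- run_stage("cohort", hash, {
    if (!is.null(config$cohort$path)) {
      read_feature_table(config$cohort$path, require_label = TRUE)
    } else {
      spec <- cohort_spec_from_config(config$cohort$spec %||% list(), config$seed)
      records <- simulate_cohort(spec)
      write_feature_table(records, file.path(out, "cohort.csv"))
      records
    }
  })
  log("info", paste0("event=cohort n=", nrow(cohort)))

  enc <- run_stage("encode", hash, encode_records(cohort, config$encoding))
  labels <- attr(enc, "label")
  if (is.null(labels)) tn_stop("data_error", "cohort has no labels")

  split <- run_stage("split", hash,
                     split_cohort(cohort, config$train_fraction, config$seed))
  split_counts <- lapply(split, function(part) as.list(table(part$label)))
  jsonlite::write_json(list(train = split_counts$train, test = split_counts$test),
                       file.path(out, "split.json"), auto_unbox = TRUE, pretty = TRUE)
  log("info", sprintf("event=split train_dm=%d train_non_dm=%d test_dm=%d test_non_dm=%d",
                      sum(split$train$label == "DM"), sum(split$train$label == "non_DM"),
                      sum(split$test$label == "DM"), sum(split$test$label == "non_DM")))

  x_train <- encode_records(split$train, config$encoding)
  x_test <- encode_records(split$test, config$encoding)

  net <- run_stage("fit", hash,
                   deep_rbfnn(x_train, split$train$label, config$network))
  save_model(net, file.path(out, "model.json"))
  trace <- data.frame(epoch = seq_along(net$report$mse), mse = net$report$mse)
  utils::write.table(trace, file.path(out, "epochs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(trace))) {
    log("debug", sprintf("event=epoch epoch=%d mse=%.8g", trace$epoch[i], trace$mse[i]))
  }
  log("info", sprintf("event=fit epochs=%d final_mse=%.8g converged=%s settled=%s",
                      net$report$epochs_run, net$report$final_train_mse,
                      net$report$converged, net$report$settled))

  results <- run_stage("evaluate", hash, {
    pred <- predict(net, x_test)
    scores <- predict(net, x_test, type = "score")
    cm <- confusion_matrix(pred, split$test$label)
    metrics <- classification_metrics(cm)
    roc <- roc_curve(scores[, "DM"], split$test$label)
    write_metric_report(list(deep_rbfnn = metrics),
                        file.path(out, "metrics.json"),
                        file.path(out, "metrics.tsv"))
    utils::write.table(roc$points, file.path(out, "roc.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    list(confusion = cm, metrics = metrics, roc = roc)
  })
  log("info", sprintf("event=evaluate accuracy=%.4f auc=%.4f",
                      results$metrics$accuracy, results$roc$auc))

  if (isTRUE(config$crossval)) {
    cv <- run_stage("crossval", hash,
                    fivefold_cv(x_train, split$train$label, config$network,
                                seed = derive_seed(config$seed, 11L)))
    jsonlite::write_json(list(summary = cv$summary, accuracies = cv$accuracies),
                         file.path(out, "folds.json"), digits = NA, pretty = TRUE)
    results$crossval <- cv
    log("info", sprintf("event=crossval mean_accuracy=%.4f",
                        mean(cv$accuracies)))
  }

  if (!is.null(config$compare_hidden_layers)) {
    cmp <- run_stage("compare", hash, {
      alt_cfg <- config$network
      alt_cfg$hidden_layers <- as.integer(unlist(config$compare_hidden_layers))
      main_factory <- function(x, y, s) {
        cfg <- config$network; cfg$seed <- s
        deep_rbfnn(x, y, cfg)
      }
      alt_factory <- function(x, y, s) {
        cfg <- alt_cfg; cfg$seed <- s
        deep_rbfnn(x, y, cfg)
      }
      five_by_two_cv(main_factory, alt_factory, x_train, split$train$label,
                     seed = derive_seed(config$seed, 13L))
    })
    write_cv_comparison(cmp, file.path(out, "comparison.json"))
    results$comparison <- cmp
    log("info", sprintf("event=compare p=%.4f decision=%s", cmp$p_value,
                        gsub(" ", "_", cmp$decision)))
  }

  log("info", "event=done")
  invisible(structure(out, results = results))
}
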