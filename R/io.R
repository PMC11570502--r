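# Delimited-text I/O (comma-separated, header row, "." decimal, UTF-8),
# schema validation, YAML pipeline configuration, and the driver tying the
# stages together: simulate -> classify -> segment -> grammar -> stats.

read_validated <- function(path, required, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  missing <- setdiff(required, names(d))
  if (length(missing))
    stop("schema error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  rejected <- rep(FALSE, nrow(d))
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    rejected <- rejected | (is.na(v) & !is.na(d[[col]]))
    d[[col]] <- v
  }
  if (any(rejected))
    warning(sum(rejected), " row(s) rejected in ", basename(path),
            " (unparseable numeric field)", call. = FALSE)
  structure(d[!rejected, , drop = FALSE],
            validation = list(n_read = nrow(d), n_rejected = sum(rejected)))
}

#' Read a call table from CSV
#'
#' Columns: `trial_id`, `call_index`, `onset_s`, `duration_s`,
#' `max_freq_khz`, and optionally `true_type` / `assigned_type`. Rows are
#' sorted by onset within trial; rows with unparseable numeric fields are
#' rejected with a warning.
#'
#' @param path CSV file path.
#' @return data.frame with the in-memory column names (`onset`, `duration`,
#'   `max_frequency`).
#' @export
read_calls <- function(path) {
  d <- read_validated(path,
                      c("trial_id", "call_index", "onset_s", "duration_s",
                        "max_freq_khz"),
                      c("call_index", "onset_s", "duration_s", "max_freq_khz"))
  names(d)[match(c("onset_s", "duration_s", "max_freq_khz"), names(d))] <-
    c("onset", "duration", "max_frequency")
  if (any(d$duration <= 0) || any(d$max_frequency <= 0))
    stop("durations and frequencies must be positive", call. = FALSE)
  d <- d[order(d$trial_id, d$onset), ]
  rownames(d) <- NULL
  d
}

#' Read a trial table from CSV
#'
#' Columns: `trial_id`, `dataset`, `stimulus`, `mode`, `elevation`,
#' `group_location`, optionally `responded`.
#'
#' @param path CSV file path.
#' @return data.frame of trials.
#' @export
read_trials <- function(path) {
  d <- read_validated(path,
                      c("trial_id", "stimulus", "mode", "elevation",
                        "group_location"), character(0))
  bad <- (d$stimulus == "tree" | d$mode == "visual_model") !=
    (d$elevation == "none")
  if (any(bad))
    warning(sum(bad), " trial(s) violate the elevation convention ",
            "(elevation 'none' iff falling-tree stimulus or visual model)",
            call. = FALSE)
  d
}

#' Write a corpus to calls.csv and trials.csv
#'
#' Inverse of [read_calls()]/[read_trials()]: comma-separated, header row,
#' UTF-8, "." decimal.
#'
#' @param corpus a `"callgram_corpus"` (or list with `calls` and `trials`).
#' @param dir output directory (created if needed).
#' @return named character vector of the two file paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls <- corpus$calls
  names(calls)[match(c("onset", "duration", "max_frequency"), names(calls))] <-
    c("onset_s", "duration_s", "max_freq_khz")
  paths <- c(calls = file.path(dir, "calls.csv"),
             trials = file.path(dir, "trials.csv"))
  utils::write.csv(calls, paths["calls"], row.names = FALSE,
                   fileEncoding = "UTF-8")
  utils::write.csv(corpus$trials, paths["trials"], row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(paths)
}

#' Pipeline configuration
#'
#' Assembles (or reads from a single YAML file) the thresholds, stage
#' toggles and seed of [run_pipeline()].
#'
#' @param seed integer seed for all stochastic stages.
#' @param stages character subset of
#'   `c("simulate", "classify", "segment", "grammar", "stats")`.
#' @param threshold_s segmentation bout criterion (s); `"auto"` uses the
#'   mixture-derived boundary.
#' @param k_range candidate cluster counts.
#' @param n_boot bootstrap iterations for the mode-selection LRT.
#' @param ridge_sd Gaussian ridge SD for the count models (`NULL` = none).
#' @param window_s analysis window (s).
#' @param n_trials named per-stimulus trial counts for the simulate stage.
#' @param standardize z-score features before clustering.
#' @return list of class `"callgram_pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1, stages = c("simulate", "classify",
                                                 "segment", "grammar", "stats"),
                            threshold_s = 1, k_range = 2:10, n_boot = 199,
                            ridge_sd = 1, window_s = 160,
                            n_trials = c(leopard = 44, eagle = 60, tree = 83,
                                         chimpanzee = 14),
                            standardize = TRUE) {
  stopifnot(window_s > 0, n_boot >= 99,
            identical(threshold_s, "auto") || threshold_s > 0)
  structure(list(seed = as.integer(seed), stages = stages,
                 threshold_s = threshold_s, k_range = k_range,
                 n_boot = n_boot, ridge_sd = ridge_sd, window_s = window_s,
                 n_trials = n_trials, standardize = standardize),
            class = "callgram_pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file with any subset of the `pipeline_config()` fields.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(raw$n_trials)) raw$n_trials <- unlist(raw$n_trials)
  if (!is.null(raw$k_range)) raw$k_range <- do.call(seq,
                                                    as.list(range(unlist(raw$k_range))))
  do.call(pipeline_config, raw)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or read the given
#' corpus), classify call types, segment sequences, grammar analysis, and
#' the context-specificity count models — writing every artifact plus a
#' manifest (package version, seed, config, file checksums) when `out_dir`
#' is given. Reruns with the same config and seed are bit-identical for the
#' deterministic stages.
#'
#' @param config a [pipeline_config()].
#' @param corpus optional pre-built corpus (skips the simulate stage).
#' @param out_dir optional output directory.
#' @return list with the per-stage results: `corpus`, `classification`,
#'   `segmentation`, `grammar`, `stats`, `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config(), corpus = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "callgram_pipeline_config"))
  set.seed(config$seed)
  res <- list()
  stage <- function(name) name %in% config$stages

  if (stage("simulate") && is.null(corpus)) {
    corpus <- generate_corpus(
      generator_config(window = config$window_s, seed = config$seed),
      n_trials = config$n_trials)
  }
  if (is.null(corpus))
    stop("stage 'simulate' disabled and no corpus supplied", call. = FALSE)
  res$corpus <- corpus

  calls <- corpus$calls
  if (stage("classify")) {
    if (nrow(calls) < 3) stop("classify: too few calls", call. = FALSE)
    feats <- if (config$standardize) standardize_features(calls)$x else
      as.matrix(calls[, c("duration", "max_frequency")])
    sel <- select_k(feats, config$k_range)
    fit2 <- if (sel$best_k == 2) sel$fits$k2 else pam_cluster(feats, 2)
    calls <- label_clusters(fit2, calls)
    res$classification <- list(best_k = sel$best_k, curve = sel$curve,
                               fit = fit2,
                               agreement = if ("true_type" %in% names(calls))
                                 100 * mean(calls$assigned_type == calls$true_type)
                               else NA_real_)
  }

  if (stage("segment")) {
    if (!"assigned_type" %in% names(calls))
      stop("segment: calls are unlabeled; enable the classify stage",
           call. = FALSE)
    iv <- compute_intervals(calls)
    modes <- select_modes(iv$interval, K_max = 5, n_boot = config$n_boot,
                          n_init = 3)
    mix <- fit_log_mixture(iv$interval, K = 2)
    thr <- if (identical(config$threshold_s, "auto")) mix$boundary_s else
      config$threshold_s
    seg <- segment_sequences(calls, threshold_s = thr)
    res$segmentation <- list(intervals = iv, modes = modes, mixture = mix,
                             threshold_s = thr,
                             sequences = seg$sequences,
                             n_singletons = seg$n_singletons)
  }

  if (stage("grammar")) {
    if (is.null(res$segmentation))
      stop("grammar: no sequences; enable the segment stage", call. = FALSE)
    sq <- res$segmentation$sequences
    sq$pattern <- as.character(classify_pattern(sq$symbols))
    sq$initiation <- initiation(sq$symbols)
    sq$termination <- termination_bigram(sq$symbols)
    res$grammar <- list(sequences = sq,
                        rules = check_rules(sq$symbols),
                        summary = repertoire_summary(sq$symbols),
                        trie = build_trie(sq$symbols))
  }

  if (stage("stats")) {
    if (is.null(res$grammar)) stop("stats: enable the grammar stage",
                                   call. = FALSE)
    sq <- res$grammar$sequences
    res$stats <- list(
      response_rates = response_rate(corpus$trials, corpus$calls,
                                     config$window_s))
    for (cat in c("initiation", "pattern", "termination")) {
      tab <- build_count_table(sq, corpus$trials, cat,
                               window = config$window_s)
      fit <- suppressWarnings(
        fit_poisson_glmm(tab, ~ level * stimulus + group_location,
                         ridge_sd = config$ridge_sd))
      null <- suppressWarnings(refit_glmm(fit, ~1))
      res$stats[[cat]] <- list(table = tab, fit = fit,
                               lrt_vs_null = lr_test(fit, null),
                               drop1 = drop1_interactions(fit))
    }
  }

  if (!is.null(out_dir)) res$manifest <- write_pipeline(res, config, out_dir)
  res
}

write_pipeline <- function(res, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(res$corpus, out_dir)
  if (!is.null(res$classification))
    utils::write.csv(res$classification$curve,
                     file.path(out_dir, "silhouette_curve.csv"),
                     row.names = FALSE)
  if (!is.null(res$grammar)) {
    utils::write.csv(res$grammar$sequences,
                     file.path(out_dir, "sequences.csv"), row.names = FALSE)
    export_trie_dot(res$grammar$trie, file.path(out_dir, "trie.dot"))
    jsonlite::write_json(unclass(res$grammar$summary),
                         file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(res$stats$response_rates))
    utils::write.csv(res$stats$response_rates,
                     file.path(out_dir, "rates.csv"), row.names = FALSE)
  files <- list.files(out_dir, full.names = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("callgram")),
                   seed = config$seed,
                   config = unclass(config),
                   checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
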