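# Per-trial count tables for the context-specificity models, and vocal
# response rates per stimulus.

category_levels <- function(category) {
  switch(category,
         initiation = c("A", "B"),
         pattern = pattern_levels()[1:4],
         termination = c("AA_gram", "BA_gram"),
         stop("unknown category: ", category, call. = FALSE))
}

sequence_feature <- function(symbols, category) {
  switch(category,
         initiation = initiation(symbols),
         pattern = as.character(classify_pattern(symbols)),
         termination = termination_bigram(symbols))
}

#' Build a per-trial count table for one sequence feature
#'
#' For every responding trial (at least one sequence starting within the
#' analysis window) the table holds one row per level of the chosen
#' category — the sequence's first call (`initiation`), its overall pattern
#' (`pattern`), or its final bigram (`termination`) — with the count of
#' sequences of that level, the trial covariates, and the exposure offset
#' `log(total sequences in the trial + 1)`. Unobserved levels get explicit
#' zeros. Sequences outside the category's levels (`other` patterns or
#' terminations) are excluded from the counts but still contribute to the
#' offset total by default.
#'
#' Factor reference levels follow the reporting convention of the analysis:
#' category level "A" / "A_repeat" / "AA_gram" first, stimulus reference
#' "eagle", group location reference "north".
#'
#' @param sequences data.frame from [segment_sequences()] (`trial_id`,
#'   `symbols`, `start`).
#' @param trials trial metadata (`trial_id`, `stimulus`, `group_location`,
#'   `elevation`, `mode`).
#' @param category `"initiation"`, `"pattern"` or `"termination"`.
#' @param window analysis window in seconds.
#' @param offset_all when `TRUE` (default) the offset counts all sequences
#'   in the window, including unclassified ones; otherwise only sequences
#'   within the category levels.
#' @return data.frame: `trial_id`, `level`, `count`, `stimulus`,
#'   `group_location`, `elevation`, `offset`; attribute `n_excluded_trials`
#'   counts responding trials without sequences.
#' @export
build_count_table <- function(sequences, trials, category, window = 160,
                              offset_all = TRUE) {
  category <- match.arg(category, c("initiation", "pattern", "termination"))
  levs <- category_levels(category)
  seqs <- sequences[sequences$start <= window, , drop = FALSE]
  feat <- sequence_feature(seqs$symbols, category)
  keep_trials <- unique(seqs$trial_id)
  n_excluded <- sum(!trials$trial_id %in% keep_trials & trials$responded %in% TRUE)

  grid <- expand.grid(trial_id = keep_trials, level = levs,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cnt <- table(factor(seqs$trial_id, keep_trials),
               factor(feat, levs))
  grid$count <- as.integer(cnt[cbind(grid$trial_id, grid$level)])
  tot <- if (offset_all) table(factor(seqs$trial_id, keep_trials)) else
    rowSums(cnt)
  grid$offset <- log(as.numeric(tot[grid$trial_id]) + 1)

  meta_cols <- intersect(c("stimulus", "group_location", "elevation", "mode"),
                         names(trials))
  grid <- merge(grid, trials[, c("trial_id", meta_cols)], by = "trial_id",
                sort = FALSE)
  grid$level <- factor(grid$level, levs)
  if ("stimulus" %in% names(grid)) {
    st <- unique(grid$stimulus)
    grid$stimulus <- factor(grid$stimulus,
                            c(intersect("eagle", st), sort(setdiff(st, "eagle"))))
  }
  if ("group_location" %in% names(grid))
    grid$group_location <- factor(grid$group_location,
                                  intersect(c("north", "south"),
                                            unique(grid$group_location)))
  grid <- grid[order(grid$trial_id, grid$level), ]
  rownames(grid) <- NULL
  structure(grid, n_excluded_trials = n_excluded)
}

#' Vocal response rates per stimulus
#'
#' The percentage of trials in which at least one call was produced within
#' the first `window` seconds, per stimulus and presentation mode. Stimuli
#' without trials are omitted.
#'
#' @param trials trial metadata with `trial_id`, `stimulus` and (optionally)
#'   `mode`.
#' @param calls call records with `trial_id` and `onset`.
#' @param window analysis window in seconds; `window = 0` gives 0 everywhere.
#' @return data.frame: `mode`, `stimulus`, `n_trials`, `n_responded`,
#'   `rate` (percent).
#' @export
response_rate <- function(trials, calls, window = 160) {
  in_window <- unique(calls$trial_id[calls$onset < window])
  trials$respond_win <- trials$trial_id %in% in_window
  if (!"mode" %in% names(trials)) trials$mode <- "all"
  agg <- stats::aggregate(respond_win ~ mode + stimulus, trials,
                          function(v) c(n = length(v), k = sum(v)))
  out <- data.frame(mode = agg$mode, stimulus = agg$stimulus,
                    n_trials = agg$respond_win[, "n"],
                    n_responded = agg$respond_win[, "k"])
  out$rate <- 100 * out$n_responded / out$n_trials
  out[order(out$mode, out$stimulus), ]
}
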