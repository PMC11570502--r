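# Synthetic corpus generation: trials, call features, sequence strings and
# their timing layout. All randomness flows through R's global RNG; a seed in
# the config makes generate_corpus() reproducible end to end.

# inverse-CDF draw from a normal truncated at +/- trunc SD around the mean
rtrunc_norm <- function(n, mean, sd, trunc) {
  lo <- stats::pnorm(-trunc)
  mean + sd * stats::qnorm(stats::runif(n, lo, 1 - lo))
}

# inverse-CDF draw from a log-normal truncated to (lo, hi) on the seconds scale
rtrunc_lnorm <- function(n, mu, sigma, lo = 0, hi = Inf) {
  plo <- stats::plnorm(lo, mu, sigma)
  phi <- stats::plnorm(hi, mu, sigma)
  stats::qlnorm(stats::runif(n, plo, phi), mu, sigma)
}

#' Sample acoustic features for calls of one type
#'
#' Draws duration (s) and maximum frequency (kHz) from the per-type normal
#' distributions of the configuration, truncated at `config$truncation` SD
#' and with durations floored at `config$duration_floor`. Under the defaults
#' (truncation 3) the A and B maximum-frequency supports are disjoint:
#' A <= 1.48 kHz, B >= 2.53 kHz.
#'
#' @param call_type `"A"` or `"B"`.
#' @param config a [generator_config()].
#' @param n number of calls to draw.
#' @return data.frame with columns `duration` and `max_frequency`.
#' @export
sample_call_features <- function(call_type, config, n = 1) {
  call_type <- match.arg(call_type, c("A", "B"))
  p <- config$acoustic[[call_type]]
  data.frame(
    duration = pmax(rtrunc_norm(n, p$dur_mean, p$dur_sd, config$truncation),
                    config$duration_floor),
    max_frequency = pmax(rtrunc_norm(n, p$freq_mean, p$freq_sd, config$truncation),
                         1e-6))
}

#' Sample within- and between-sequence inter-call intervals
#'
#' Draws from the moment-matched log-normal interval distributions of the
#' configuration: within-sequence gaps truncated above at
#' `config$intervals$within_max` (1 s by default) and between-sequence gaps
#' truncated below at `config$intervals$between_min` (2 s).
#'
#' @param config a [generator_config()].
#' @param n_within,n_between number of draws from each component.
#' @return list with numeric vectors `within` and `between` (seconds).
#' @export
sample_intervals <- function(config, n_within, n_between) {
  iv <- config$intervals
  w <- lognormal_params(iv$within_mean, iv$within_sd)
  b <- lognormal_params(iv$between_mean, iv$between_sd)
  list(within = rtrunc_lnorm(n_within, w["mu"], w["sigma"], hi = iv$within_max),
       between = rtrunc_lnorm(n_between, b["mu"], b["sigma"], lo = iv$between_min))
}

#' Generate one sequence symbol string for a given pattern
#'
#' Produces a string over \{A, B\} matching the requested pattern class:
#' `A_repeat` = `A{2,}`, `BA` = `(BA)+`, `A_BA` = `A+(BA)+`,
#' `BA_A` = `(BA)+A+`. Segment repetition counts are 1 + Geom(`repeat_prob`)
#' (A-repetitions use 2 + Geom so the sequence has at least two calls). Every
#' output satisfies the three combinatorial rules by construction.
#'
#' @param pattern one of `"A_repeat"`, `"BA"`, `"A_BA"`, `"BA_A"`.
#' @param repeat_prob geometric success probability for repetition counts.
#' @return a single character string, length >= 2.
#' @export
#' @examples
#' set.seed(1)
#' generate_sequence_string("BA")
generate_sequence_string <- function(pattern, repeat_prob = 0.54) {
  pattern <- match.arg(pattern, pattern_levels()[1:4])
  reps <- function(min_n) min_n + stats::rgeom(1, repeat_prob)
  switch(pattern,
    A_repeat = strrep("A", reps(2)),
    BA       = strrep("BA", reps(1)),
    A_BA     = paste0(strrep("A", reps(1)), strrep("BA", reps(1))),
    BA_A     = paste0(strrep("BA", reps(1)), strrep("A", reps(1))))
}

# lay out one trial's sequences on the time axis; returns NULL if the window
# cannot hold the drawn material (caller regenerates)
layout_trial <- function(trial_id, strings, config) {
  onset <- NULL; duration <- NULL; freq <- NULL; type <- NULL
  t <- stats::runif(1, 0, 5)
  for (s in strings) {
    sym <- strsplit(s, "")[[1]]
    n <- length(sym)
    feats <- data.frame(duration = numeric(n), max_frequency = numeric(n))
    for (ct in c("A", "B")) {
      idx <- which(sym == ct)
      if (length(idx))
        feats[idx, ] <- sample_call_features(ct, config, length(idx))
    }
    gaps <- sample_intervals(config, n - 1L, 0)$within
    on <- numeric(n)
    for (j in seq_len(n)) {
      on[j] <- t
      t <- t + feats$duration[j] + if (j < n) gaps[j] else 0
    }
    onset <- c(onset, on)
    duration <- c(duration, feats$duration)
    freq <- c(freq, feats$max_frequency)
    type <- c(type, sym)
    t <- t + sample_intervals(config, 0, 1)$between
  }
  if (onset[length(onset)] > config$window) return(NULL)
  data.frame(trial_id = trial_id,
             call_index = seq_along(onset) - 1L,
             onset = onset, duration = duration, max_frequency = freq,
             true_type = type, stringsAsFactors = FALSE)
}

#' Generate a synthetic trial corpus
#'
#' Simulates playback/model trials and the call records of the single
#' responding caller per trial. Each responding trial receives
#' `1 + Pois(seq_rate)` sequences whose patterns follow the per-stimulus
#' `pattern_probs`; sequence strings are grammar-conforming by construction;
#' within-sequence gaps are drawn from the within-interval distribution
#' (truncated below 1 s) and between-sequence gaps from the between-interval
#' distribution (truncated above 2 s). Trials whose drawn material does not
#' fit in the analysis window are regenerated (with a warning, counted in the
#' result).
#'
#' @param config a [generator_config()]; `config$seed`, when non-`NULL`,
#'   makes the output reproducible.
#' @param n_trials named integer vector of trials per stimulus. Defaults to
#'   the playback-study composition: leopard 44, eagle 60, tree 83,
#'   chimpanzee 14.
#' @param mode `"playback"` or `"visual_model"`.
#' @return list of class `"callgram_corpus"` with elements
#'   \describe{
#'     \item{trials}{data.frame: `trial_id`, `dataset`, `stimulus`, `mode`,
#'       `elevation`, `group_location`, `responded`.}
#'     \item{calls}{data.frame: `trial_id`, `call_index` (0-based), `onset`,
#'       `duration` (s), `max_frequency` (kHz), `true_type`.}
#'     \item{n_regenerated}{number of trial layouts that had to be redrawn.}
#'   }
#' @export
#' @examples
#' corp <- generate_corpus(generator_config(seed = 1),
#'                         n_trials = c(leopard = 5, eagle = 5))
#' table(corp$calls$true_type)
generate_corpus <- function(config,
                            n_trials = c(leopard = 44, eagle = 60,
                                         tree = 83, chimpanzee = 14),
                            mode = c("playback", "visual_model")) {
  validate_config(config)
  mode <- match.arg(mode)
  if (is.null(names(n_trials)) || any(!nzchar(names(n_trials))))
    stop("n_trials must be a named vector of per-stimulus counts", call. = FALSE)
  if (any(n_trials < 0)) stop("n_trials must be >= 0", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  resp <- config$response_probs[[mode]]
  trials <- list(); calls <- list(); n_regen <- 0L; id <- 0L
  for (st in names(n_trials)) {
    pr <- if (st %in% names(resp)) resp[[st]] else 0
    for (i in seq_len(n_trials[[st]])) {
      id <- id + 1L
      tid <- sprintf("T%04d", id)
      elev <- if (st == "tree" || mode == "visual_model") "none" else
        sample(c("ground", "tree"), 1)
      responded <- stats::runif(1) < pr
      trials[[id]] <- data.frame(
        trial_id = tid, dataset = "synthetic", stimulus = st, mode = mode,
        elevation = elev,
        group_location = sample(c("north", "south"), 1),
        responded = responded, stringsAsFactors = FALSE)
      if (!responded) next
      repeat {
        n_seq <- 1L + stats::rpois(1, config$seq_rate)
        pats <- sample(names(config$pattern_probs[[st]]), n_seq,
                       replace = TRUE, prob = config$pattern_probs[[st]])
        strings <- vapply(pats, generate_sequence_string, "",
                          repeat_prob = config$repeat_prob)
        laid <- layout_trial(tid, strings, config)
        if (!is.null(laid)) break
        n_regen <- n_regen + 1L
        warning("trial ", tid, " regenerated: drawn material exceeded the ",
                config$window, " s window", call. = FALSE)
      }
      calls[[id]] <- laid
    }
  }
  out <- list(trials = do.call(rbind, trials),
              calls = if (length(calls)) do.call(rbind, Filter(Negate(is.null), calls))
                      else empty_calls(),
              n_regenerated = n_regen)
  rownames(out$trials) <- NULL
  if (!is.null(out$calls)) rownames(out$calls) <- NULL
  class(out) <- "callgram_corpus"
  out
}

empty_calls <- function() {
  data.frame(trial_id = character(), call_index = integer(), onset = numeric(),
             duration = numeric(), max_frequency = numeric(),
             true_type = character(), stringsAsFactors = FALSE)
}

#' @export
print.callgram_corpus <- function(x, ...) {
  cat("Synthetic call corpus:", nrow(x$trials), "trials,",
      sum(x$trials$responded), "with vocal response,",
      nrow(x$calls), "calls\n")
  invisible(x)
}

#' Inject combinatorial-rule violations into sequence strings
#'
#' Negative-control fixture generator: modifies approximately `rate` of the
#' given sequence symbol strings so that each modified string violates the
#' named rule. `B_singularity` doubles a B (or prepends "BB");
#' `A_suffixation` appends "AB" (ends in B, leaving the other two rules
#' intact); `A_dominance` prepends enough B calls to outnumber the A calls —
#' note that a dominance violation cannot occur alone: any string without
#' "BB" that ends in "A" automatically has at least as many A as B calls, so
#' dominance injections co-violate B-Singularity.
#'
#' @param symbols character vector of sequence strings over \{A, B\}.
#' @param rule one of `"A_dominance"`, `"A_suffixation"`, `"B_singularity"`.
#' @param rate fraction of sequences to modify, in \[0, 1\].
#' @return list with `symbols` (modified vector) and `modified` (integer
#'   indices of the altered sequences).
#' @export
inject_rule_violations <- function(symbols, rule, rate) {
  rule <- match.arg(rule, rule_ids())
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate > 1)
    stop("rate must be a single number in [0, 1]", call. = FALSE)
  hit <- which(stats::runif(length(symbols)) < rate)
  out <- symbols
  for (i in hit) {
    s <- out[i]
    out[i] <- switch(rule,
      B_singularity = if (grepl("B", s, fixed = TRUE))
        sub("B", "BB", s) else paste0("BB", s),
      A_suffixation = paste0(s, "AB"),
      A_dominance = {
        nA <- nchar(gsub("[^A]", "", s))
        nB <- nchar(s) - nA
        paste0(strrep("B", max(nA - nB + 1L, 1L)), s)
      })
  }
  list(symbols = out, modified = hit)
}
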