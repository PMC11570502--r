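#' Generator configuration for synthetic call corpora
#'
#' Builds the parameter set that drives [generate_corpus()]. Defaults encode
#' the published acoustic and temporal structure of Olive colobus alarm
#' calling: two call types ("A": short, low-frequency; "B": long,
#' high-frequency), within- and between-sequence inter-call intervals, the
#' per-stimulus mix of sequence patterns, and per-stimulus vocal response
#' probabilities over a 160 s analysis window.
#'
#' Acoustic features are drawn from per-type normal distributions truncated at
#' `truncation` standard deviations and floored at `duration_floor` seconds.
#' Inter-call intervals are log-normal, parameterised by moment matching so
#' that the arithmetic mean/SD equal the configured values; within-sequence
#' gaps are truncated above at `within_max` and between-sequence gaps below at
#' `between_min` (seconds).
#'
#' @param acoustic named list with elements `A` and `B`, each a list with
#'   `freq_mean`, `freq_sd` (kHz) and `dur_mean`, `dur_sd` (s).
#' @param truncation truncation of the acoustic feature normals, in SD units.
#' @param duration_floor minimum call duration in seconds.
#' @param intervals list with `within_mean`, `within_sd`, `between_mean`,
#'   `between_sd` (arithmetic scale, seconds) and truncation bounds
#'   `within_max`, `between_min`.
#' @param pattern_probs named list mapping each stimulus to a probability
#'   vector over the four sequence patterns
#'   `c(A_repeat, BA, A_BA, BA_A)`; each must sum to 1.
#' @param repeat_prob success probability of the geometric law for the number
#'   of gram repetitions per segment (repetitions = 1 + Geom(p)).
#' @param seq_rate rate of the shifted Poisson law for sequences per
#'   responding trial (n = 1 + Pois(rate)).
#' @param response_probs nested list `mode -> stimulus -> probability` that a
#'   trial receives any vocal response.
#' @param window analysis window in seconds.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#'
#' @return A list of class `"callgram_config"`.
#' @seealso [generate_corpus()], [sample_call_features()], [sample_intervals()]
#' @export
#' @examples
#' cfg <- generator_config(seed = 1)
#' cfg$acoustic$A$freq_mean
generator_config <- function(acoustic = list(
                               A = list(freq_mean = 1.00, freq_sd = 0.16,
                                        dur_mean = 0.12, dur_sd = 0.12),
                               B = list(freq_mean = 7.72, freq_sd = 1.73,
                                        dur_mean = 0.58, dur_sd = 0.28)),
                             truncation = 3,
                             duration_floor = 0.01,
                             intervals = list(within_mean = 0.12, within_sd = 0.14,
                                              between_mean = 22.8, between_sd = 21.3,
                                              within_max = 1, between_min = 2),
                             pattern_probs = list(
                               leopard    = c(A_repeat = 0.0485, BA = 0.720,
                                              A_BA = 0.0485, BA_A = 0.183),
                               eagle      = c(A_repeat = 0.488, BA = 0.076,
                                              A_BA = 0.360, BA_A = 0.076),
                               tree       = c(A_repeat = 0.133, BA = 0.134,
                                              A_BA = 0.133, BA_A = 0.600),
                               chimpanzee = c(A_repeat = 0.25, BA = 0.25,
                                              A_BA = 0.25, BA_A = 0.25)),
                             repeat_prob = 0.54,
                             seq_rate = 1.4,
                             response_probs = list(
                               playback = c(leopard = 0.614, eagle = 0.367,
                                            tree = 0.506, chimpanzee = 0),
                               visual_model = c(leopard = 0.667, eagle = 0)),
                             window = 160,
                             seed = NULL) {
  cfg <- structure(
    list(acoustic = acoustic, truncation = truncation,
         duration_floor = duration_floor, intervals = intervals,
         pattern_probs = pattern_probs, repeat_prob = repeat_prob,
         seq_rate = seq_rate, response_probs = response_probs,
         window = window, seed = seed),
    class = "callgram_config")
  validate_config(cfg)
  cfg
}

#' Validate a generator configuration
#'
#' Checks the structural invariants of a [generator_config()] object:
#' probability vectors sum to one (within 1e-9), all SDs and the truncation
#' are positive, probabilities lie in \[0, 1\], and the window is positive.
#'
#' @param config object to validate.
#' @return `config`, invisibly; errors with a message naming the offending
#'   field otherwise.
#' @export
validate_config <- function(config) {
  if (!inherits(config, "callgram_config"))
    stop("not a callgram_config object", call. = FALSE)
  ac <- config$acoustic
  for (ct in c("A", "B")) {
    p <- ac[[ct]]
    if (is.null(p)) stop("acoustic parameters missing for type ", ct, call. = FALSE)
    if (!all(c(p$freq_sd, p$dur_sd) > 0))
      stop("acoustic SDs must be > 0 for type ", ct, call. = FALSE)
    if (!all(c(p$freq_mean, p$dur_mean) > 0))
      stop("acoustic means must be > 0 for type ", ct, call. = FALSE)
  }
  if (!(config$truncation > 0)) stop("truncation must be > 0", call. = FALSE)
  if (!(config$duration_floor > 0)) stop("duration_floor must be > 0", call. = FALSE)
  iv <- config$intervals
  if (!all(c(iv$within_sd, iv$between_sd) > 0))
    stop("interval SDs must be > 0", call. = FALSE)
  if (!all(c(iv$within_mean, iv$between_mean) > 0))
    stop("interval means must be > 0", call. = FALSE)
  for (st in names(config$pattern_probs)) {
    p <- config$pattern_probs[[st]]
    if (length(p) != 4L || !setequal(names(p), pattern_levels()[1:4]))
      stop("pattern_probs[", st, "] must name the four patterns", call. = FALSE)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
      stop("pattern_probs[", st, "] must be a probability vector summing to 1",
           call. = FALSE)
  }
  if (!(config$repeat_prob > 0 && config$repeat_prob <= 1))
    stop("repeat_prob must be in (0, 1]", call. = FALSE)
  if (!(config$seq_rate >= 0)) stop("seq_rate must be >= 0", call. = FALSE)
  for (md in names(config$response_probs)) {
    p <- config$response_probs[[md]]
    if (any(p < 0 | p > 1))
      stop("response_probs[", md, "] must lie in [0, 1]", call. = FALSE)
  }
  if (!(config$window > 0)) stop("window must be > 0", call. = FALSE)
  invisible(config)
}

#' Moment-matched log-normal parameters
#'
#' Returns the log-scale location and scale of the log-normal distribution
#' whose arithmetic mean and SD equal `mean` and `sd`:
#' \eqn{\sigma^2 = \log(1 + sd^2/mean^2)}, \eqn{\mu = \log(mean) - \sigma^2/2}.
#'
#' @param mean,sd arithmetic-scale mean and standard deviation (both > 0).
#' @return named vector `c(mu, sigma)` on the natural-log scale.
#' @export
#' @examples
#' p <- lognormal_params(22.8, 21.3)
#' exp(p["mu"] + p["sigma"]^2 / 2)  # 22.8
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

pattern_levels <- function() c("A_repeat", "BA", "A_BA", "BA_A", "other")

rule_ids <- function() c("A_dominance", "A_suffixation", "B_singularity")
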