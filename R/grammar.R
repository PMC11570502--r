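# Grammar analysis of call sequences: pattern classes, the three
# combinatorial rules, bigram/initiation/termination features and the
# repertoire summary.

check_symbols <- function(symbols, min_len = 2) {
  if (!is.character(symbols)) stop("symbols must be character", call. = FALSE)
  bad <- grepl("[^AB]", symbols) | nchar(symbols) < min_len
  if (any(bad))
    stop("invalid sequence string(s) at position ",
         paste(utils::head(which(bad), 5), collapse = ", "),
         ": need length >= ", min_len, " over {A,B}", call. = FALSE)
  invisible(symbols)
}

#' Classify a sequence into its pattern class
#'
#' Full-string match against the four basic sequence patterns:
#' `A_repeat` = `^A{2,}$`, `BA` = `^(BA)+$`, `A_BA` = `^A+(BA)+$`,
#' `BA_A` = `^(BA)+A+$`; anything else is `other`. The four expressions are
#' mutually exclusive, so classification order is immaterial.
#'
#' @param symbols character vector of sequence strings (length >= 2, over
#'   \{A, B\}).
#' @return factor with levels `A_repeat`, `BA`, `A_BA`, `BA_A`, `other`.
#' @export
#' @examples
#' classify_pattern(c("AAA", "BA", "ABA", "BAA", "ABAA"))
classify_pattern <- function(symbols) {
  check_symbols(symbols)
  out <- rep("other", length(symbols))
  out[grepl("^A{2,}$", symbols)] <- "A_repeat"
  out[grepl("^(BA)+$", symbols)] <- "BA"
  out[grepl("^A+(BA)+$", symbols)] <- "A_BA"
  out[grepl("^(BA)+A+$", symbols)] <- "BA_A"
  factor(out, levels = pattern_levels())
}

#' Evaluate the three combinatorial rules over a corpus
#'
#' Per sequence:
#' \describe{
#'   \item{A_dominance}{the number of B calls never exceeds the number of A
#'     calls (#A >= #B). Stated with an indicator over positions, twice the
#'     number of A calls is at least the sequence length.}
#'   \item{A_suffixation}{the sequence ends with an A call.}
#'   \item{B_singularity}{no two B calls in succession (no "BB").}
#' }
#' A-Dominance is in fact implied by the other two rules: if no B is followed
#' by a B and the final call is an A, every B has an A successor of its own,
#' so #A >= #B.
#'
#' @param symbols character vector of sequence strings (length >= 2).
#' @return list of class `"callgram_rules"`; per rule a list with `holds`
#'   (no violations in the corpus), `violations` (indices) and `fraction`.
#' @export
check_rules <- function(symbols) {
  check_symbols(symbols)
  nA <- nchar(gsub("[^A]", "", symbols))
  n <- nchar(symbols)
  ok <- list(
    A_dominance = 2 * nA >= n,
    A_suffixation = endsWith(symbols, "A"),
    B_singularity = !grepl("BB", symbols, fixed = TRUE))
  out <- lapply(ok, function(o)
    list(holds = all(o), violations = which(!o), fraction = mean(!o)))
  structure(out, class = "callgram_rules")
}

#' @export
print.callgram_rules <- function(x, ...) {
  for (r in names(x))
    cat(sprintf("%-14s %s  (%.1f%% violating)\n", r,
                if (x[[r]]$holds) "holds" else "VIOLATED",
                100 * x[[r]]$fraction))
  invisible(x)
}

#' Bigram counts of a sequence
#'
#' Counts the `n - 1` contiguous call pairs of one sequence.
#'
#' @param symbols a single sequence string (length >= 2).
#' @return named integer vector over `AA`, `AB`, `BA`, `BB`; sums to
#'   `nchar(symbols) - 1`.
#' @export
#' @examples
#' bigram_counts("BABA")  # BA:2, AB:1
bigram_counts <- function(symbols) {
  stopifnot(length(symbols) == 1L)
  check_symbols(symbols)
  s <- strsplit(symbols, "")[[1]]
  bg <- paste0(s[-length(s)], s[-1])
  tab <- table(factor(bg, levels = c("AA", "AB", "BA", "BB")))
  stats::setNames(as.integer(tab), names(tab))
}

#' First call of each sequence
#'
#' @param symbols character vector of sequence strings.
#' @return character vector of `"A"`/`"B"`.
#' @export
initiation <- function(symbols) {
  check_symbols(symbols)
  substr(symbols, 1, 1)
}

#' Terminal bigram class of each sequence
#'
#' The last two calls mapped to `AA_gram`, `BA_gram` or `other` (the latter
#' never occurs in rule-conforming corpora, which always end in A preceded by
#' A or B).
#'
#' @param symbols character vector of sequence strings.
#' @return character vector over `AA_gram`, `BA_gram`, `other`.
#' @export
termination_bigram <- function(symbols) {
  check_symbols(symbols)
  last2 <- substr(symbols, nchar(symbols) - 1, nchar(symbols))
  out <- rep("other", length(symbols))
  out[last2 == "AA"] <- "AA_gram"
  out[last2 == "BA"] <- "BA_gram"
  out
}

#' Repertoire summary of a sequence corpus
#'
#' Tallies the corpus at both senses of "type": exact string identity (for
#' the distinct/singleton type counts) and pattern class (for the four-way
#' classification). Percentages are over all sequences.
#'
#' @param symbols character vector of sequence strings (nonempty).
#' @return list of class `"callgram_repertoire"`: `n_sequences`, `n_types`,
#'   `n_singleton_types`, `mean_length`, `sd_length`, `max_length`,
#'   `pct_mixed` (contains at least one B), `pct_A_repetition`,
#'   `pct_B_repetition`, `pct_four_types` (share of the four basic patterns),
#'   `n_unclassified` (pattern `other`), `pattern_pct`, `initiation_pct`,
#'   `termination_pct`.
#' @export
repertoire_summary <- function(symbols) {
  if (!length(symbols)) stop("empty corpus", call. = FALSE)
  check_symbols(symbols)
  n <- length(symbols)
  len <- nchar(symbols)
  types <- table(symbols)
  pat <- classify_pattern(symbols)
  pat_pct <- 100 * as.numeric(table(pat)) / n
  names(pat_pct) <- levels(pat)
  init_pct <- 100 * table(factor(initiation(symbols), c("A", "B"))) / n
  term_pct <- 100 * table(factor(termination_bigram(symbols),
                                 c("AA_gram", "BA_gram", "other"))) / n
  has_B <- grepl("B", symbols, fixed = TRUE)
  all_A <- !has_B
  all_B <- !grepl("A", symbols, fixed = TRUE)
  structure(list(
    n_sequences = n,
    n_types = length(types),
    n_singleton_types = sum(types == 1),
    mean_length = mean(len), sd_length = stats::sd(len),
    max_length = max(len),
    pct_mixed = 100 * mean(has_B & !all_B),
    pct_A_repetition = 100 * mean(all_A),
    pct_B_repetition = 100 * mean(all_B),
    pct_four_types = 100 * mean(pat != "other"),
    n_unclassified = sum(pat == "other"),
    pattern_pct = pat_pct,
    initiation_pct = stats::setNames(as.numeric(init_pct), names(init_pct)),
    termination_pct = stats::setNames(as.numeric(term_pct), names(term_pct))),
    class = "callgram_repertoire")
}

#' @export
print.callgram_repertoire <- function(x, ...) {
  cat(sprintf("%d sequences, %d distinct types (%d singletons)\n",
              x$n_sequences, x$n_types, x$n_singleton_types))
  cat(sprintf("length %.1f +/- %.1f calls (max %d)\n",
              x$mean_length, x$sd_length, x$max_length))
  cat(sprintf("mixed %.1f%% | A-repetition %.1f%% | B-repetition %.1f%%\n",
              x$pct_mixed, x$pct_A_repetition, x$pct_B_repetition))
  cat(sprintf("four basic patterns %.1f%% (%d unclassified)\n",
              x$pct_four_types, x$n_unclassified))
  cat("patterns (%):", paste(sprintf("%s %.1f", names(x$pattern_pct),
                                     x$pattern_pct), collapse = ", "), "\n")
  invisible(x)
}
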