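# Shared fixtures: all synthetic, built in code at test time.

# acoustic feature sample with known call types
acoustic_sample <- function(nA, nB, cfg = generator_config(), seed = 1) {
  set.seed(seed)
  feats <- rbind(sample_call_features("A", cfg, nA),
                 sample_call_features("B", cfg, nB))
  feats$true_type <- rep(c("A", "B"), c(nA, nB))
  feats
}

# count table simulated from the Poisson random-intercept model itself
sim_count_data <- function(G, beta, sigma, seed,
                           stimuli = c("eagle", "leopard")) {
  set.seed(seed)
  tab <- expand.grid(trial_id = sprintf("T%04d", seq_len(G)),
                     level = c("A", "B"))
  tab$stimulus <- factor(rep(sample(stimuli, G, TRUE), 2), stimuli)
  X <- stats::model.matrix(~ level * stimulus, tab)
  stopifnot(ncol(X) == length(beta))
  u <- stats::rnorm(G, 0, sigma)
  tab$offset <- log(stats::rpois(G, 3)[as.integer(factor(tab$trial_id))] + 1)
  tab$count <- stats::rpois(nrow(tab),
                            exp(drop(X %*% beta) + tab$offset +
                                  u[as.integer(factor(tab$trial_id))]))
  tab
}

# independent character-loop oracle for the three combinatorial rules
rule_oracle <- function(s) {
  ch <- strsplit(s, "")[[1]]
  nA <- sum(ch == "A")
  nB <- sum(ch == "B")
  no_bb <- TRUE
  for (i in seq_len(length(ch) - 1))
    if (ch[i] == "B" && ch[i + 1] == "B") no_bb <- FALSE
  c(A_dominance = nA >= nB,
    A_suffixation = ch[length(ch)] == "A",
    B_singularity = no_bb)
}

# all strings over {A,B} of a given length
enum_strings <- function(len) {
  apply(do.call(expand.grid, rep(list(c("A", "B")), len)), 1, paste,
        collapse = "")
}

# independent regex oracle for the pattern classes
pattern_oracle <- function(s) {
  if (grepl("^A{2,}$", s)) "A_repeat"
  else if (grepl("^(BA)+$", s)) "BA"
  else if (grepl("^A+(BA)+$", s)) "A_BA"
  else if (grepl("^(BA)+A+$", s)) "BA_A"
  else "other"
}
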