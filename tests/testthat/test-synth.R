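# Synthetic corpus generator: configuration validation, determinism,
# calibration of the acoustic/interval/pattern distributions, and the
# rule-violation injector.

test_that("configuration invariants are enforced", {
  expect_s3_class(generator_config(), "callgram_config")
  bad <- generator_config()
  bad$pattern_probs$leopard <- c(A_repeat = 0.5, BA = 0.6, A_BA = 0, BA_A = 0)
  expect_error(validate_config(bad), "summing to 1")
  bad <- generator_config()
  bad$acoustic$A$freq_sd <- -1
  expect_error(validate_config(bad), "SDs must be > 0")
  bad <- generator_config()
  bad$truncation <- 0
  expect_error(validate_config(bad), "truncation")
  expect_error(generate_corpus(generator_config(), n_trials = c(5, 5)),
               "named")
})

test_that("a fixed seed makes the corpus byte-identical", {
  cfg <- generator_config(seed = 123)
  c1 <- suppressWarnings(generate_corpus(cfg, c(leopard = 10, eagle = 10)))
  c2 <- suppressWarnings(generate_corpus(cfg, c(leopard = 10, eagle = 10)))
  expect_identical(c1, c2)
  cfg2 <- generator_config(seed = 124)
  c3 <- suppressWarnings(generate_corpus(cfg2, c(leopard = 10, eagle = 10)))
  expect_false(identical(c1$calls, c3$calls))
})

test_that("silent stimuli yield no calls and trial layout obeys the design", {
  cfg <- generator_config(seed = 5)
  corp <- suppressWarnings(generate_corpus(cfg))
  chimp <- corp$trials$trial_id[corp$trials$stimulus == "chimpanzee"]
  expect_length(intersect(corp$calls$trial_id, chimp), 0)
  # elevation 'none' iff falling-tree stimulus (playback mode)
  expect_equal(corp$trials$elevation == "none", corp$trials$stimulus == "tree")
  vis <- suppressWarnings(generate_corpus(generator_config(seed = 6),
                                          c(leopard = 15, eagle = 10),
                                          mode = "visual_model"))
  expect_true(all(vis$trials$elevation == "none"))
  expect_length(intersect(vis$calls$trial_id,
                          vis$trials$trial_id[vis$trials$stimulus == "eagle"]), 0)
  # call-record invariants
  expect_true(all(corp$calls$duration > 0))
  expect_true(all(corp$calls$max_frequency > 0))
  expect_true(all(corp$calls$onset <= cfg$window))
  by_trial <- split(corp$calls$onset, corp$calls$trial_id)
  expect_true(all(vapply(by_trial, function(o) all(diff(o) > 0), TRUE)))
})

test_that("acoustic features match the truncated-normal moments", {
  cfg <- generator_config()
  set.seed(42)
  fa <- sample_call_features("A", cfg, 10000)
  # symmetric +/-3 SD truncation leaves the mean at 1.00 kHz
  expect_lt(abs(mean(fa$max_frequency) - 1.00), 0.01)
  expect_true(all(fa$max_frequency <= 1.00 + 3 * 0.16 + 1e-12))
  fb <- sample_call_features("B", cfg, 10000)
  # supports are disjoint under the defaults: 1.00+3*0.16 < 7.72-3*1.73
  expect_gt(min(fb$max_frequency), max(fa$max_frequency))
  # degenerate truncation pins features at the means
  cfg0 <- generator_config(truncation = 1e-4)
  f0 <- sample_call_features("A", cfg0, 100)
  expect_lt(max(abs(f0$max_frequency - 1.00)), 1e-3)
  expect_lt(max(abs(f0$duration - 0.12)), 1e-3)
})

test_that("interval draws match the truncated log-normal oracle", {
  cfg <- generator_config()
  set.seed(7)
  iv <- sample_intervals(cfg, 20000, 20000)
  # closed-form mean of a log-normal truncated above at t:
  #   E[X | X < t] = m * pnorm((log t - mu - s^2)/s) / pnorm((log t - mu)/s)
  p <- lognormal_params(0.12, 0.14)
  tr_mean_w <- 0.12 * stats::pnorm((log(1) - p["mu"] - p["sigma"]^2) / p["sigma"]) /
    stats::pnorm((log(1) - p["mu"]) / p["sigma"])
  expect_lt(abs(mean(iv$within) - tr_mean_w),
            3 * stats::sd(iv$within) / sqrt(length(iv$within)))
  # truncation shifts the within mean by < 0.005 s off the configured 0.12
  expect_lt(abs(tr_mean_w - 0.12), 0.005)
  p2 <- lognormal_params(22.8, 21.3)
  tr_mean_b <- (22.8 - 22.8 * stats::pnorm((log(2) - p2["mu"] - p2["sigma"]^2) / p2["sigma"])) /
    stats::pnorm(log(2), p2["mu"], p2["sigma"], lower.tail = FALSE)
  expect_lt(abs(mean(iv$between) - tr_mean_b),
            3 * stats::sd(iv$between) / sqrt(length(iv$between)))
  expect_lt(abs(tr_mean_b - 22.8), 0.2)
  expect_true(all(iv$within < 1) && all(iv$between > 2))
})

test_that("sequence strings obey their pattern grammar and the three rules", {
  set.seed(3)
  for (pat in c("A_repeat", "BA", "A_BA", "BA_A")) {
    s <- replicate(200, generate_sequence_string(pat))
    expect_true(all(nchar(s) >= 2))
    expect_true(all(as.character(classify_pattern(s)) == pat))
    rep_check <- check_rules(s)
    for (r in names(rep_check)) expect_true(rep_check[[r]]$holds)
  }
  expect_error(generate_sequence_string("BB_gram"))
})

test_that("generated corpora satisfy all rules across seeds", {
  for (seed in 1:5) {
    corp <- suppressWarnings(
      generate_corpus(generator_config(seed = seed),
                      c(leopard = 15, eagle = 15, tree = 15)))
    seqs <- segment_sequences(corp$calls, type_column = "true_type")$sequences
    rep <- check_rules(seqs$symbols)
    for (r in names(rep)) expect_true(rep[[r]]$holds)
  }
})

test_that("per-stimulus pattern frequencies converge to pattern_probs", {
  cfg <- generator_config(seed = 99)
  corp <- suppressWarnings(generate_corpus(cfg, c(leopard = 3700)))
  seqs <- segment_sequences(corp$calls, type_column = "true_type")$sequences
  expect_gt(nrow(seqs), 5000)
  pat <- classify_pattern(seqs$symbols)
  counts <- table(droplevels(pat))
  probs <- cfg$pattern_probs$leopard[names(counts)]
  expect_gt(stats::chisq.test(counts, p = probs / sum(probs))$p.value, 0.001)
  # BA share within the exact binomial 99% CI around 0.72
  n <- length(pat)
  ci <- stats::binom.test(sum(pat == "BA"), n, 0.72,
                          conf.level = 0.99)$conf.int
  expect_true(0.72 >= ci[1] && 0.72 <= ci[2])
})

test_that("rule-violation injection hits the named rule at the given rate", {
  set.seed(11)
  base <- replicate(400, generate_sequence_string(
    sample(c("A_repeat", "BA", "A_BA", "BA_A"), 1)))
  expect_error(inject_rule_violations(base, "B_singularity", 1.5), "rate")
  # rate 0 is the identity
  v0 <- inject_rule_violations(base, "A_suffixation", 0)
  expect_identical(v0$symbols, base)
  expect_length(v0$modified, 0)
  # rate 1: every sequence now contains "BB"
  v1 <- inject_rule_violations(base, "B_singularity", 1)
  expect_true(all(grepl("BB", v1$symbols, fixed = TRUE)))
  expect_equal(check_rules(v1$symbols)$B_singularity$fraction, 1)
  # rate 0.5: the rule report flags about half (binomial 99% band)
  v5 <- inject_rule_violations(base, "A_suffixation", 0.5)
  frac <- check_rules(v5$symbols)$A_suffixation$fraction
  expect_lt(abs(frac - 0.5), 2.58 * sqrt(0.25 / length(base)))
  # suffixation injection leaves the other two rules intact
  expect_true(check_rules(v5$symbols)$A_dominance$holds)
  expect_true(check_rules(v5$symbols)$B_singularity$holds)
  # dominance injection flags dominance on every modified sequence
  vd <- inject_rule_violations(base, "A_dominance", 1)
  expect_equal(check_rules(vd$symbols)$A_dominance$fraction, 1)
})
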