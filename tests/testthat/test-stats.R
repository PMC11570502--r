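# Count tables, the Laplace Poisson GLMM (against closed forms and the
# lme4/emmeans oracles), LRTs, contrasts, bootstrap CIs, stability,
# dispersion and response rates.

test_that("count tables hold explicit zeros, covariates and the log(N+1) offset", {
  seqs <- data.frame(trial_id = c("t1", "t1", "t1", "t2", "t3"),
                     symbols = c("BA", "BA", "ABA", "AAA", "BAA"),
                     start = c(1, 10, 40, 200, 5))
  trials <- data.frame(trial_id = c("t1", "t2", "t3"),
                       stimulus = c("leopard", "eagle", "eagle"),
                       group_location = c("north", "south", "north"),
                       responded = c(TRUE, TRUE, TRUE))
  tab <- build_count_table(seqs, trials, "initiation")
  t1 <- tab[tab$trial_id == "t1", ]
  expect_equal(t1$count[t1$level == "A"], 1L)   # ABA
  expect_equal(t1$count[t1$level == "B"], 2L)   # BA, BA
  expect_equal(unique(t1$offset), log(4))       # 3 sequences + 1
  # t2's only sequence starts beyond the window: trial drops out
  expect_false("t2" %in% tab$trial_id)
  expect_equal(attr(tab, "n_excluded_trials"), 1L)
  # t3 contributes an explicit zero for the unobserved A level
  t3 <- tab[tab$trial_id == "t3", ]
  expect_equal(t3$count[t3$level == "A"], 0L)
  expect_equal(sum(tab$count), 4L)
  expect_equal(levels(tab$stimulus)[1], "eagle")
  expect_error(build_count_table(seqs, trials, "shape"), "should be one of")
  # conservation on a generated corpus
  corp <- suppressWarnings(generate_corpus(generator_config(seed = 51),
                                           c(leopard = 20, eagle = 20)))
  sq <- segment_sequences(corp$calls, type_column = "true_type")$sequences
  tb <- build_count_table(sq, corp$trials, "initiation")
  expect_equal(sum(tb$count), nrow(sq))
})

test_that("GLMM reduces to closed forms and the ordinary Poisson GLM", {
  set.seed(52)
  y <- rpois(60, 4)
  tab <- data.frame(trial_id = sprintf("g%02d", 1:60), count = y)
  # intercept-only, vanishing random effect, no offset: log(mean(y))
  f0 <- fit_poisson_glmm(tab, ~1, sd_fixed = 1e-4)
  expect_equal(unname(f0$coefficients), log(mean(y)), tolerance = 1e-4)
  # with covariates, the sd->0 limit matches glm() to 1e-4
  tab2 <- sim_count_data(80, c(-0.5, -1, 0.6, 1), sigma = 0, seed = 53)
  fg <- fit_poisson_glmm(tab2, ~ level * stimulus, sd_fixed = 1e-4)
  ref <- glm(count ~ level * stimulus + offset(offset), poisson, tab2)
  expect_equal(unname(fg$coefficients), unname(coef(ref)), tolerance = 1e-4)
  # a huge ridge SD reproduces the unpenalized fit
  f1 <- fit_poisson_glmm(tab2, ~ level * stimulus)
  f2 <- fit_poisson_glmm(tab2, ~ level * stimulus, ridge_sd = 1e6)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-4)
})

test_that("GLMM matches the lme4 oracle on simulated data", {
  skip_if_not_installed("lme4")
  tab <- sim_count_data(100, c(-0.6, -1.8, -1, 3), sigma = 0.3, seed = 54)
  fit <- fit_poisson_glmm(tab, ~ level * stimulus)
  ref <- lme4::glmer(count ~ level * stimulus + offset(offset) +
                       (1 | trial_id), tab, poisson)
  expect_equal(unname(fit$coefficients), unname(lme4::fixef(ref)),
               tolerance = 1e-3)
  expect_equal(unname(fit$se), unname(sqrt(diag(as.matrix(vcov(ref))))),
               tolerance = 1e-3)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-5)
  expect_equal(fit$sd_intercept,
               sqrt(unname(unlist(lme4::VarCorr(ref)))), tolerance = 1e-3)
})

test_that("parameter recovery: estimates within 3 SE at n = 500 trials", {
  beta <- c(-0.6, -1.8, -1, 3)
  tab <- sim_count_data(500, beta, sigma = 0.3, seed = 55)
  fit <- fit_poisson_glmm(tab, ~ level * stimulus)
  expect_true(all(abs(fit$coefficients - beta) <= 3 * fit$se))
  expect_lt(abs(fit$sd_intercept - 0.3), 0.12)
})

test_that("ridge keeps a separated cell finite and warns without it", {
  set.seed(56)
  tab <- sim_count_data(60, c(0.5, 0, 0.3, 0), sigma = 0.2, seed = 56)
  tab$count[tab$level == "B" & tab$stimulus == "eagle"] <- 0L  # separation
  expect_warning(fit_poisson_glmm(tab, ~ level * stimulus), "separation")
  fr <- fit_poisson_glmm(tab, ~ level * stimulus, ridge_sd = 1)
  expect_true(all(is.finite(fr$coefficients)))
  expect_true(all(abs(fr$coefficients) < 10))
})

test_that("likelihood-ratio tests follow the chi-square recipe", {
  tab <- sim_count_data(80, c(-0.5, -1, 0.6, 1), sigma = 0.2, seed = 57)
  full <- fit_poisson_glmm(tab, ~ level * stimulus)
  red <- fit_poisson_glmm(tab, ~ level + stimulus)
  t <- lr_test(full, red)
  expect_equal(t$chi2, max(2 * (full$loglik - red$loglik), 0))
  expect_equal(t$df, 1)
  expect_equal(t$p_value, pchisq(t$chi2, 1, lower.tail = FALSE))
  same <- lr_test(full, full)
  expect_equal(same$chi2, 0)
  expect_equal(same$p_value, 1)
  other <- fit_poisson_glmm(sim_count_data(70, c(0, 0, 0, 0), 0.2, 58),
                            ~ level * stimulus)
  expect_error(lr_test(full, other), "same data")
})

test_that("drop1 respects marginality and flags the refit stage", {
  tab <- sim_count_data(90, c(-0.5, -1, 0.6, 2), sigma = 0.2, seed = 59)
  fit <- fit_poisson_glmm(tab, ~ level * stimulus)
  d1 <- drop1_interactions(fit)
  # only the interaction is droppable first, and it is strongly supported
  expect_equal(d1$term[!d1$refitted], "level:stimulus")
  expect_lt(d1$p_value[d1$term == "level:stimulus"], 0.001)
  # chi2 agrees with a manual lr_test on the same pair
  red <- fit_poisson_glmm(tab, ~ level + stimulus)
  expect_equal(d1$chi2[d1$term == "level:stimulus"],
               lr_test(fit, red)$chi2, tolerance = 1e-6)
  # without a real interaction the model is refitted and mains are tested
  tab0 <- sim_count_data(90, c(-0.5, -1, 0.6, 0), sigma = 0.2, seed = 60)
  d0 <- drop1_interactions(fit_poisson_glmm(tab0, ~ level * stimulus))
  expect_true(all(c("level", "stimulus") %in% d0$term[d0$refitted]))
})

test_that("pairwise contrasts agree with the emmeans oracle", {
  skip_if_not_installed("lme4")
  skip_if_not_installed("emmeans")
  tab <- sim_count_data(100, c(-0.6, -1.2, -0.8, 0.5, 1.5, 0.7),
                        sigma = 0.25, seed = 61,
                        stimuli = c("eagle", "leopard", "tree"))
  fit <- fit_poisson_glmm(tab, ~ level * stimulus)
  pc <- pairwise_contrasts(fit, "stimulus")
  expect_equal(nrow(pc), 3)                 # k(k-1)/2 for k = 3
  ref <- lme4::glmer(count ~ level * stimulus + offset(offset) +
                       (1 | trial_id), tab, poisson)
  em <- summary(emmeans::emmeans(ref, pairwise ~ stimulus,
                                 data = tab)$contrasts)
  expect_equal(pc$estimate, em$estimate, tolerance = 1e-3)
  expect_equal(pc$se, em$SE, tolerance = 1e-3)
  expect_equal(pc$p_adjusted, em$p.value, tolerance = 0.02)
  # a two-level factor gives a single contrast with no adjustment
  pc2 <- pairwise_contrasts(fit, "level")
  expect_equal(nrow(pc2), 1)
  expect_equal(pc2$p_adjusted, pc2$p_value, tolerance = 1e-6)
  # symmetric cells: contrast of equal cells is within 3 SE of zero
  tabs <- sim_count_data(150, c(-0.5, -1, 0, 0), sigma = 0.2, seed = 62)
  pcs <- pairwise_contrasts(fit_poisson_glmm(tabs, ~ level * stimulus),
                            "stimulus")
  expect_lt(abs(pcs$estimate), 3 * pcs$se)
})

test_that("bootstrap CIs are reproducible, bracket estimates, and shrink with information", {
  tab <- sim_count_data(60, c(-0.5, -1, 0.6, 1), sigma = 0.2, seed = 63)
  fit <- fit_poisson_glmm(tab, ~ level * stimulus)
  ci1 <- bootstrap_ci(fit, n_boot = 60, seed = 7)
  ci2 <- bootstrap_ci(fit, n_boot = 60, seed = 7)
  expect_identical(ci1, ci2)
  expect_true(all(ci1$lower < ci1$upper))
  # huge counts: interval width collapses
  set.seed(64)
  big <- data.frame(trial_id = sprintf("g%02d", 1:50),
                    count = rpois(50, 2000))
  bf <- fit_poisson_glmm(big, ~1, sd_fixed = 1e-4)
  bci <- bootstrap_ci(bf, n_boot = 60, seed = 8)
  expect_lt(bci$upper - bci$lower, 0.05)
})

test_that("leave-one-trial-out stability brackets the estimate", {
  tab <- sim_count_data(30, c(-0.3, -0.8, 0.4, 0.8), sigma = 0.2, seed = 65)
  # duplicate one trial so it has (near) zero leverage
  dup <- tab[tab$trial_id == "T0001", ]
  dup$trial_id <- "T0031"
  tab2 <- rbind(tab, dup)
  fit <- fit_poisson_glmm(tab2, ~ level * stimulus)
  st <- stability_analysis(fit)
  expect_equal(nrow(st), fit$npar_fixed)
  expect_true(all(st$min <= fit$coefficients + 1e-8))
  expect_true(all(st$max >= fit$coefficients - 1e-8))
  # an influential outlier trial widens the bracket
  out <- tab2
  out$count[out$trial_id == "T0002"] <- c(40L, 40L)
  sto <- stability_analysis(fit_poisson_glmm(out, ~ level * stimulus))
  expect_gt(max(sto$max - sto$min), max(st$max - st$min))
  few <- sim_count_data(2, c(0, 0, 0, 0), 0.1, 66)
  expect_error(stability_analysis(
    suppressWarnings(fit_poisson_glmm(few, ~level, ridge_sd = 1))), "3 groups")
})

test_that("dispersion check is calibrated and detects overdispersion", {
  tab <- sim_count_data(80, c(-0.3, -0.8, 0.4, 0.8), sigma = 0.2, seed = 67)
  fit <- fit_poisson_glmm(tab, ~ level * stimulus)
  dc <- dispersion_check(fit, n_sim = 200, seed = 1)
  expect_lt(abs(dc$ratio - 1), 0.15)
  expect_gt(dc$p_value, 0.05)
  # inject negative-binomial noise (size 0.5): ratio > 1, p small
  over <- tab
  set.seed(68)
  over$count <- rnbinom(nrow(over), size = 0.5,
                        mu = pmax(fit$fitted, 0.2))
  fo <- suppressWarnings(fit_poisson_glmm(over, ~ level * stimulus,
                                          ridge_sd = 1))
  do <- dispersion_check(fo, n_sim = 200, seed = 2)
  expect_gt(do$ratio, 1)
  expect_lt(do$p_value, 0.05)
  # constant counts stay well-defined
  const <- data.frame(trial_id = sprintf("g%02d", 1:20), count = rep(3L, 20))
  fc <- suppressWarnings(fit_poisson_glmm(const, ~1, sd_fixed = 1e-4))
  dcc <- dispersion_check(fc, n_sim = 50, seed = 3)
  expect_true(is.finite(dcc$ratio))
})

test_that("response rates match the generator probabilities and the window", {
  cfg <- generator_config(seed = 71)
  corp <- suppressWarnings(generate_corpus(cfg, c(leopard = 1000)))
  rr <- response_rate(corp$trials, corp$calls)
  ci <- binom.test(rr$n_responded, rr$n_trials, 0.614,
                   conf.level = 0.99)$conf.int
  expect_true(0.614 >= ci[1] && 0.614 <= ci[2])
  # silent stimulus reports 0%
  corp2 <- suppressWarnings(generate_corpus(generator_config(seed = 72),
                                            c(chimpanzee = 30, leopard = 10)))
  rr2 <- response_rate(corp2$trials, corp2$calls)
  expect_equal(rr2$rate[rr2$stimulus == "chimpanzee"], 0)
  # an empty window admits no responses
  rr0 <- response_rate(corp2$trials, corp2$calls, window = 0)
  expect_true(all(rr0$rate == 0))
})

test_that("context-dependent pattern probabilities drive the interaction LRT", {
  # published-scale contrasts between stimuli: decisive interaction
  corp <- suppressWarnings(generate_corpus(generator_config(seed = 73)))
  sq <- segment_sequences(corp$calls, type_column = "true_type")$sequences
  tab <- build_count_table(sq, corp$trials, "initiation")
  full <- suppressWarnings(fit_poisson_glmm(tab, ~ level * stimulus,
                                            ridge_sd = 1, se = FALSE))
  red <- suppressWarnings(fit_poisson_glmm(tab, ~ level + stimulus,
                                           ridge_sd = 1, se = FALSE))
  expect_lt(lr_test(full, red)$p_value, 0.001)
  # context-invariant probabilities: no systematic rejection
  cfg0 <- generator_config(seed = 74)
  flat <- c(A_repeat = 0.25, BA = 0.25, A_BA = 0.25, BA_A = 0.25)
  for (st in names(cfg0$pattern_probs)) cfg0$pattern_probs[[st]] <- flat
  rej <- vapply(1:12, function(r) {
    cfg0$seed <- 74 + r
    co <- suppressWarnings(generate_corpus(cfg0, c(leopard = 25, eagle = 25,
                                                   tree = 25)))
    s <- segment_sequences(co$calls, type_column = "true_type")$sequences
    tb <- build_count_table(s, co$trials, "initiation")
    f <- suppressWarnings(fit_poisson_glmm(tb, ~ level * stimulus,
                                           ridge_sd = 1, se = FALSE))
    r0 <- suppressWarnings(fit_poisson_glmm(tb, ~ level + stimulus,
                                            ridge_sd = 1, se = FALSE))
    lr_test(f, r0)$p_value < 0.05
  }, TRUE)
  expect_lte(sum(rej), 3)                   # ~5% nominal over 12 corpora
})
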