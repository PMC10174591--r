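test_that("bound transforms are inverse to each other and respect bounds", {
  spec <- model_spec("M12")
  x <- seq(-3, 3, length.out = spec$n_free_parameters)
  th <- fearvol:::to_natural(spec, x)
  expect_true(all(th > spec$free$lower & th < spec$free$upper))
  expect_equal(unname(fearvol:::to_unconstrained(spec, th)), x, tolerance = 1e-8)
})

test_that("MAP recovers generating parameters from a long session", {
  spec <- model_spec("M1")
  cfg <- task_config(trials_per_condition = 600, seed = 3)
  sch <- generate_schedule(cfg)
  truth <- theta_m1(rep(0.3, 4), rep(4, 4))
  sess <- simulate_agent(spec, truth, sch, seed = 8)
  f <- fit_map(spec, sess, fit_config(seed = 2, laplace_draws = 50))
  expect_true(all(abs(f$theta[1:4] - 0.3) < 0.1))
  expect_true(all(f$theta > spec$free$lower & f$theta < spec$free$upper))
})

test_that("a near-indifferent agent leaves learning rates unidentified and flagged", {
  spec <- model_spec("M1")
  sch <- generate_schedule(task_config(seed = 10))
  sess <- simulate_agent(spec, theta_m1(betas = rep(1e-6, 4)), sch, seed = 5)
  f <- fit_map(spec, sess, fit_config(seed = 2, n_restarts = 4,
                                      laplace_draws = 20))
  expect_true(any(grepl("^alpha", f$flat_params)))
})

test_that("WAIC matches an independent two-pass oracle", {
  expect_error(compute_waic(matrix(log(0.5), 1, 3)), "at least 2")
  expect_equal(compute_waic(matrix(log(0.5), 2, 1))$waic, -2 * log(0.5))

  set.seed(4)
  ll <- matrix(log(runif(60, 0.2, 0.9)), nrow = 10)
  # oracle: naive two-pass computation
  lppd <- sum(log(colMeans(exp(ll))))
  p_w <- sum(apply(ll, 2, function(x) sum((x - mean(x))^2) / (length(x) - 1)))
  w <- compute_waic(ll)
  expect_equal(w$waic, -2 * (lppd - p_w), tolerance = 1e-12)
})

test_that("PSIS-LOO reduces to WAIC for a degenerate posterior and matches exact LOO on a conjugate toy", {
  ll <- matrix(rep(log(c(0.3, 0.6, 0.8)), each = 5), nrow = 5)
  l <- compute_looic(ll)
  expect_equal(l$looic, -2 * sum(log(c(0.3, 0.6, 0.8))), tolerance = 1e-10)
  expect_equal(l$looic, compute_waic(ll)$waic, tolerance = 1e-10)

  # Bernoulli data with a Beta(1, 1) prior: the exact leave-one-out
  # predictive density is available in closed form
  y <- c(1, 1, 0)
  a0 <- 1; b0 <- 1
  set.seed(11)
  S <- 40000
  draws <- rbeta(S, a0 + sum(y), b0 + length(y) - sum(y))
  ll <- vapply(y, function(yi) if (yi == 1) log(draws) else log(1 - draws),
               numeric(S))
  exact <- vapply(seq_along(y), function(i) {
    a <- a0 + sum(y[-i]); b <- b0 + (length(y) - 1) - sum(y[-i])
    p1 <- a / (a + b)
    log(ifelse(y[i] == 1, p1, 1 - p1))
  }, 0)
  l <- compute_looic(ll)
  expect_equal(l$elpd_loo, sum(exact), tolerance = 0.01)
})

test_that("pseudo-R2 interpolates between chance and perfection", {
  expect_equal(pseudo_r2(100 * log(0.5), 100), 0)
  expect_equal(pseudo_r2(0, 100), 1)
  expect_equal(pseudo_r2(50 * log(0.5), 100), 0.5)
})

test_that("balanced accuracy matches a hand-worked confusion count", {
  # alpha = .5, beta = 8; choices 1,0,0,0 with outcomes 1,1,0,0.
  # Hand recursion: trial 1 is a tie (V = .5, half credit, class 1);
  # trial 2 predicts 1 but choice is 0 (wrong); trial 3 predicts 0 and
  # choice is 0 (right); trial 4 predicts 1 but choice is 0 (wrong).
  # So class-1 accuracy = 1/2, class-0 accuracy = 1/3.
  trials <- make_trials(rep("neut_freq", 4), c(1, 0, 0, 0), c(1, 1, 0, 0))
  sess <- make_session(trials)
  th <- theta_m1(rep(0.5, 4), rep(8, 4))
  res <- balanced_accuracy(model_spec("M1"), th, sess)
  expect_equal(res$value, (1 / 2 + 1 / 3) / 2)
  expect_equal(unname(res$per_class), c(1 / 3, 1 / 2))
  expect_false(res$degenerate)

  # a subject who always takes the rewarded option 1 is matched perfectly,
  # but only one choice class exists
  always <- make_session(make_trials(rep("neut_freq", 4), c(1, 1, 1, 1),
                                     c(1, 1, 1, 1)))
  res2 <- balanced_accuracy(model_spec("M1"), theta_m1(rep(.9, 4), rep(9, 4)),
                            always)
  expect_true(res2$degenerate)
  expect_equal(res2$per_class[["option1"]], 0.875)  # tie on the first trial

  # indifferent model earns exactly half credit everywhere
  res3 <- balanced_accuracy(model_spec("M1"), theta_m1(betas = rep(0, 4)), sess)
  expect_equal(res3$value, 0.5)
})

test_that("model comparison table has winner-relative deltas", {
  set.seed(3)
  cs <- cohort_spec(n_subjects = 4, seed = 6,
                    task = task_config(trials_per_condition = 30))
  gen <- generate_cohort(cs)
  cfg <- fit_config(seed = 1, n_restarts = 3, laplace_draws = 40)
  f1 <- fit_cohort_map(model_spec("M1"), gen$sessions, cfg)
  f2 <- fit_cohort_map(model_spec("M2"), gen$sessions, cfg)

  single <- compare_models(list(M1 = f1))
  expect_equal(single$delta_looic, 0)
  expect_identical(attr(single, "winner"), "M1")

  tab <- compare_models(list(M1 = f1, M2 = f2))
  expect_true(all(tab$delta_looic >= 0))
  expect_true(all(tab$delta_waic >= 0))
  expect_true(any(tab$delta_looic == 0))

  js <- jsonlite::fromJSON(fit_to_json(f1))
  expect_equal(js$model_id, "M1")
  expect_equal(js$looic, f1$looic)
  expect_equal(nrow(js$estimates), 4)

  other <- generate_cohort(cohort_spec(n_subjects = 4, seed = 99,
                                       task = task_config(trials_per_condition = 30)))
  f_other <- fit_cohort_map(model_spec("M2"), other$sessions, cfg)
  expect_error(compare_models(list(M1 = f1, M2 = f_other)), "identical sessions")
})

test_that("hierarchical fit shrinks toward the group and agrees with MAP", {
  set.seed(8)
  cs <- cohort_spec(n_subjects = 6, model_id = "M2", seed = 14,
                    task = task_config(trials_per_condition = 40))
  gen <- generate_cohort(cs)
  spec <- model_spec("M2")
  hcfg <- fit_config("hierarchical_mcmc", chains = 2, iterations = 400,
                     warmup = 200, seed = 9)
  h1 <- fit_hierarchical(spec, gen$sessions, hcfg)
  h2 <- fit_hierarchical(spec, gen$sessions, hcfg)
  expect_identical(h1$estimates, h2$estimates)   # seeded reproducibility

  mcfg <- fit_config(seed = 4, n_restarts = 4, laplace_draws = 40)
  m <- fit_cohort_map(spec, gen$sessions, mcfg)
  # pooled over parameters, hierarchical posterior means track MAP estimates
  expect_gt(cor(as.vector(h1$estimates), as.vector(m$estimates)), 0.8)
  # shrinkage: subject spread does not exceed the MAP spread on alphas
  a_cols <- grep("^alpha", colnames(m$estimates))
  expect_lte(mean(apply(h1$estimates[, a_cols], 2, sd)),
             mean(apply(m$estimates[, a_cols], 2, sd)) * 1.25)
  expect_true(all(h1$estimates > 0 & h1$estimates < 10))
})
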