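grid_small <- grid_spec(n_v = 30, n_sv = 20, n_k = 8)

test_that("uniform prior is normalized and symmetric", {
  g <- grid_small
  p <- init_prior(g)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(sum(apply(p, 1, sum) * g$v), 0.5, tolerance = 1e-10)
  sv_marg <- apply(p, 2, sum)
  expect_true(all(abs(sv_marg - 1 / g$n_sv) < 1e-12))
})

test_that("propagation conserves mass and is near-identity at the stable extreme", {
  g <- grid_small
  p <- init_prior(g)
  for (i in 1:5) {
    p <- propagate(p, g)
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
  # vanishing-width limit: the value kernel approaches the identity
  gtiny <- grid_spec(n_v = 30, n_sv = 2, sv_range = c(-14, -13.9),
                     n_k = 2, k_range = c(-6, -5.9))
  expect_gt(min(diag(gtiny$T_v[[1]])), 0.99)
  # smallest k: the SV random walk is nearly frozen
  expect_gt(min(diag(g$T_sv[[1]])), 0.99)
  # all kernels are row-stochastic
  expect_true(all(abs(vapply(g$T_v, rowSums, numeric(g$n_v)) - 1) < 1e-12))
  expect_true(all(abs(vapply(g$T_sv, rowSums, numeric(g$n_sv)) - 1) < 1e-12))
})

test_that("outcome updates shift and restore the value marginal symmetrically", {
  g <- grid_small
  p <- observe(init_prior(g), 1, g)
  expect_gt(sum(apply(p, 1, sum) * g$v), 0.5)
  p <- observe(p, 0, g)
  expect_equal(sum(apply(p, 1, sum) * g$v), 0.5, tolerance = 1e-10)
})

test_that("pure observation matches the conjugate Beta filter on the grid", {
  g <- grid_spec(n_v = 200, n_sv = 10, n_k = 5)
  p <- init_prior(g)
  y <- rep(1, 20)
  for (yi in y) p <- observe(p, yi, g)   # propagation off
  got <- sum(apply(p, 1, sum) * g$v)
  # conjugate oracle: uniform prior + 20 successes -> Beta(21, 1)
  expect_equal(got, 21 / 22, tolerance = 0.01)

  # monotonicity: every additional success raises the mean
  p <- init_prior(g); last <- 0.5
  for (i in 1:10) {
    p <- observe(p, 1, g)
    m <- sum(apply(p, 1, sum) * g$v)
    expect_gt(m, last)
    last <- m
  }
})

test_that("latent outcome mapping uses the anticorrelated structure", {
  expect_identical(infer_latent_outcome(1L, 1L, tracked_option = 1L), 1L)
  expect_identical(infer_latent_outcome(0L, 1L, tracked_option = 1L), 0L)
  expect_identical(infer_latent_outcome(0L, 0L, tracked_option = 1L), 1L)
  expect_true(is.na(infer_latent_outcome(NA, 0L)))
})

test_that("subjective volatility separates frequent from infrequent reversal schedules", {
  g <- grid_small
  sv_means <- vapply(1:12, function(seed) {
    cfg <- task_config(seed = seed)
    s <- simulate_oracle_session(cfg, seed = seed + 500)
    f <- filter_sequence(s, "neut_freq", g)
    i <- filter_sequence(s, "neut_infreq", g)
    c(freq = mean(f$sv_mean), infreq = mean(i$sv_mean))
  }, c(freq = 0, infreq = 0))
  expect_gt(mean(sv_means["freq", ]), mean(sv_means["infreq", ]))
  # and a reversal-free environment is calmer still
  calm <- filter_outcomes(rbinom(60, 1, 0.85), g)
  expect_lt(mean(calm$sv_mean), mean(sv_means["freq", ]))
})

test_that("subjective volatility rises after a reversal", {
  g <- grid_small
  # deterministic contingency with one reversal at trial 31
  y <- c(rep(1, 30), rep(0, 30))
  tr <- filter_outcomes(y, g)
  pre <- mean(tr$sv_mean[26:30])
  post <- mean(tr$sv_mean[33:38])
  expect_gt(post, pre)
})

test_that("missing trials propagate without observing", {
  g <- grid_small
  y <- c(1, 1, NA, 1)
  tr <- filter_outcomes(y, g)
  expect_equal(nrow(tr), 4L)
  expect_true(is.na(tr$y[3]))
  # the missing trial relaxes the value estimate (diffusion, no evidence)
  expect_lt(tr$v_mean[3], tr$v_mean[2])
})

test_that("value estimates are stable under grid refinement", {
  cfg <- task_config(seed = 33)
  s <- simulate_oracle_session(cfg, seed = 44)
  y <- with(s$trials[s$trials$condition == "fear_freq", ],
            infer_latent_outcome(choice, outcome))
  coarse <- filter_outcomes(y, grid_spec(n_v = 50, n_sv = 20, n_k = 8))
  fine <- filter_outcomes(y, grid_spec(n_v = 100, n_sv = 20, n_k = 8))
  expect_lt(max(abs(coarse$v_mean - fine$v_mean)), 0.02)
})

test_that("filtering a session condition returns a condition-local trace", {
  s <- simulate_oracle_session(task_config(seed = 3), seed = 9)
  tr <- filter_sequence(s, "fear_infreq", grid_small)
  expect_equal(nrow(tr), 60L)
  expect_identical(tr$condition_trial, 1:60)
  expect_true(all(tr$v_mean > 0 & tr$v_mean < 1))
  expect_true(all(tr$sv_mean >= min(grid_small$sv) &
                    tr$sv_mean <= max(grid_small$sv)))
  expect_error(filter_sequence(s, "nope", grid_small), "not present")
})
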