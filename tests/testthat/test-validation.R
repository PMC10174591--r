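test_that("hdi is the shortest window of sorted samples", {
  expect_equal(unname(hdi(rep(3.2, 10))), c(3.2, 3.2))
  expect_equal(unname(diff(hdi(1:100, 0.95))), 94)
  s <- rnorm(500)
  expect_identical(hdi(s), hdi(sample(s)))
  expect_error(hdi(1), "at least 2")
})

test_that("reversal curves recover the expected shapes", {
  cfg <- task_config(seed = 2)
  oracle <- lapply(1:5, function(i)
    simulate_oracle_session(task_config(seed = i), seed = i))
  rc <- reversal_curve(oracle, "neut_freq", window = 9)
  expect_true(all(rc$mean == 1))

  sch <- generate_schedule(cfg)
  chance <- lapply(1:8, function(i)
    simulate_agent(model_spec("M1"), theta_m1(betas = rep(0, 4)), sch, seed = i))
  rc0 <- reversal_curve(chance, "neut_freq", window = 9)
  expect_true(all(abs(rc0$mean - 0.5) < 0.2))

  learner <- lapply(1:10, function(i)
    simulate_agent(model_spec("M1"), theta_m1(rep(.5, 4), rep(6, 4)),
                   generate_schedule(task_config(seed = 100 + i)), seed = i))
  rcl <- reversal_curve(learner, "neut_freq", window = 9)
  expect_lt(rcl$mean[1], mean(rcl$mean[6:9]))   # dip then recovery

  expect_error(reversal_curve(oracle, "neut_freq", window = 12),
               "minimum inter-reversal")
  band <- reversal_curve_band(list(chance, learner), "neut_freq", 5)
  expect_true(all(band$hdi_lo <= band$hdi_hi))
})

test_that("WSLS rates match hand-counted transitions", {
  # one condition, 6 valid trials, hand-worked:
  # choices 1 1 0 0 1 1, outcomes 1 0 1 1 0 1
  tr <- make_trials(rep("fear_freq", 6), c(1, 1, 0, 0, 1, 1),
                    c(1, 0, 1, 1, 0, 1))
  w <- wsls_rate(make_session(tr))
  # wins at t1(stay), t3(stay), t4(switch); losses at t2(switch), t5(stay)
  expect_equal(w$win_stay, 2 / 3)
  expect_equal(w$loss_switch, 1 / 2)
  expect_equal(w$wsls_sum, 2 / 3 + 1 / 2)
  expect_equal(w$n_win, 3L)
  expect_equal(w$n_loss, 2L)

  stay <- make_trials(rep("fear_freq", 5), rep(1, 5), c(1, 0, 1, 0, 1))
  ws <- wsls_rate(make_session(stay))
  expect_equal(c(ws$win_stay, ws$loss_switch, ws$wsls_sum), c(1, 0, 1))

  alt <- make_trials(rep("fear_freq", 5), c(1, 0, 1, 0, 1), c(1, 0, 1, 0, 1))
  wa <- wsls_rate(make_session(alt))
  expect_equal(c(wa$win_stay, wa$loss_switch, wa$wsls_sum), c(0, 1, 1))

  # transitions never cross conditions
  mixed <- make_trials(c("fear_freq", "neut_freq", "fear_freq"),
                       c(1, 0, 1), c(1, 1, 1))
  wm <- wsls_rate(make_session(mixed))
  expect_equal(wm$n_win + wm$n_loss, 1L)
})

test_that("third-trial-after-reversal accuracy separates fast from slow learners", {
  oracle <- lapply(1:4, function(i)
    simulate_oracle_session(task_config(seed = i), seed = i))
  expect_equal(third_trial_accuracy(oracle, "neut_freq"), 1.0)

  mk <- function(alpha, n = 12) lapply(seq_len(n), function(i)
    simulate_agent(model_spec("M1"), theta_m1(rep(alpha, 4), rep(6, 4)),
                   generate_schedule(task_config(seed = 400 + i)), seed = i))
  chance <- lapply(1:12, function(i)
    simulate_agent(model_spec("M1"), theta_m1(betas = rep(0, 4)),
                   generate_schedule(task_config(seed = 400 + i)), seed = i))
  expect_lt(abs(third_trial_accuracy(chance, "neut_freq") - 0.5), 0.12)
  expect_gt(third_trial_accuracy(mk(0.75), "neut_freq"),
            third_trial_accuracy(mk(0.05), "neut_freq"))
})

test_that("posterior-predictive accuracy correlates with real accuracy for self-generated data", {
  set.seed(1)
  cs <- cohort_spec(n_subjects = 8, group_sd = 0.8, seed = 17)
  gen <- generate_cohort(cs)
  fit <- fit_cohort_map(model_spec("M1"), gen$sessions,
                        fit_config(seed = 2, n_restarts = 4, laplace_draws = 30))
  ppc <- posterior_predictive(fit, gen$sessions, n_rep = 30, seed = 5)
  expect_true(all(dim(ppc$real) == c(8, 4)))
  expect_gt(mean(ppc$correlations$r, na.rm = TRUE), 0.3)
  expect_error(posterior_predictive(fit, gen$sessions[1:2]), "at least 3")
})

test_that("parameter recovery reports per-parameter correlations", {
  set.seed(2)
  cs <- cohort_spec(n_subjects = 12, group_sd = 0.6, seed = 23)
  gp <- sample_group_parameters(cs)
  rep_ <- parameter_recovery(model_spec("M1"), gp$params,
                             config = fit_config(seed = 3, n_restarts = 4,
                                                 laplace_draws = 10))
  expect_named(rep_$param_cor, model_spec("M1")$free$name)
  expect_true(all(rep_$param_cor >= -1 & rep_$param_cor <= 1))
  expect_gt(mean(rep_$param_cor[1:4]), 0.3)
  expect_error(parameter_recovery(model_spec("M1"), gp$params[1:4, ]),
               "at least 10")
})

test_that("model recovery confusion counts sum to the number of replicates", {
  mr <- model_recovery("M2", n_replicates = 2, candidate_ids = c("M1", "M2"),
                       cohort = cohort_spec(n_subjects = 5, model_id = "M2",
                                            task = task_config(trials_per_condition = 40)),
                       config = fit_config(seed = 5, n_restarts = 3,
                                           laplace_draws = 40),
                       seed = 31)
  expect_equal(sum(mr$confusion), 2)
  expect_true(all(mr$winners %in% c("M1", "M2")))
})
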