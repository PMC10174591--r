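test_that("registry exposes twelve models with the expected free-parameter counts", {
  counts <- vapply(model_spec(), function(s) s$n_free_parameters, 0L)
  expect_identical(counts,
                   c(M1 = 8L, M2 = 4L, M3 = 5L, M4 = 8L, M5 = 9L, M6 = 9L,
                     M7 = 10L, M8 = 10L, M9 = 7L, M10 = 8L, M11 = 8L,
                     M12 = 11L))
  expect_error(model_spec("M99"), "unknown model")
  js <- jsonlite::fromJSON(spec_to_json(model_spec("M5")))
  expect_equal(js$n_free_parameters, 9)
  expect_equal(js$choice_rule, "softmax_lapse")
})

test_that("elementary update and choice rules match their closed forms", {
  expect_equal(unname(rw_update(0.5, 0.2, 1)), c(0.6, 0.4))
  expect_equal(unname(rw_update(0.7, 0, 1)["chosen"]), 0.7)
  expect_equal(unname(rw_update(0.7, 1, 0)["chosen"]), 0)
  expect_equal(unname(rw_update(0.5, 0.2, 1, two_arm = TRUE)), 0.6)
  expect_error(rw_update(1.5, 0.2, 1))

  expect_equal(softmax_choice(0.4, 0.4, 5), 0.5)
  expect_equal(softmax_choice(0.9, 0.1, 0), 0.5)
  expect_equal(softmax_choice(1, 0, 10), 1 / (1 + exp(-10)))

  expect_equal(lapse_choice(0.9, 0), 0.9)
  expect_equal(lapse_choice(0.123, 1), 0.5)
  expect_equal(lapse_choice(0.9, 0.2), 0.82)

  expect_equal(forgetting_update(0.9, 0.5), 0.7)
  expect_equal(forgetting_update(0.9, 1), 0.5)
  expect_equal(forgetting_update(0.9, 0), 0.9)

  h <- hybrid_update(V = 0.5, A = 0.5, delta = 0.5, omega = 0.2, kappa = 0.4)
  expect_equal(unname(h["value"]), 0.6)
  expect_equal(unname(h["associability"]), 0.8 * 0.5 + 0.2 * 0.5)
  h0 <- hybrid_update(0.5, 0.7, delta = 0, omega = 0.3, kappa = 0.4)
  expect_equal(unname(h0["value"]), 0.5)
  expect_equal(unname(h0["associability"]), 0.7 * 0.7)

  expect_equal(m12_link(0.2, 1, 0), 0.2)
  expect_equal(m12_link(0.2, 0.5, 0.1), 0.2)
  expect_equal(m12_link(0.5, 5, 0.9), 1 - 1e-6)
  expect_equal(m12_link(0.1, -2, 0), 1e-6)
})

test_that("indifferent policy yields exactly chance likelihood", {
  set.seed(9)
  trials <- make_trials(sample(CONDITIONS, 40, TRUE),
                        sample(0:1, 40, TRUE), sample(0:1, 40, TRUE))
  sess <- make_session(trials)
  th <- theta_m1(betas = rep(0, 4))
  ll <- session_loglik(model_spec("M1"), th, sess)
  expect_equal(ll$total, 40 * log(0.5))
  expect_true(all(ll$p1 == 0.5))
})

test_that("likelihood agrees with the independent hand recursion for all models", {
  set.seed(31)
  for (rep in 1:6) {
    n <- 12
    trials <- make_trials(sample(CONDITIONS, n, TRUE),
                          sample(0:1, n, TRUE), sample(0:1, n, TRUE),
                          missing = runif(n) < 0.15)
    trials$choice[trials$missing] <- NA
    sess <- make_session(trials)
    for (id in names(model_spec())) {
      th <- make_theta(id)
      got <- session_loglik(model_spec(id), th, sess)
      want <- oracle_loglik(id, th, trials)
      expect_equal(got$total, want$total, tolerance = 1e-12,
                   info = paste(id, "rep", rep))
      expect_equal(got$pointwise, want$pointwise, tolerance = 1e-12)
    }
  }
})

test_that("nested models collapse onto M1 at their boundary parameters", {
  set.seed(13)
  trials <- make_trials(sample(CONDITIONS, 60, TRUE),
                        sample(0:1, 60, TRUE), sample(0:1, 60, TRUE))
  sess <- make_session(trials)
  al <- c(.2, .3, .4, .15); be <- c(2, 3, 4, 5)
  base <- session_loglik(model_spec("M1"), theta_m1(al, be), sess)$total

  # M3 with its shared beta equals M1 with four equal betas
  m3 <- stats::setNames(c(al, 3), model_spec("M3")$free$name)
  m1_eq <- session_loglik(model_spec("M1"), theta_m1(al, rep(3, 4)), sess)$total
  expect_equal(session_loglik(model_spec("M3"), m3, sess)$total, m1_eq)

  m5 <- stats::setNames(c(al, be, 0), model_spec("M5")$free$name)
  expect_equal(session_loglik(model_spec("M5"), m5, sess)$total, base)
  for (id in c("M6", "M7", "M8")) {
    spec <- model_spec(id)
    th <- stats::setNames(c(al, be, rep(0, spec$n_free_parameters - 8)),
                          spec$free$name)
    expect_equal(session_loglik(spec, th, sess)$total, base, info = id)
  }
  m12 <- stats::setNames(
    c(al[4], be, 1, al[1], 1, al[2], 1, al[3]),
    c("alpha.neut_infreq", paste0("beta.", CONDITIONS),
      "k.fear_freq", "b.fear_freq", "k.fear_infreq", "b.fear_infreq",
      "k.neut_freq", "b.neut_freq"))
  # identity links: k = 0 slope with intercept = target rate
  m12[c("k.fear_freq", "k.fear_infreq", "k.neut_freq")] <- 0
  m12[c("b.fear_freq", "b.fear_infreq", "b.neut_freq")] <- al[1:3]
  expect_equal(session_loglik(model_spec("M12"), m12, sess)$total, base)
})

test_that("likelihood is invariant to relabeling options together with choices", {
  set.seed(77)
  trials <- make_trials(sample(CONDITIONS, 50, TRUE),
                        sample(0:1, 50, TRUE), sample(0:1, 50, TRUE))
  flipped <- trials
  flipped$choice <- 1L - flipped$choice
  th <- theta_m1()
  expect_equal(session_loglik(model_spec("M1"), th, make_session(trials))$total,
               session_loglik(model_spec("M1"), th, make_session(flipped))$total)
})

test_that("choice probabilities are proper for every model", {
  set.seed(5)
  trials <- make_trials(sample(CONDITIONS, 80, TRUE),
                        sample(0:1, 80, TRUE), sample(0:1, 80, TRUE))
  sess <- make_session(trials)
  for (id in names(model_spec())) {
    p1 <- session_loglik(model_spec(id), make_theta(id), sess)$p1
    expect_true(all(p1 > 0 & p1 < 1), info = id)
  }
})

test_that("simulated agents behave sensibly and are seed-reproducible", {
  cfg <- task_config(seed = 21)
  sch <- generate_schedule(cfg)
  spec <- model_spec("M1")

  a <- simulate_agent(spec, theta_m1(), sch, seed = 4)
  b <- simulate_agent(spec, theta_m1(), sch, seed = 4)
  expect_identical(a$trials, b$trials)

  # indifferent agent sits at chance accuracy
  acc0 <- mean(vapply(1:20, function(i)
    mean(with(simulate_agent(spec, theta_m1(betas = rep(0, 4)),
                             sch, seed = i)$trials,
              choice == high_option)), 0))
  expect_lt(abs(acc0 - 0.5), 0.03)

  # decisive fast learner is well above chance
  sharp <- simulate_agent(spec, theta_m1(rep(0.9, 4), rep(9.9, 4)), sch, seed = 2)
  expect_gt(mean(sharp$trials$choice == sharp$trials$high_option), 0.7)

  # missing trials earn nothing and are marked consistently
  m <- simulate_agent(spec, theta_m1(), sch, seed = 6, missing_rate = 0.08)
  expect_true(any(m$trials$missing))
  expect_true(all(m$trials$outcome[m$trials$missing] == 0L))
  expect_true(all(is.na(m$trials$choice[m$trials$missing])))
})
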