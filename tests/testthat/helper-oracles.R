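# Independent reference implementations used as oracles. These are written
# as plain, explicit recursions with their own parameter bookkeeping so they
# share no code path with the package internals they check.

ORACLE_CONDS <- c("fear_freq", "fear_infreq", "neut_freq", "neut_infreq")

oracle_resolve <- function(model_id, theta) {
  conds <- ORACLE_CONDS
  vol <- c("freq", "infreq", "freq", "infreq")
  cue <- c("fear", "fear", "neut", "neut")
  pick <- function(p, mode) {
    key <- switch(mode, cond = conds, vol = vol, cue = cue,
                  shared = rep("shared", 4))
    unname(theta[paste0(p, ".", key)])
  }
  zero <- rep(0, 4)
  pp <- switch(model_id,
    M1 = list(update = "one", alpha = pick("alpha", "cond"),
              beta = pick("beta", "cond"), eps = zero, phi = zero),
    M2 = list(update = "one", alpha = pick("alpha", "vol"),
              beta = pick("beta", "vol"), eps = zero, phi = zero),
    M3 = list(update = "one", alpha = pick("alpha", "cond"),
              beta = pick("beta", "shared"), eps = zero, phi = zero),
    M4 = list(update = "two", alpha = pick("alpha", "cond"),
              beta = pick("beta", "cond"), eps = zero, phi = zero),
    M5 = list(update = "one", alpha = pick("alpha", "cond"),
              beta = pick("beta", "cond"), eps = pick("eps", "shared"),
              phi = zero),
    M6 = list(update = "one", alpha = pick("alpha", "cond"),
              beta = pick("beta", "cond"), eps = zero,
              phi = pick("phi", "shared")),
    M7 = list(update = "one", alpha = pick("alpha", "cond"),
              beta = pick("beta", "cond"), eps = zero,
              phi = pick("phi", "vol")),
    M8 = list(update = "one", alpha = pick("alpha", "cond"),
              beta = pick("beta", "cond"), eps = zero,
              phi = pick("phi", "cue")),
    M9 = list(update = "hyb", beta = pick("beta", "cond"), eps = zero,
              phi = zero, omega = pick("omega", "shared"),
              kappa = pick("kappa", "shared"), a0 = pick("a0", "shared")),
    M10 = list(update = "hyb", beta = pick("beta", "cond"), eps = zero,
               phi = zero, omega = pick("omega", "cue"),
               kappa = pick("kappa", "shared"), a0 = pick("a0", "shared")),
    M11 = list(update = "hyb", beta = pick("beta", "cond"), eps = zero,
               phi = zero, omega = pick("omega", "shared"),
               kappa = pick("kappa", "cue"), a0 = pick("a0", "shared")),
    M12 = {
      ab <- unname(theta["alpha.neut_infreq"])
      clip <- function(x) min(max(x, 1e-6), 1 - 1e-6)
      al <- c(clip(theta[["k.fear_freq"]] * ab + theta[["b.fear_freq"]]),
              clip(theta[["k.fear_infreq"]] * ab + theta[["b.fear_infreq"]]),
              clip(theta[["k.neut_freq"]] * ab + theta[["b.neut_freq"]]),
              ab)
      list(update = "one", alpha = al, beta = pick("beta", "cond"),
           eps = zero, phi = zero)
    })
  pp
}

oracle_loglik <- function(model_id, theta, trials) {
  pp <- oracle_resolve(model_id, theta)
  v1 <- rep(0.5, 4); v0 <- rep(0.5, 4)
  A <- if (pp$update == "hyb") pp$a0 else rep(0, 4)
  pw <- numeric(0)
  for (i in seq_len(nrow(trials))) {
    cc <- match(trials$condition[i], ORACLE_CONDS)
    if (pp$update == "two") { V1 <- v1[cc]; V0 <- v0[cc] }
    else { V1 <- v1[cc]; V0 <- 1 - v1[cc] }
    p1 <- 1 / (1 + exp(-pp$beta[cc] * (V1 - V0)))
    p1 <- (1 - pp$eps[cc]) * p1 + pp$eps[cc] / 2
    if (!trials$missing[i]) {
      ch <- trials$choice[i]; o <- trials$outcome[i]
      pc <- if (ch == 1) p1 else 1 - p1
      pw <- c(pw, log(max(pc, 1e-12)))
      Vc <- if (ch == 1) V1 else V0
      if (pp$update == "hyb") {
        d <- o - Vc
        Vn <- Vc + pp$kappa[cc] * A[cc] * d
        A[cc] <- (1 - pp$omega[cc]) * A[cc] + pp$omega[cc] * abs(d)
      } else {
        Vn <- Vc + pp$alpha[cc] * (o - Vc)
      }
      if (pp$update == "two") {
        if (ch == 1) v1[cc] <- Vn else v0[cc] <- Vn
      } else {
        v1[cc] <- if (ch == 1) Vn else 1 - Vn
      }
    }
    for (d in 1:4) {
      v1[d] <- v1[d] + pp$phi[d] * (0.5 - v1[d])
      if (pp$update == "two") v0[d] <- v0[d] + pp$phi[d] * (0.5 - v0[d])
    }
  }
  list(total = sum(pw), pointwise = pw)
}

# hand-built trial frame wrapped as a session
make_trials <- function(condition, choice, outcome,
                        missing = rep(FALSE, length(condition))) {
  n <- length(condition)
  ct <- stats::ave(seq_len(n), condition, FUN = seq_along)
  data.frame(subject_id = "toy", global_trial = seq_len(n),
             condition = condition,
             condition_cue = sub("_(freq|infreq)$", "", condition),
             condition_volatility = sub("^(fear|neut)_", "", condition),
             condition_trial = ct, choice = choice, outcome = outcome,
             missing = missing, high_option = rep(1L, n),
             stringsAsFactors = FALSE)
}

make_session <- function(trials, config = task_config()) {
  structure(list(trials = trials, config = config, schedule = NULL),
            class = "session_data")
}

# default free-parameter vector for any model, with overrides by name
make_theta <- function(model_id, overrides = c()) {
  spec <- model_spec(model_id)
  base <- c(alpha = 0.3, beta = 3, eps = 0.1, phi = 0.1, omega = 0.4,
            kappa = 0.5, a0 = 0.5, k = 1, b = 0)
  th <- stats::setNames(base[spec$free$param], spec$free$name)
  th[names(overrides)] <- overrides
  th
}

# M1 parameters in canonical order ff, fi, nf, ni
theta_m1 <- function(alphas = c(.25, .25, .35, .15), betas = rep(3, 4)) {
  stats::setNames(c(alphas, betas), model_spec("M1")$free$name)
}
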