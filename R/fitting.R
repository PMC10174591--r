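#' Fitting configuration
#'
#' @param backend `"map"` (per-subject maximum a posteriori with a Laplace
#'   approximation for posterior draws) or `"hierarchical_mcmc"` (group-level
#'   random-effects model sampled by adaptive Metropolis-within-Gibbs).
#' @param chains,iterations,warmup MCMC budget per chain; the reference
#'   budget is 4 chains x 4000 iterations, reduced configurations are used
#'   for quick runs.
#' @param seed integer seed.
#' @param n_restarts seeded multi-start count for the MAP optimiser.
#' @param laplace_draws posterior draws taken from the Laplace approximation
#'   of each subject's posterior (MAP backend).
#' @param prior_mean_sd sd of the Normal(0, .) prior on unconstrained group
#'   means (and on unconstrained subject parameters in the MAP backend).
#' @param prior_scale_sd sd of the half-Normal prior on group scales.
#' @return a `fit_config` object.
#' @export
fit_config <- function(backend = c("map", "hierarchical_mcmc"),
                       chains = 4L, iterations = 4000L,
                       warmup = floor(iterations / 2),
                       seed = 1L, n_restarts = 10L, laplace_draws = 200L,
                       prior_mean_sd = 1, prior_scale_sd = 1) {
  backend <- match.arg(backend)
  stopifnot(iterations > warmup, warmup >= 0, chains >= 1)
  structure(list(backend = backend, chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup = as.integer(warmup), seed = as.integer(seed),
                 n_restarts = as.integer(n_restarts),
                 laplace_draws = as.integer(laplace_draws),
                 prior_mean_sd = prior_mean_sd,
                 prior_scale_sd = prior_scale_sd),
            class = "fit_config")
}

# bounded parameters live on an unconstrained scale through a scaled
# inverse-probit: theta = lower + (upper - lower) * pnorm(x)
to_natural <- function(spec, x) {
  fr <- spec$free
  p <- pmin(pmax(pnorm(x), 1e-9), 1 - 1e-9)   # keep strictly inside bounds
  stats::setNames(fr$lower + (fr$upper - fr$lower) * p, fr$name)
}

to_unconstrained <- function(spec, theta) {
  fr <- spec$free
  stats::setNames(qnorm((theta[fr$name] - fr$lower) / (fr$upper - fr$lower)),
                  fr$name)
}

.neg_logpost <- function(x, spec, trials, prior_mean, prior_sd) {
  theta <- to_natural(spec, x)
  res <- .forward(spec, theta, trials)
  -(res$total + sum(dnorm(x, prior_mean, prior_sd, log = TRUE)))
}

.data_hash <- function(sessions) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  paste(vapply(sessions, function(s)
    sum(s$trials$choice * 3 + s$trials$outcome, na.rm = TRUE) +
      nrow(s$trials), 0), collapse = "|")
}

#' Per-subject MAP fit with Laplace posterior draws
#'
#' Maximises the session log-likelihood plus a weakly informative
#' Normal(0, 1) log-prior on the unconstrained scale, using seeded
#' multi-start BFGS. Posterior draws are taken from the Gaussian (Laplace)
#' approximation at the mode and mapped through the bound transforms; the
#' per-draw pointwise log-likelihoods feed WAIC/LOO.
#'
#' @param spec a `model_spec`.
#' @param session a `session_data`.
#' @param config a [fit_config()].
#' @param prior_mean,prior_sd optional per-parameter prior location/scale
#'   on the unconstrained scale (defaults: 0 and `config$prior_mean_sd`);
#'   used by the cohort fitter to shrink subjects toward the group.
#' @return object of class `map_fit`: `theta` (natural-scale point
#'   estimate), `logpost`, `loglik`, `pointwise`, `draws` (natural-scale
#'   Laplace draws), `ll_draws` (draws x valid trials), `flat_params`
#'   (parameters whose posterior is nearly as wide as the prior, i.e.
#'   poorly identified).
#' @export
fit_map <- function(spec, session, config = fit_config(),
                    prior_mean = NULL, prior_sd = NULL) {
  trials <- session$trials
  if (all(trials$missing)) stop("no valid trials to fit", call. = FALSE)
  for (cond in unique(trials$condition)) {
    if (all(trials$missing[trials$condition == cond]))
      stop("all trials missing in condition ", cond, call. = FALSE)
  }
  P <- spec$n_free_parameters
  if (is.null(prior_mean)) prior_mean <- rep(0, P)
  if (is.null(prior_sd)) prior_sd <- rep(config$prior_mean_sd, P)
  set.seed(config$seed)
  starts <- matrix(rnorm(config$n_restarts * P, 0, 1), ncol = P)
  starts <- sweep(sweep(starts, 2, prior_sd, "*"), 2, prior_mean, "+")
  starts[1, ] <- prior_mean
  best <- NULL
  for (i in seq_len(config$n_restarts)) {
    o <- tryCatch(optim(starts[i, ], .neg_logpost, spec = spec,
                        trials = trials, prior_mean = prior_mean,
                        prior_sd = prior_sd,
                        method = "BFGS", control = list(maxit = 300)),
                  error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("all optimiser restarts failed", call. = FALSE)
  H <- optimHess(best$par, .neg_logpost, spec = spec, trials = trials,
                 prior_mean = prior_mean, prior_sd = prior_sd)
  # regularise until positive definite
  ridge <- 0
  repeat {
    ch <- tryCatch(chol(H + diag(ridge, P)), error = function(e) NULL)
    if (!is.null(ch)) break
    ridge <- if (ridge == 0) 1e-6 else ridge * 10
    if (ridge > 1e3) { ch <- diag(sqrt(1 + ridge), P); break }
  }
  Sigma <- chol2inv(ch)
  sds <- sqrt(pmax(diag(Sigma), 0))
  L <- tryCatch(chol(Sigma), error = function(e) diag(sds, P))

  set.seed(config$seed + 77L)
  S <- config$laplace_draws
  Z <- matrix(rnorm(S * P), S, P)
  X <- sweep(Z %*% L, 2, best$par, "+")
  theta_hat <- to_natural(spec, best$par)
  pt <- session_loglik(spec, theta_hat, session)
  ll_draws <- matrix(NA_real_, S, length(pt$pointwise))
  for (s in seq_len(S)) {
    ll_draws[s, ] <- session_loglik(spec, to_natural(spec, X[s, ]),
                                    session)$pointwise
  }
  flat <- spec$free$name[sds > 0.9 * prior_sd]
  structure(list(model_id = spec$model_id, theta = theta_hat,
                 theta_unc = stats::setNames(best$par, spec$free$name),
                 logpost = -best$value, loglik = pt$total,
                 pointwise = pt$pointwise, draws_unc = X,
                 draws = t(apply(X, 1, function(x) to_natural(spec, x))),
                 ll_draws = ll_draws, flat_params = flat,
                 n_valid = length(pt$pointwise)),
            class = "map_fit")
}

#' Fit a model to a cohort, subject by subject (MAP backend)
#'
#' Two-pass empirical-Bayes procedure: subjects are first fitted
#' independently under the weakly informative prior; the unconstrained
#' estimates then define a group prior (their mean and spread, with a
#' floor on the spread), under which every subject is refitted. This
#' shrinks poorly identified subjects toward the group rather than toward
#' the arbitrary prior centre, the fixed-budget analogue of the
#' hierarchical model's partial pooling. Laplace draws of all subjects are
#' combined column-wise into one pointwise log-likelihood matrix (the
#' posterior factorises over subjects), from which cohort-level WAIC,
#' PSIS-LOO, pseudo-R2 and balanced accuracy are computed.
#'
#' @param spec a `model_spec`.
#' @param sessions list of `session_data`.
#' @param config a [fit_config()].
#' @param empirical_bayes set `FALSE` to skip the group-prior second pass.
#' @return object of class `cohort_fit` exposing `estimates` (subjects x
#'   free parameters, natural scale), `ll_matrix`, `looic`, `waic`,
#'   `pseudo_r2`, `balanced_accuracy`, `pareto_k`, `group_mean`,
#'   `group_scale` (unconstrained-scale group prior of the second pass).
#' @export
fit_cohort_map <- function(spec, sessions, config = fit_config(),
                           empirical_bayes = TRUE) {
  fits <- vector("list", length(sessions))
  for (i in seq_along(sessions)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i * 131L
    fits[[i]] <- fit_map(spec, sessions[[i]], cfg_i)
  }
  mu <- rep(0, spec$n_free_parameters)
  sdv <- rep(config$prior_mean_sd, spec$n_free_parameters)
  if (empirical_bayes && length(sessions) >= 3) {
    X1 <- do.call(rbind, lapply(fits, function(f) f$theta_unc))
    mu <- colMeans(X1)
    sdv <- pmax(apply(X1, 2, sd), 0.3)
    for (i in seq_along(sessions)) {
      cfg_i <- config
      cfg_i$seed <- config$seed + i * 131L + 17L
      fits[[i]] <- fit_map(spec, sessions[[i]], cfg_i,
                           prior_mean = mu, prior_sd = sdv)
    }
  }
  est <- do.call(rbind, lapply(fits, function(f) f$theta))
  rownames(est) <- vapply(sessions, function(s) s$trials$subject_id[1], "")
  ll_matrix <- do.call(cbind, lapply(fits, function(f) f$ll_draws))
  total_ll <- sum(vapply(fits, function(f) f$loglik, 0))
  n_valid <- sum(vapply(fits, function(f) f$n_valid, 0L))
  ba <- mean(vapply(seq_along(sessions), function(i)
    balanced_accuracy(spec, fits[[i]]$theta, sessions[[i]])$value, 0))
  w <- compute_waic(ll_matrix)
  l <- compute_looic(ll_matrix)
  structure(list(model_id = spec$model_id, backend = "map",
                 subject_fits = fits, estimates = est,
                 group_mean = stats::setNames(mu, spec$free$name),
                 group_scale = stats::setNames(sdv, spec$free$name),
                 ll_matrix = ll_matrix, loglik = total_ll,
                 n_valid = n_valid, waic = w$waic, looic = l$looic,
                 pareto_k = l$pareto_k,
                 pseudo_r2 = pseudo_r2(total_ll, n_valid),
                 balanced_accuracy = ba,
                 n_free_parameters = spec$n_free_parameters,
                 data_hash = .data_hash(sessions)),
            class = "cohort_fit")
}

# log posterior pieces for the hierarchical model ---------------------------

.hier_subject_ll <- function(spec, trials, mu, sigma, z) {
  theta <- to_natural(spec, mu + sigma * z)
  .forward(spec, theta, trials)$total
}

#' Hierarchical Bayesian fit of a cohort
#'
#' Non-centered random-effects model on the unconstrained scale: for free
#' parameter p and subject s, `x_sp = mu_p + sigma_p * z_sp`, with
#' `mu_p ~ Normal(0, 1)`, `sigma_p ~ half-Normal(0, 1)`, `z_sp ~ Normal(0,
#' 1)`, and bounded parameters obtained by scaled inverse-probit. Sampling
#' is adaptive random-walk Metropolis-within-Gibbs: one block per subject
#' (the z-vector) and one per parameter (mu, log sigma), with proposal
#' scales tuned toward 30% acceptance during warmup. Per-subject point
#' estimates are posterior means of the natural-scale parameters.
#'
#' @param spec a `model_spec`.
#' @param sessions list of at least two `session_data`.
#' @param config a [fit_config()] (use reduced budgets for quick runs).
#' @param init optional warm start: a `cohort_fit` from [fit_cohort_map()]
#'   (chains start near its group solution, shortening warmup), or a list
#'   with `mu`, `sigma`, `Z`.
#' @return object of class `hier_fit` with `estimates`, `group_mean`,
#'   `group_scale` (posterior means), `draws` (list of arrays), `ll_matrix`,
#'   `looic`, `waic`, `pseudo_r2`, `balanced_accuracy`, `diagnostics`
#'   (split R-hat per group parameter, acceptance rates, warnings).
#' @export
fit_hierarchical <- function(spec, sessions,
                             config = fit_config("hierarchical_mcmc"),
                             init = NULL) {
  stopifnot(length(sessions) >= 2)
  if (inherits(init, "cohort_fit")) {
    X <- do.call(rbind, lapply(init$subject_fits, function(f) f$theta_unc))
    mu0 <- colMeans(X)
    sig0 <- pmax(apply(X, 2, sd), 0.1)
    init <- list(mu = mu0, sigma = sig0,
                 Z = sweep(sweep(X, 2, mu0), 2, sig0, "/"))
  }
  S <- length(sessions)
  P <- spec$n_free_parameters
  trials_list <- lapply(sessions, `[[`, "trials")
  n_save <- config$iterations - config$warmup
  n_chains <- config$chains
  nv <- vapply(trials_list, function(tr) sum(!tr$missing), 0L)
  N <- sum(nv)

  mu_draws <- array(NA_real_, c(n_save, n_chains, P))
  sigma_draws <- array(NA_real_, c(n_save, n_chains, P))
  theta_sum <- matrix(0, S, P)     # running sum of natural draws
  ll_matrix <- matrix(NA_real_, n_save * n_chains, N)
  accept <- c(z = 0, grp = 0)

  for (ch in seq_len(n_chains)) {
    set.seed(config$seed + 1000L * ch)
    if (is.null(init)) {
      mu <- rnorm(P, 0, 0.1); log_sig <- rnorm(P, log(0.5), 0.1)
      Z <- matrix(rnorm(S * P, 0, 0.1), S, P)
    } else {
      mu <- init$mu + rnorm(P, 0, 0.02)
      log_sig <- log(init$sigma) + rnorm(P, 0, 0.02)
      Z <- init$Z + matrix(rnorm(S * P, 0, 0.02), S, P)
    }
    step_z <- rep(0.15, S); step_g <- rep(0.1, P)
    cur_ll <- vapply(seq_len(S), function(s)
      .hier_subject_ll(spec, trials_list[[s]], mu, exp(log_sig), Z[s, ]), 0)
    n_acc_z <- rep(0, S); n_acc_g <- rep(0, P); n_try <- 0

    for (it in seq_len(config$iterations)) {
      sig <- exp(log_sig)
      # subject blocks
      for (s in seq_len(S)) {
        z_prop <- Z[s, ] + rnorm(P, 0, step_z[s])
        ll_prop <- .hier_subject_ll(spec, trials_list[[s]], mu, sig, z_prop)
        log_r <- (ll_prop + sum(dnorm(z_prop, log = TRUE))) -
                 (cur_ll[s] + sum(dnorm(Z[s, ], log = TRUE)))
        if (log(runif(1)) < log_r) {
          Z[s, ] <- z_prop; cur_ll[s] <- ll_prop; n_acc_z[s] <- n_acc_z[s] + 1
        }
      }
      # group blocks: (mu_p, log sigma_p) jointly
      for (p in seq_len(P)) {
        mu_p <- mu; ls_p <- log_sig
        mu_p[p] <- mu[p] + rnorm(1, 0, step_g[p])
        ls_p[p] <- log_sig[p] + rnorm(1, 0, step_g[p])
        sig_p <- exp(ls_p)
        ll_prop <- vapply(seq_len(S), function(s)
          .hier_subject_ll(spec, trials_list[[s]], mu_p, sig_p, Z[s, ]), 0)
        log_r <- (sum(ll_prop) + dnorm(mu_p[p], 0, config$prior_mean_sd, log = TRUE) +
                    dnorm(sig_p[p], 0, config$prior_scale_sd, log = TRUE) + ls_p[p]) -
                 (sum(cur_ll) + dnorm(mu[p], 0, config$prior_mean_sd, log = TRUE) +
                    dnorm(exp(log_sig[p]), 0, config$prior_scale_sd, log = TRUE) + log_sig[p])
        if (log(runif(1)) < log_r) {
          mu <- mu_p; log_sig <- ls_p; cur_ll <- ll_prop
          n_acc_g[p] <- n_acc_g[p] + 1
        }
      }
      n_try <- n_try + 1
      # warmup adaptation toward ~30% acceptance
      if (it <= config$warmup && it %% 50 == 0) {
        rz <- n_acc_z / n_try; rg <- n_acc_g / n_try
        step_z <- step_z * exp(pmin(pmax(rz - 0.3, -0.3), 0.3))
        step_g <- step_g * exp(pmin(pmax(rg - 0.3, -0.3), 0.3))
      }
      if (it > config$warmup) {
        j <- it - config$warmup
        mu_draws[j, ch, ] <- mu
        sigma_draws[j, ch, ] <- exp(log_sig)
        row <- (ch - 1) * n_save + j
        off <- 0
        for (s in seq_len(S)) {
          theta <- to_natural(spec, mu + exp(log_sig) * Z[s, ])
          theta_sum[s, ] <- theta_sum[s, ] + theta / (n_save * n_chains)
          pw <- session_loglik(spec, theta, sessions[[s]])$pointwise
          ll_matrix[row, off + seq_along(pw)] <- pw
          off <- off + length(pw)
        }
      }
    }
    accept["z"] <- accept["z"] + mean(n_acc_z / n_try) / n_chains
    accept["grp"] <- accept["grp"] + mean(n_acc_g / n_try) / n_chains
  }

  rhat <- c(mu = max(apply(mu_draws, 3, .split_rhat)),
            sigma = max(apply(sigma_draws, 3, .split_rhat)))
  warn <- character(0)
  if (any(rhat > 1.1, na.rm = TRUE))
    warn <- c(warn, sprintf("split R-hat above 1.1 (max %.3f): increase the MCMC budget", max(rhat, na.rm = TRUE)))

  colnames(theta_sum) <- spec$free$name
  rownames(theta_sum) <- vapply(sessions, function(s) s$trials$subject_id[1], "")
  total_ll <- sum(vapply(seq_len(S), function(s)
    session_loglik(spec, theta_sum[s, ], sessions[[s]])$total, 0))
  ba <- mean(vapply(seq_len(S), function(s)
    balanced_accuracy(spec, theta_sum[s, ], sessions[[s]])$value, 0))
  w <- compute_waic(ll_matrix)
  l <- compute_looic(ll_matrix)
  gm <- stats::setNames(colMeans(matrix(mu_draws, ncol = P)), spec$free$name)
  gs <- stats::setNames(colMeans(matrix(sigma_draws, ncol = P)), spec$free$name)
  structure(list(model_id = spec$model_id, backend = "hierarchical_mcmc",
                 estimates = theta_sum, group_mean = gm, group_scale = gs,
                 draws = list(mu = mu_draws, sigma = sigma_draws),
                 ll_matrix = ll_matrix, loglik = total_ll, n_valid = N,
                 waic = w$waic, looic = l$looic, pareto_k = l$pareto_k,
                 pseudo_r2 = pseudo_r2(total_ll, N),
                 balanced_accuracy = ba,
                 n_free_parameters = spec$n_free_parameters,
                 diagnostics = list(rhat = rhat, accept = accept,
                                    warnings = warn),
                 data_hash = .data_hash(sessions)),
            class = "hier_fit")
}

.split_rhat <- function(x) {
  # x: iterations x chains
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(xs)
  mean_j <- colMeans(xs); var_j <- apply(xs, 2, var)
  B <- half * var(mean_j); W <- mean(var_j)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# ---- information criteria -------------------------------------------------

.logmeanexp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Widely applicable information criterion from a pointwise matrix
#'
#' @param ll matrix of posterior draws (rows) by observations (columns) of
#'   pointwise log-likelihoods.
#' @return list with `waic`, `lppd`, `p_waic`.
#' @export
compute_waic <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2) stop("WAIC needs at least 2 posterior draws", call. = FALSE)
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihoods", call. = FALSE)
  lppd <- sum(apply(ll, 2, .logmeanexp))
  p_waic <- sum(apply(ll, 2, var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}

# Generalised Pareto fit to tail exceedances (empirical-Bayes profile
# estimate; Zhang & Stephens 2009 style).
.gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  prior <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (prior * xstar)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), 0)
  l_j <- n * (log(theta / k_j) + k_j - 1)
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(l_j - l_j[j])), 0)
  theta_hat <- sum(theta * w)
  k_hat <- mean(log1p(-theta_hat * x))   # Pareto shape (xi convention)
  sigma_hat <- -k_hat / theta_hat
  list(k = k_hat, sigma = sigma_hat)
}

.psis_smooth <- function(lw) {
  # lw: log importance ratios for one observation; returns smoothed,
  # self-normalised log-weights and the Pareto k diagnostic
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (M < 5) {
    return(list(lw = lw - .logmeanexp(lw) - log(S), k = NA_real_))
  }
  ord <- order(lw)
  tail_idx <- ord[(S - M + 1):S]
  cut <- exp(lw[ord[S - M]])
  exc <- exp(lw[tail_idx]) - cut
  k <- NA_real_
  if (length(unique(exc)) >= 2 && all(is.finite(exc))) {
    fit <- .gpd_fit(exc[exc > 0] + 1e-12)
    k <- fit$k
    p <- (seq_len(M) - 0.5) / M
    q <- if (abs(fit$k) < 1e-8) -fit$sigma * log(1 - p) else
      fit$sigma * ((1 - p)^(-fit$k) - 1) / fit$k
    sm <- log(cut + q)
    sm <- pmin(sm, 0)                 # truncate at the raw maximum
    lw[tail_idx[order(lw[tail_idx])]] <- sm
  }
  lw <- lw - .logmeanexp(lw) - log(S)
  list(lw = lw, k = k)
}

#' PSIS-LOO information criterion from a pointwise matrix
#'
#' Pareto-smoothed importance sampling over posterior draws; raw importance
#' ratios for leaving out observation i are `1 / p(y_i | draw)`, their upper
#' tail replaced by expected order statistics of a fitted generalised
#' Pareto distribution.
#'
#' @param ll matrix of draws x observations pointwise log-likelihoods.
#' @return list with `looic`, `elpd_loo`, `pointwise` and the `pareto_k`
#'   diagnostics.
#' @export
compute_looic <- function(ll) {
  ll <- as.matrix(ll)
  if (nrow(ll) < 2) stop("LOO needs at least 2 posterior draws", call. = FALSE)
  if (any(!is.finite(ll))) stop("non-finite pointwise log-likelihoods", call. = FALSE)
  N <- ncol(ll)
  elpd <- numeric(N); kk <- numeric(N)
  for (i in seq_len(N)) {
    sm <- .psis_smooth(-ll[, i])
    # elpd_i = log sum_s w_s p(y_i | theta_s), weights already normalised
    elpd[i] <- .logmeanexp(ll[, i] + sm$lw + log(nrow(ll)))
    kk[i] <- sm$k
  }
  list(looic = -2 * sum(elpd), elpd_loo = sum(elpd), pointwise = elpd,
       pareto_k = kk)
}

#' McFadden-style pseudo-R2 against the chance policy
#'
#' `1 - LL / (n * log(0.5))`: 0 for a model no better than coin flipping,
#' 1 for perfect one-step-ahead prediction.
#'
#' @param total_loglik summed log-likelihood over valid trials.
#' @param n_valid number of valid (non-missing) trials.
#' @export
pseudo_r2 <- function(total_loglik, n_valid) {
  stopifnot(n_valid >= 1)
  1 - total_loglik / (n_valid * log(0.5))
}

#' Balanced accuracy of one-step-ahead choice prediction
#'
#' The predicted choice on each valid trial is the option the model gives
#' probability above 0.5 (an exact tie earns half credit). Accuracy is
#' computed separately for trials on which the subject actually chose
#' option 0 and option 1, then averaged over the two classes.
#'
#' @param spec a `model_spec`.
#' @param theta named free-parameter vector.
#' @param session a `session_data`.
#' @return list with `value`, per-class accuracies and `degenerate` flag
#'   (TRUE when only one choice class is present).
#' @export
balanced_accuracy <- function(spec, theta, session) {
  res <- session_loglik(spec, theta, session)
  ok <- !session$trials$missing
  p1 <- res$p1[ok]
  choice <- session$trials$choice[ok]
  credit <- ifelse(p1 == 0.5, 0.5, as.numeric((p1 > 0.5) == (choice == 1)))
  classes <- sort(unique(choice))
  acc <- vapply(classes, function(cl) mean(credit[choice == cl]), 0)
  list(value = mean(acc),
       per_class = stats::setNames(acc, paste0("option", classes)),
       degenerate = length(classes) < 2)
}

#' Model-comparison table
#'
#' @param fits named list of `cohort_fit`/`hier_fit` objects fitted to the
#'   same sessions.
#' @return a `model_comparison` data frame: parameters, LOOIC, WAIC, their
#'   deltas relative to the winner (minimum LOOIC; ties broken by WAIC then
#'   fewer parameters), pseudo-R2 and balanced accuracy. The winner id is
#'   stored in `attr(, "winner")`.
#' @export
compare_models <- function(fits) {
  if (inherits(fits, "cohort_fit") || inherits(fits, "hier_fit"))
    fits <- list(fits)
  hashes <- vapply(fits, function(f) f$data_hash, "")
  if (length(unique(hashes)) > 1)
    stop("model fits were not computed on identical sessions", call. = FALSE)
  tab <- data.frame(
    model = vapply(fits, function(f) f$model_id, ""),
    n_parameters = vapply(fits, function(f) f$n_free_parameters, 0L),
    looic = vapply(fits, function(f) f$looic, 0),
    waic = vapply(fits, function(f) f$waic, 0),
    pseudo_r2 = vapply(fits, function(f) f$pseudo_r2, 0),
    balanced_accuracy = vapply(fits, function(f) f$balanced_accuracy, 0),
    stringsAsFactors = FALSE)
  tab$delta_looic <- tab$looic - min(tab$looic)
  tab$delta_waic <- tab$waic - min(tab$waic)
  ord <- order(tab$looic, tab$waic, tab$n_parameters)
  winner <- tab$model[ord[1]]
  tab <- tab[, c("model", "n_parameters", "delta_looic", "delta_waic",
                 "pseudo_r2", "balanced_accuracy", "looic", "waic")]
  attr(tab, "winner") <- winner
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' Serialize a fit result to JSON
#'
#' Writes per-subject point estimates, fit indices and diagnostics (no
#' draws) for archiving next to the session CSVs.
#'
#' @param fit a `cohort_fit` or `hier_fit`.
#' @param path output path; with `NULL` the JSON string is returned.
#' @export
fit_to_json <- function(fit, path = NULL) {
  payload <- list(
    model_id = fit$model_id, backend = fit$backend,
    n_free_parameters = fit$n_free_parameters,
    estimates = as.data.frame(cbind(subject = rownames(fit$estimates),
                                    as.data.frame(fit$estimates))),
    looic = fit$looic, waic = fit$waic, pseudo_r2 = fit$pseudo_r2,
    balanced_accuracy = fit$balanced_accuracy,
    max_pareto_k = max(fit$pareto_k, na.rm = TRUE),
    diagnostics = fit$diagnostics)
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                            pretty = TRUE))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (winner:", attr(x, "winner"), ")\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
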