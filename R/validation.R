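#' Highest-density interval of a sample
#'
#' Shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted samples.
#'
#' @param samples numeric vector (length >= 2).
#' @param mass probability mass (default 0.95).
#' @return numeric `c(lower, upper)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (length(samples) < 2) stop("hdi needs at least 2 samples", call. = FALSE)
  s <- sort(samples)
  n <- length(s)
  m <- ceiling(mass * n)
  widths <- s[m:n] - s[seq_len(n - m + 1)]
  i <- which.min(widths)
  c(lower = s[i], upper = s[i + m - 1])
}

.min_interval <- function(config, condition) {
  interval_for(config, condition)[1]
}

#' Choice accuracy aligned to contingency reversals
#'
#' For each reversal of the given condition, trials at post-reversal
#' positions 1..W (position 1 is the first trial under the new contingency)
#' are scored as correct when the choice is the new high-probability
#' option; scores are averaged over reversals within subject, then across
#' subjects.
#'
#' @param sessions list of `session_data` (each carries its schedule).
#' @param condition condition label.
#' @param window number of post-reversal positions W (must not exceed the
#'   condition's minimum inter-reversal interval).
#' @return data frame `position`, `mean`, `se`, `n_subjects`, plus the
#'   per-subject matrix in `attr(, "by_subject")`.
#' @export
reversal_curve <- function(sessions, condition, window = 9L) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  stopifnot(window >= 1)
  cfg <- sessions[[1]]$config
  if (window > .min_interval(cfg, condition))
    stop("window exceeds the minimum inter-reversal interval", call. = FALSE)
  by_subj <- t(vapply(sessions, function(sess) {
    tr <- sess$trials[sess$trials$condition == condition, ]
    tr <- tr[order(tr$condition_trial), ]
    revs <- sess$schedule$reversals[[condition]]
    acc <- matrix(NA_real_, length(revs), window)
    for (r in seq_along(revs)) {
      for (w in seq_len(window)) {
        ct <- revs[r] + w - 1L
        if (ct > nrow(tr)) next
        row <- tr[tr$condition_trial == ct, ]
        if (nrow(row) == 1 && !row$missing)
          acc[r, w] <- as.numeric(row$choice == row$high_option)
      }
    }
    colMeans(acc, na.rm = TRUE)
  }, numeric(window)))
  mu <- colMeans(by_subj, na.rm = TRUE)
  se <- apply(by_subj, 2, function(x) sd(x, na.rm = TRUE) / sqrt(sum(!is.na(x))))
  out <- data.frame(position = seq_len(window), mean = mu, se = se,
                    n_subjects = length(sessions))
  attr(out, "by_subject") <- by_subj
  out
}

#' 95% HDI band of simulated reversal curves
#'
#' @param replicate_cohorts list of session lists (one per simulation
#'   replicate).
#' @param condition condition label.
#' @param window post-reversal window.
#' @param mass HDI mass.
#' @return data frame `position`, `hdi_lo`, `hdi_hi`, `mean`.
#' @export
reversal_curve_band <- function(replicate_cohorts, condition, window = 9L,
                                mass = 0.95) {
  curves <- vapply(replicate_cohorts, function(cohort)
    reversal_curve(cohort, condition, window)$mean, numeric(window))
  band <- apply(curves, 1, hdi, mass = mass)
  data.frame(position = seq_len(window), hdi_lo = band["lower", ],
             hdi_hi = band["upper", ], mean = rowMeans(curves))
}

#' Win-stay / loss-switch rates of a session
#'
#' Transitions are counted between consecutive valid trials of the same
#' condition (staying or switching is only meaningful against the same
#' contingency in this interleaved design). Win-stay is the probability of
#' repeating a rewarded choice; loss-switch of abandoning an unrewarded
#' one; WSLS is their sum.
#'
#' @param session a `session_data`.
#' @return list `win_stay`, `loss_switch`, `wsls_sum`, transition counts,
#'   and `defined` flags per component.
#' @export
wsls_rate <- function(session) {
  stay_w <- integer(0); stay_l <- integer(0)
  for (cond in unique(session$trials$condition)) {
    tr <- session$trials[session$trials$condition == cond, ]
    tr <- tr[order(tr$condition_trial), ]
    tr <- tr[!tr$missing, ]
    if (nrow(tr) < 2) next
    prev <- tr[-nrow(tr), ]; nxt <- tr[-1, ]
    stay <- as.integer(nxt$choice == prev$choice)
    stay_w <- c(stay_w, stay[prev$outcome == 1])
    stay_l <- c(stay_l, stay[prev$outcome == 0])
  }
  ws <- if (length(stay_w)) mean(stay_w) else NA_real_
  ls <- if (length(stay_l)) mean(1 - stay_l) else NA_real_
  list(win_stay = ws, loss_switch = ls, wsls_sum = ws + ls,
       n_win = length(stay_w), n_loss = length(stay_l),
       defined = c(win_stay = length(stay_w) > 0,
                   loss_switch = length(stay_l) > 0))
}

#' Accuracy on the third trial after each reversal
#'
#' @param sessions list of `session_data`.
#' @param condition condition label.
#' @return mean proportion of third-post-reversal trials on which the
#'   post-reversal high option was chosen (over reversals, then subjects);
#'   `NA` with a warning if no reversal qualifies.
#' @export
third_trial_accuracy <- function(sessions, condition) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  per_subj <- vapply(sessions, function(sess) {
    tr <- sess$trials[sess$trials$condition == condition, ]
    revs <- sess$schedule$reversals[[condition]]
    acc <- c()
    for (p in revs) {
      row <- tr[tr$condition_trial == p + 2L, ]
      if (nrow(row) == 1 && !row$missing)
        acc <- c(acc, as.numeric(row$choice == row$high_option))
    }
    if (length(acc)) mean(acc) else NA_real_
  }, 0)
  if (all(is.na(per_subj))) {
    warning("no reversal with a valid third post-reversal trial")
    return(NA_real_)
  }
  mean(per_subj, na.rm = TRUE)
}

.session_accuracy <- function(session) {
  tr <- session$trials[!session$trials$missing, ]
  vapply(CONDITIONS, function(cd) {
    sub <- tr[tr$condition == cd, ]
    if (nrow(sub) == 0) return(NA_real_)
    mean(sub$choice == sub$high_option)
  }, 0)
}

#' Posterior-predictive accuracy check
#'
#' Each subject is re-simulated on their own schedule from their fitted
#' parameters (`n_rep` seeded replicates); the replicate-mean simulated
#' accuracy is correlated with the real accuracy across subjects, per
#' condition.
#'
#' @param fit a `cohort_fit` or `hier_fit` (subject point estimates are
#'   used).
#' @param sessions the sessions the fit was computed on.
#' @param n_rep simulation replicates per subject (default 100).
#' @param seed integer seed.
#' @return list with `correlations` (per-condition data frame of r and p),
#'   `real` and `simulated` accuracy matrices (subjects x conditions).
#' @export
posterior_predictive <- function(fit, sessions, n_rep = 100L, seed = 1L) {
  if (length(sessions) < 3) stop("need at least 3 subjects", call. = FALSE)
  spec <- model_spec(fit$model_id)
  real <- t(vapply(sessions, .session_accuracy, numeric(4)))
  sim <- matrix(NA_real_, length(sessions), 4,
                dimnames = list(NULL, CONDITIONS))
  for (i in seq_along(sessions)) {
    theta <- fit$estimates[i, ]
    acc <- matrix(NA_real_, n_rep, 4)
    for (r in seq_len(n_rep)) {
      s <- simulate_agent(spec, theta, sessions[[i]]$schedule,
                          seed = seed + 977L * i + r)
      acc[r, ] <- .session_accuracy(s)
    }
    sim[i, ] <- colMeans(acc)
  }
  cors <- do.call(rbind, lapply(CONDITIONS, function(cd) {
    x <- real[, cd]; y <- sim[, cd]
    if (sd(x) == 0 || sd(y) == 0)
      return(data.frame(condition = cd, r = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    ct <- cor.test(x, y)
    data.frame(condition = cd, r = unname(ct$estimate), p = ct$p.value,
               degenerate = FALSE)
  }))
  list(correlations = cors, real = real, simulated = sim)
}

#' Parameter recovery for one model
#'
#' Simulates one session per synthetic subject from known parameters (each
#' subject gets a fresh seeded schedule), refits with the MAP backend, and
#' correlates generating against recovered values per free parameter.
#'
#' @param spec a `model_spec`.
#' @param true_params matrix (subjects x free parameters, natural scale,
#'   columns named as in `spec$free$name`).
#' @param task a [task_config()].
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @return object of class `recovery_report`: `param_cor`, `truth`,
#'   `recovered`, `n_failed`.
#' @export
parameter_recovery <- function(spec, true_params, task = task_config(),
                               config = fit_config(), seed = 1L) {
  n <- nrow(true_params)
  if (n < 10) stop("parameter recovery needs at least 10 subjects", call. = FALSE)
  rec <- matrix(NA_real_, n, spec$n_free_parameters,
                dimnames = list(NULL, spec$free$name))
  failed <- 0L
  sessions <- lapply(seq_len(n), function(i) {
    cfg_t <- task; cfg_t$seed <- seed + 7919L * i
    simulate_agent(spec, true_params[i, ], generate_schedule(cfg_t),
                   seed = seed + 104729L + i, subject_id = paste0("sim", i))
  })
  cfg_f <- config; cfg_f$seed <- seed
  cohort <- tryCatch(fit_cohort_map(spec, sessions, cfg_f),
                     error = function(e) NULL)
  if (!is.null(cohort)) {
    rec[, ] <- cohort$estimates
  } else {
    # cohort-level pass failed: fall back to independent per-subject fits
    for (i in seq_len(n)) {
      f <- tryCatch({
        cfg_i <- config; cfg_i$seed <- seed + i
        fit_map(spec, sessions[[i]], cfg_i)
      }, error = function(e) NULL)
      if (is.null(f)) failed <- failed + 1L else rec[i, ] <- f$theta
    }
  }
  ok <- stats::complete.cases(rec)
  cors <- vapply(spec$free$name, function(p)
    cor(true_params[ok, p], rec[ok, p]), 0)
  structure(list(param_cor = cors, truth = true_params, recovered = rec,
                 n_failed = failed, model_id = spec$model_id),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$model_id, "-", nrow(x$truth), "subjects,",
      x$n_failed, "failed fits\n")
  print(round(x$param_cor, 3))
  invisible(x)
}

#' Model recovery: confusion of generating vs winning model
#'
#' Simulates replicate cohorts from a generating model and lets the
#' candidate models compete on each; the winner per replicate is recorded.
#'
#' @param generating_id id of the generating model.
#' @param n_replicates number of replicate cohorts.
#' @param candidate_ids ids of the competing models.
#' @param cohort a [cohort_spec()] used (with replicate-specific seeds) to
#'   generate each cohort.
#' @param config a [fit_config()].
#' @param seed integer seed.
#' @return list with `winners` (character per replicate) and `confusion`
#'   (named counts over candidates).
#' @export
model_recovery <- function(generating_id, n_replicates = 10L,
                           candidate_ids = c("M1", "M2", "M3", "M5"),
                           cohort = cohort_spec(model_id = generating_id),
                           config = fit_config(), seed = 1L) {
  stopifnot(n_replicates >= 1)
  winners <- character(n_replicates)
  for (r in seq_len(n_replicates)) {
    cs <- cohort
    cs$model_id <- generating_id
    cs$seed <- seed + 6151L * r
    gen <- generate_cohort(cs)
    fits <- lapply(candidate_ids, function(id) {
      cfg <- config; cfg$seed <- seed + r
      fit_cohort_map(model_spec(id), gen$sessions, cfg)
    })
    names(fits) <- candidate_ids
    winners[r] <- attr(compare_models(fits), "winner")
  }
  confusion <- table(factor(winners, levels = candidate_ids))
  list(winners = winners, confusion = confusion,
       generating = generating_id)
}
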