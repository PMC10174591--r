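#' Default group-level means (natural scale) for a model's free parameters
#'
#' The M1 preset mirrors the qualitative behavioral pattern the pipeline is
#' designed to detect: under neutral cues the learning rate is higher in
#' the volatile (frequent-reversal) environment (0.35 vs 0.15), while under
#' fearful cues this adjustment is absent (0.25 in both); inverse
#' temperatures sit at 3. Other parameter kinds get mid-range values.
#'
#' @param spec a `model_spec`.
#' @return named vector over `spec$free$name`.
#' @export
default_group_means <- function(spec) {
  base <- c(alpha = 0.25, beta = 3, eps = 0.1, phi = 0.1, omega = 0.4,
            kappa = 0.4, a0 = 0.5, k = 1, b = 0)
  mu <- stats::setNames(base[spec$free$param], spec$free$name)
  pattern <- c(alpha.neut_freq = 0.35, alpha.neut_infreq = 0.15,
               alpha.fear_freq = 0.25, alpha.fear_infreq = 0.25)
  hit <- intersect(names(mu), names(pattern))
  mu[hit] <- pattern[hit]
  mu
}

#' Specification of a synthetic participant cohort
#'
#' @param n_subjects number of synthetic subjects (default 40).
#' @param model_id generating model (default `"M1"`).
#' @param group_means named natural-scale group means over the generating
#'   model's free parameters (default [default_group_means()]).
#' @param group_sd between-subject sd on the unconstrained scale (default
#'   0.5).
#' @param covariate_slope slope linking a standardized per-subject trait to
#'   the subject's cue-by-volatility contrast on the unconstrained learning
#'   rate scale (0 disables the covariate).
#' @param covariate_noise_sd extra contrast noise beyond `group_sd`.
#' @param missing_rate per-trial non-response probability (capped at 0.1,
#'   mirroring the usual exclusion threshold for inattentive subjects).
#' @param task a [task_config()].
#' @param seed integer seed.
#' @return a `cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects = 40L, model_id = "M1",
                        group_means = NULL, group_sd = 0.5,
                        covariate_slope = 0, covariate_noise_sd = 0,
                        missing_rate = 0, task = task_config(), seed = 1L) {
  stopifnot(n_subjects >= 1, group_sd >= 0)
  if (missing_rate < 0 || missing_rate > 0.1)
    stop("missing_rate must lie in [0, 0.1]", call. = FALSE)
  spec <- model_spec(model_id)
  if (is.null(group_means)) group_means <- default_group_means(spec)
  structure(list(n_subjects = as.integer(n_subjects), model_id = model_id,
                 group_means = group_means, group_sd = group_sd,
                 covariate_slope = covariate_slope,
                 covariate_noise_sd = covariate_noise_sd,
                 missing_rate = missing_rate, task = task,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# contrast pattern over the four alpha conditions such that adding
# delta * pattern on the unconstrained scale shifts the (unconstrained)
# bias contrast by exactly delta
.contrast_pattern <- function(free_names) {
  p <- stats::setNames(rep(0, length(free_names)), free_names)
  pat <- c(alpha.fear_freq = 0.25, alpha.fear_infreq = -0.25,
           alpha.neut_freq = -0.25, alpha.neut_infreq = 0.25)
  hit <- intersect(free_names, names(pat))
  p[hit] <- pat[hit]
  p
}

#' Draw per-subject generating parameters from the group distribution
#'
#' Subjects are drawn on the unconstrained scale (group mean plus
#' `group_sd` times a standard-normal deviate, per parameter) and mapped
#' through the same scaled inverse-probit transform the fitters use. When a
#' covariate is configured, a standardized trait is drawn per subject and
#' its slope times the trait is added along the interaction-contrast
#' direction of the learning rates.
#'
#' @param cohort a [cohort_spec()].
#' @return list `params` (subjects x free parameters, natural scale),
#'   `covariate` (vector or NULL), `unconstrained`.
#' @export
sample_group_parameters <- function(cohort) {
  spec <- model_spec(cohort$model_id)
  mu_unc <- to_unconstrained(spec, cohort$group_means)
  set.seed(cohort$seed)
  n <- cohort$n_subjects
  P <- spec$n_free_parameters
  X <- matrix(rnorm(n * P, 0, 1), n, P)
  X <- sweep(X * cohort$group_sd, 2, mu_unc, "+")
  covariate <- NULL
  if (cohort$covariate_slope != 0 || cohort$covariate_noise_sd != 0) {
    covariate <- rnorm(n)
    pat <- .contrast_pattern(spec$free$name)
    shift <- cohort$covariate_slope * covariate +
      rnorm(n, 0, cohort$covariate_noise_sd)
    X <- X + outer(shift, pat)
  }
  params <- t(apply(X, 1, function(x) to_natural(spec, x)))
  colnames(params) <- spec$free$name
  list(params = params, covariate = covariate, unconstrained = X)
}

#' Generate a full synthetic cohort
#'
#' Each subject receives a fresh seeded schedule and interleaving, and a
#' session simulated from their own generating parameters.
#'
#' @param cohort a [cohort_spec()].
#' @return list `sessions` (list of `session_data`), `true_params`
#'   (natural-scale matrix), `covariate`, `spec` (the cohort spec).
#' @export
generate_cohort <- function(cohort) {
  gp <- sample_group_parameters(cohort)
  spec <- model_spec(cohort$model_id)
  sessions <- vector("list", cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    task_i <- cohort$task
    task_i$seed <- cohort$seed + 7919L * i
    sch <- generate_schedule(task_i)
    sessions[[i]] <- simulate_agent(spec, gp$params[i, ], sch,
                                    seed = cohort$seed + 104729L + i,
                                    subject_id = sprintf("sub%03d", i),
                                    missing_rate = cohort$missing_rate)
  }
  rownames(gp$params) <- sprintf("sub%03d", seq_len(cohort$n_subjects))
  list(sessions = sessions, true_params = gp$params,
       covariate = gp$covariate, spec = cohort)
}
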