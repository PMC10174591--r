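#' @title Model family: twelve condition-keyed learning models
#' @description
#' The candidate space crosses a delta-rule value learner with different
#' assumptions about how the four task conditions share parameters:
#'
#' * M1 - learning rate and inverse temperature per condition (8 free).
#' * M2 - parameters shared across cues, split only by volatility (4).
#' * M3 - per-condition learning rates, one shared inverse temperature (5).
#' * M4 - two-armed variant: only the chosen option's value is updated (8).
#' * M5 - M1 plus a shared lapse rate mixed into the softmax (9).
#' * M6 - M1 plus a shared forgetting decay toward 0.5 (9).
#' * M7 - forgetting split by volatility (10).
#' * M8 - forgetting split by cue (10).
#' * M9 - Pearce-Hall hybrid: associability-scaled updates, shared weight
#'   and scale plus initial associability (7).
#' * M10 - hybrid with the associability weight split by cue (8).
#' * M11 - hybrid with the update scale split by cue (8).
#' * M12 - per-condition learning rates expressed as linear functions of the
#'   neutral-infrequent learning rate (11).
#' @name model_family
NULL

PARAM_BOUNDS <- list(alpha = c(0, 1), beta = c(0, 10), eps = c(0, 1),
                     phi = c(0, 1), omega = c(0, 1), kappa = c(0, 1),
                     a0 = c(0, 1), k = c(-2, 2), b = c(-1, 1))

.share <- function(kind) {
  switch(kind,
    condition  = stats::setNames(CONDITIONS, CONDITIONS),
    volatility = stats::setNames(cond_vol(CONDITIONS), CONDITIONS),
    cue        = stats::setNames(cond_cue(CONDITIONS), CONDITIONS),
    shared     = stats::setNames(rep("shared", 4), CONDITIONS))
}

.free_table <- function(sharing) {
  rows <- lapply(names(sharing), function(p) {
    groups <- unique(sharing[[p]])
    data.frame(name = paste(p, groups, sep = "."), param = p, group = groups,
               lower = PARAM_BOUNDS[[p]][1], upper = PARAM_BOUNDS[[p]][2],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.make_spec <- function(id, update_rule, choice_rule, sharing,
                       m12_links = FALSE) {
  free <- .free_table(sharing)
  if (m12_links) {
    # the three non-reference learning rates come from linear links, each
    # contributing a slope and an intercept instead of a free rate
    free <- free[!(free$param == "alpha" & free$group != "neut_infreq"), ]
    linked <- setdiff(CONDITIONS, "neut_infreq")
    link_rows <- do.call(rbind, lapply(linked, function(cd) {
      data.frame(name = c(paste0("k.", cd), paste0("b.", cd)),
                 param = c("k", "b"), group = cd,
                 lower = c(PARAM_BOUNDS$k[1], PARAM_BOUNDS$b[1]),
                 upper = c(PARAM_BOUNDS$k[2], PARAM_BOUNDS$b[2]),
                 stringsAsFactors = FALSE)
    }))
    free <- rbind(free, link_rows)
  }
  rownames(free) <- NULL
  structure(list(model_id = id, update_rule = update_rule,
                 choice_rule = choice_rule, sharing = sharing,
                 m12_links = m12_links, free = free,
                 n_free_parameters = nrow(free)),
            class = "model_spec")
}

.build_registry <- function() {
  pc <- .share("condition"); pv <- .share("volatility")
  cue <- .share("cue"); sh <- .share("shared")
  list(
    M1  = .make_spec("M1", "rw_onearm", "softmax", list(alpha = pc, beta = pc)),
    M2  = .make_spec("M2", "rw_onearm", "softmax", list(alpha = pv, beta = pv)),
    M3  = .make_spec("M3", "rw_onearm", "softmax", list(alpha = pc, beta = sh)),
    M4  = .make_spec("M4", "rw_twoarm", "softmax", list(alpha = pc, beta = pc)),
    M5  = .make_spec("M5", "rw_onearm", "softmax_lapse",
                     list(alpha = pc, beta = pc, eps = sh)),
    M6  = .make_spec("M6", "rw_forget", "softmax",
                     list(alpha = pc, beta = pc, phi = sh)),
    M7  = .make_spec("M7", "rw_forget", "softmax",
                     list(alpha = pc, beta = pc, phi = pv)),
    M8  = .make_spec("M8", "rw_forget", "softmax",
                     list(alpha = pc, beta = pc, phi = cue)),
    M9  = .make_spec("M9", "pearce_hall_hybrid", "softmax",
                     list(beta = pc, omega = sh, kappa = sh, a0 = sh)),
    M10 = .make_spec("M10", "pearce_hall_hybrid", "softmax",
                     list(beta = pc, omega = cue, kappa = sh, a0 = sh)),
    M11 = .make_spec("M11", "pearce_hall_hybrid", "softmax",
                     list(beta = pc, omega = sh, kappa = cue, a0 = sh)),
    M12 = .make_spec("M12", "rw_onearm", "softmax",
                     list(alpha = pc, beta = pc), m12_links = TRUE)
  )
}

.registry_cache <- new.env(parent = emptyenv())

#' Model registry
#'
#' @param id optional model id `"M1"`..`"M12"`; with no id the full named
#'   list of specs is returned.
#' @return a `model_spec` or a named list of them.
#' @export
model_spec <- function(id = NULL) {
  if (is.null(.registry_cache$reg)) .registry_cache$reg <- .build_registry()
  reg <- .registry_cache$reg
  if (is.null(id)) return(reg)
  if (!id %in% names(reg)) stop("unknown model id: ", id, call. = FALSE)
  reg[[id]]
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$model_id, "-", x$update_rule, "/", x$choice_rule,
      "-", x$n_free_parameters, "free parameters\n")
  invisible(x)
}

#' Export a model specification as JSON
#'
#' @param spec a `model_spec`.
#' @return a JSON string (update rule, choice rule, sharing map, free
#'   parameters with bounds).
#' @export
spec_to_json <- function(spec) {
  jsonlite::toJSON(list(model_id = spec$model_id,
                        update_rule = spec$update_rule,
                        choice_rule = spec$choice_rule,
                        sharing = spec$sharing,
                        n_free_parameters = spec$n_free_parameters,
                        free_parameters = spec$free),
                   auto_unbox = TRUE, pretty = TRUE)
}

# ---- elementary update and choice rules ----------------------------------

#' Delta-rule value update
#'
#' Moves the chosen option's value toward the outcome by a fraction `alpha`
#' of the prediction error; under the one-armed reading the unchosen value
#' is the complement of the chosen one.
#'
#' @param V current value of the chosen option, in `[0, 1]`.
#' @param alpha learning rate in `(0, 1)`.
#' @param O binary outcome.
#' @param two_arm if `TRUE` only the chosen value is returned (no
#'   complement).
#' @return named vector with `chosen` (and `unchosen` unless `two_arm`).
#' @export
rw_update <- function(V, alpha, O, two_arm = FALSE) {
  stopifnot(V >= 0, V <= 1, alpha >= 0, alpha <= 1, O %in% c(0, 1))
  chosen <- V + alpha * (O - V)
  if (two_arm) c(chosen = chosen) else c(chosen = chosen, unchosen = 1 - chosen)
}

#' Softmax choice probability
#'
#' @param V_A,V_B option values.
#' @param beta inverse temperature in `(0, 10)`; 0 is indifference.
#' @return probability of choosing A.
#' @export
softmax_choice <- function(V_A, V_B, beta) {
  1 / (1 + exp(-beta * (V_A - V_B)))
}

#' Mix a lapse process into a choice probability
#'
#' With probability `eps` the agent chooses at random regardless of values.
#'
#' @param p_softmax softmax probability.
#' @param eps lapse rate in `(0, 1)`.
#' @export
lapse_choice <- function(p_softmax, eps) {
  (1 - eps) * p_softmax + eps / 2
}

#' Forgetting decay toward the indifference level
#'
#' @param V value.
#' @param phi decay rate in `(0, 1)`; 1 resets to 0.5.
#' @export
forgetting_update <- function(V, phi) {
  V + phi * (0.5 - V)
}

#' Pearce-Hall hybrid update
#'
#' The effective learning rate is `kappa * A`, where the associability `A`
#' tracks a running average of absolute prediction errors with weight
#' `omega`.
#'
#' @param V value of the chosen option.
#' @param A current associability.
#' @param delta prediction error (outcome minus value).
#' @param omega associability update weight in `(0, 1)`.
#' @param kappa update scale in `(0, 1)`.
#' @return named vector `c(value, associability)`.
#' @export
hybrid_update <- function(V, A, delta, omega, kappa) {
  c(value = V + kappa * A * delta,
    associability = (1 - omega) * A + omega * abs(delta))
}

#' Linear link from the reference learning rate (M12)
#'
#' @param alpha_base learning rate of the neutral-infrequent condition.
#' @param k slope.
#' @param b intercept.
#' @param clip half-width kept away from the `(0, 1)` boundaries.
#' @export
m12_link <- function(alpha_base, k, b, clip = 1e-6) {
  pmin(pmax(k * alpha_base + b, clip), 1 - clip)
}

# ---- parameter resolution -------------------------------------------------

#' Expand a free-parameter vector into per-condition parameter vectors
#'
#' @param spec a `model_spec`.
#' @param theta named numeric vector over `spec$free$name`.
#' @return list of length-4 vectors (canonical condition order) for alpha,
#'   beta, eps, phi, omega, kappa, a0.
#' @export
resolve_params <- function(spec, theta) {
  miss <- setdiff(spec$free$name, names(theta))
  if (length(miss))
    stop("parameters missing for ", spec$model_id, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  fr <- spec$free
  # closed-bound check: the fitting transform keeps estimates strictly
  # inside, but boundary values (e.g. the beta = 0 chance policy) are legal
  # inputs for evaluation
  bad <- theta[fr$name] < fr$lower | theta[fr$name] > fr$upper
  if (any(bad))
    stop("parameter out of open bounds: ",
         paste(fr$name[bad], collapse = ", "), call. = FALSE)
  defaults <- list(alpha = rep(0.5, 4), beta = rep(1, 4), eps = rep(0, 4),
                   phi = rep(0, 4), omega = rep(0, 4), kappa = rep(0, 4),
                   a0 = rep(0, 4))
  out <- lapply(defaults, stats::setNames, CONDITIONS)
  for (p in names(spec$sharing)) {
    if (spec$m12_links && p == "alpha") next
    groups <- spec$sharing[[p]]
    out[[p]][CONDITIONS] <- theta[paste(p, groups[CONDITIONS], sep = ".")]
  }
  if (spec$m12_links) {
    base <- theta[["alpha.neut_infreq"]]
    out$alpha["neut_infreq"] <- base
    for (cd in setdiff(CONDITIONS, "neut_infreq")) {
      out$alpha[cd] <- m12_link(base, theta[[paste0("k.", cd)]],
                                theta[[paste0("b.", cd)]])
    }
  }
  out
}

.update_code <- function(update_rule) {
  switch(update_rule, rw_onearm = 0L, rw_forget = 0L, rw_twoarm = 1L,
         pearce_hall_hybrid = 2L,
         stop("unknown update rule: ", update_rule, call. = FALSE))
}

.forward <- function(spec, theta, trials, simulate = FALSE,
                     config = NULL) {
  pr <- resolve_params(spec, theta)
  cond_idx <- match(trials$condition, CONDITIONS) - 1L
  if (simulate) {
    rl_forward_cpp(cond_idx, integer(nrow(trials)), integer(nrow(trials)),
                   trials$missing, .update_code(spec$update_rule),
                   pr$alpha, pr$beta, pr$eps, pr$phi, pr$omega, pr$kappa,
                   pr$a0, TRUE, trials$high_option,
                   config$reward_prob_high, config$reward_prob_low)
  } else {
    choice <- ifelse(trials$missing, -1L, trials$choice)
    rl_forward_cpp(cond_idx, as.integer(choice), as.integer(trials$outcome),
                   trials$missing, .update_code(spec$update_rule),
                   pr$alpha, pr$beta, pr$eps, pr$phi, pr$omega, pr$kappa,
                   pr$a0, FALSE, integer(nrow(trials)), 0, 0)
  }
}

#' One-step-ahead log-likelihood of a session under a model
#'
#' Four independent latent value states are kept, one per condition, all
#' initialised at 0.5. Missing trials contribute no likelihood term and no
#' learning update, but forgetting (where the model has it) still decays all
#' states on every trial. Choice probabilities are floored at 1e-12 before
#' the log.
#'
#' @param spec a `model_spec`.
#' @param theta named free-parameter vector (see `spec$free$name`).
#' @param session a `session_data` object.
#' @return list with `total` (sum over non-missing trials), `pointwise`
#'   (per non-missing trial, in session order) and `p1` (model probability
#'   of choosing option 1 on every trial, including missing ones).
#' @export
session_loglik <- function(spec, theta, session) {
  res <- .forward(spec, theta, session$trials)
  ll <- res$ll[!is.na(res$ll)]
  list(total = res$total, pointwise = ll, p1 = res$p1)
}

#' Simulate an agent of a given model on a schedule
#'
#' Choices are sampled from the model's one-step-ahead probabilities and
#' outcomes delivered from the schedule. Deterministic given `seed`.
#'
#' @param spec a `model_spec`.
#' @param theta named free-parameter vector.
#' @param schedule a `reversal_schedule` (its config is reused).
#' @param seed integer seed.
#' @param subject_id identifier stored in the trial frame.
#' @param missing_rate probability that a trial is a non-response (default
#'   0; non-responses earn no reward and trigger no update).
#' @return a `session_data` object.
#' @export
simulate_agent <- function(spec, theta, schedule, seed = 1L,
                           subject_id = "sim", missing_rate = 0) {
  config <- schedule$config
  fr <- session_frame(config, schedule, subject_id = subject_id,
                      interleave_seed = config$seed + 1L)
  set.seed(seed)
  fr$missing <- runif(nrow(fr)) < missing_rate
  res <- .forward(spec, theta, fr, simulate = TRUE, config = config)
  fr$choice <- res$choice
  fr$outcome <- res$outcome
  new_session(fr, config, schedule)
}
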