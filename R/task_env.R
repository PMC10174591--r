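#' @useDynLib fearvol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom optim optimHess qnorm pnorm dnorm var
#'   sd cor cor.test pbeta pnorm median quantile p.adjust setNames
#' @importFrom utils head read.csv write.csv
NULL

#' Canonical condition labels of the 2 x 2 cue-by-volatility design
#'
#' Cue (fearful vs neutral face) crossed with environmental volatility
#' (frequent reversals every 9-11 condition-local trials vs infrequent
#' reversals every 18-22). The order is fixed and used everywhere a
#' per-condition parameter vector is indexed.
#'
#' @export
CONDITIONS <- c("fear_freq", "fear_infreq", "neut_freq", "neut_infreq")

cond_cue <- function(cond) sub("_(freq|infreq)$", "", cond)
cond_vol <- function(cond) sub("^(fear|neut)_", "", cond)

#' Task configuration for the cue-biased reversal-learning task
#'
#' @param trials_per_condition trials per condition (total is 4x this).
#' @param reward_prob_high,reward_prob_low reward probability of the
#'   currently good / bad option.
#' @param freq_interval integer range (low, high) of inter-reversal gaps, in
#'   condition-local trials, for the frequent-reversal conditions.
#' @param infreq_interval same for the infrequent-reversal conditions.
#' @param seed integer seed controlling schedule and interleaving draws.
#' @return an object of class `task_config`.
#' @export
task_config <- function(trials_per_condition = 60L,
                        reward_prob_high = 0.85,
                        reward_prob_low = 0.15,
                        freq_interval = c(9L, 11L),
                        infreq_interval = c(18L, 22L),
                        seed = 1L) {
  stopifnot(length(freq_interval) == 2L, length(infreq_interval) == 2L)
  if (freq_interval[1] > freq_interval[2] ||
      infreq_interval[1] > infreq_interval[2])
    stop("interval ranges must have low <= high", call. = FALSE)
  if (trials_per_condition < max(freq_interval, infreq_interval))
    stop("trials_per_condition must be at least the largest reversal interval",
         call. = FALSE)
  stopifnot(reward_prob_high >= 0, reward_prob_high <= 1,
            reward_prob_low >= 0, reward_prob_low <= 1)
  structure(list(trials_per_condition = as.integer(trials_per_condition),
                 conditions = CONDITIONS,
                 reward_prob_high = reward_prob_high,
                 reward_prob_low = reward_prob_low,
                 freq_interval = as.integer(freq_interval),
                 infreq_interval = as.integer(infreq_interval),
                 seed = as.integer(seed)),
            class = "task_config")
}

interval_for <- function(config, cond) {
  if (cond_vol(cond) == "freq") config$freq_interval else config$infreq_interval
}

#' Generate a reversal schedule for all four conditions
#'
#' Each condition gets its own condition-local reversal sequence: gaps are
#' drawn uniformly from the condition's interval range (the first reversal
#' offset comes from the same distribution), cumulated until the end of the
#' condition's 60 trials; a final partial interval is truncated without a
#' reversal. The initially good option is a fair coin per condition and flips
#' at every reversal.
#'
#' @param config a [task_config()].
#' @return object of class `reversal_schedule`: per condition the 1-based
#'   condition-local trial indices at which the contingency flips
#'   (`reversals`) and the good option (0/1) for every condition-local trial
#'   (`high_option`).
#' @export
generate_schedule <- function(config) {
  set.seed(config$seed)
  n <- config$trials_per_condition
  out <- list(reversals = list(), high_option = list())
  for (cond in config$conditions) {
    iv <- interval_for(config, cond)
    pos <- integer(0)
    at <- 0L
    repeat {
      gap <- sample(seq.int(iv[1], iv[2]), 1L)
      at <- at + gap
      if (at > n) break
      pos <- c(pos, at)
    }
    start <- sample(0:1, 1L)
    high <- integer(n)
    cur <- start
    for (t in seq_len(n)) {
      if (t %in% pos) cur <- 1L - cur
      high[t] <- cur
    }
    out$reversals[[cond]] <- pos
    out$high_option[[cond]] <- high
  }
  structure(c(out, list(config = config)), class = "reversal_schedule")
}

#' Interleave the four conditions across the session
#'
#' A seeded random permutation of `trials_per_condition` copies of each
#' condition label, mirroring the intermixed presentation of the task.
#'
#' @param config a [task_config()].
#' @param seed optional seed override (defaults to `config$seed + 1`).
#' @return character vector of length `4 * trials_per_condition`.
#' @export
interleave_conditions <- function(config, seed = config$seed + 1L) {
  set.seed(seed)
  sample(rep(config$conditions, each = config$trials_per_condition))
}

#' Deliver a probabilistic outcome for one trial
#'
#' Reward arrives with probability `reward_prob_high` when the chosen option
#' is the currently good one and `reward_prob_low` otherwise. A missing
#' response earns nothing.
#'
#' @param schedule a [generate_schedule()] result.
#' @param condition condition label.
#' @param condition_trial 1-based condition-local trial index.
#' @param choice 0, 1, or `NA` (missing).
#' @return 0 or 1.
#' @export
deliver_outcome <- function(schedule, condition, condition_trial, choice) {
  if (is.na(choice)) return(0L)
  stopifnot(choice %in% c(0L, 1L))
  cfg <- schedule$config
  high <- schedule$high_option[[condition]][condition_trial]
  p <- if (choice == high) cfg$reward_prob_high else cfg$reward_prob_low
  as.integer(runif(1) < p)
}

#' Assemble the per-trial frame for a session (conditions, schedule lookup)
#'
#' Internal scaffold shared by the simulators: global order, condition-local
#' indices, and the good option on every trial.
#' @noRd
session_frame <- function(config, schedule, subject_id = "s1",
                          interleave_seed = config$seed + 1L) {
  cond <- interleave_conditions(config, seed = interleave_seed)
  n <- length(cond)
  ctrial <- integer(n)
  cnt <- stats::setNames(integer(4), config$conditions)
  for (t in seq_len(n)) {
    cnt[cond[t]] <- cnt[cond[t]] + 1L
    ctrial[t] <- cnt[cond[t]]
  }
  high <- mapply(function(cd, ct) schedule$high_option[[cd]][ct], cond, ctrial)
  data.frame(subject_id = subject_id,
             global_trial = seq_len(n),
             condition = cond,
             condition_cue = cond_cue(cond),
             condition_volatility = cond_vol(cond),
             condition_trial = ctrial,
             high_option = as.integer(high),
             stringsAsFactors = FALSE)
}

#' Build a session from explicit choices
#'
#' Wraps per-trial records into a `session_data` object (trial data frame
#' plus its config and schedule). Used by the simulators and the reader.
#' @noRd
new_session <- function(trials, config, schedule) {
  structure(list(trials = trials, config = config, schedule = schedule),
            class = "session_data")
}

#' @export
print.session_data <- function(x, ...) {
  cat("<session_data>", x$trials$subject_id[1], "-",
      nrow(x$trials), "trials,",
      sum(x$trials$missing), "missing\n")
  invisible(x)
}

#' Simulate a session from an oracle policy
#'
#' The oracle always chooses the currently good option; used for reward-rate
#' calibration of the schedule machinery.
#'
#' @param config a [task_config()].
#' @param seed seed for outcome draws (schedule uses `config$seed`).
#' @return a `session_data` object.
#' @export
simulate_oracle_session <- function(config = task_config(), seed = 1L) {
  schedule <- generate_schedule(config)
  fr <- session_frame(config, schedule)
  set.seed(seed)
  fr$choice <- fr$high_option
  p <- ifelse(fr$choice == fr$high_option,
              config$reward_prob_high, config$reward_prob_low)
  fr$outcome <- as.integer(runif(nrow(fr)) < p)
  fr$missing <- FALSE
  new_session(fr, config, schedule)
}

#' All inter-reversal gaps of a schedule, per volatility level
#'
#' Includes the offset of the first reversal (drawn from the same interval
#' distribution); the truncated tail interval is not a gap.
#'
#' @param schedule a `reversal_schedule`.
#' @return named list with numeric vectors `freq` and `infreq`.
#' @export
schedule_gaps <- function(schedule) {
  gaps <- list(freq = numeric(0), infreq = numeric(0))
  for (cond in names(schedule$reversals)) {
    v <- cond_vol(cond)
    gaps[[v]] <- c(gaps[[v]], diff(c(0L, schedule$reversals[[cond]])))
  }
  gaps
}
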