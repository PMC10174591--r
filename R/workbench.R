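SESSION_COLUMNS <- c("subject_id", "global_trial", "condition_cue",
                     "condition_volatility", "condition_trial", "choice",
                     "outcome", "missing", "high_option")

#' Write sessions to a delimited text file
#'
#' One row per trial; option ids are 0-based, condition-local trial indices
#' 1-based. Missing choices are written as empty fields.
#'
#' @param sessions list of `session_data` (or a single one).
#' @param path output CSV path.
#' @export
write_sessions <- function(sessions, path) {
  if (inherits(sessions, "session_data")) sessions <- list(sessions)
  rows <- do.call(rbind, lapply(sessions, function(s)
    s$trials[, SESSION_COLUMNS]))
  rows$choice[rows$missing] <- NA
  write.csv(rows, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.rebuild_schedule <- function(trials, config) {
  revs <- list(); high <- list()
  for (cond in CONDITIONS) {
    tr <- trials[trials$condition == cond, ]
    tr <- tr[order(tr$condition_trial), ]
    h <- tr$high_option
    revs[[cond]] <- which(diff(h) != 0) + 1L
    high[[cond]] <- h
  }
  structure(list(reversals = revs, high_option = high, config = config),
            class = "reversal_schedule")
}

#' Read sessions from a delimited text file
#'
#' Rows with an unparseable or absent choice are marked missing (with a
#' warning); subjects missing more than 10% of their trials are flagged in
#' `attr(, "flagged_subjects")` but not excluded - exclusion is a reported
#' analysis decision, not an automatic one.
#'
#' @param path CSV path following the [write_sessions()] schema.
#' @param config task configuration to attach (default [task_config()]);
#'   reversal schedules are rebuilt from the per-trial `high_option`
#'   column.
#' @return list of `session_data`, one per subject.
#' @export
read_sessions <- function(path, config = task_config()) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  miss_cols <- setdiff(SESSION_COLUMNS, names(raw))
  if (length(miss_cols))
    stop("session file lacks mandatory column(s): ",
         paste(miss_cols, collapse = ", "), call. = FALSE)
  bad_cue <- !raw$condition_cue %in% c("fear", "neut")
  bad_vol <- !raw$condition_volatility %in% c("freq", "infreq")
  if (any(bad_cue | bad_vol))
    stop("unknown condition label in rows: ",
         paste(head(which(bad_cue | bad_vol), 5), collapse = ", "),
         call. = FALSE)
  raw$condition <- paste(raw$condition_cue, raw$condition_volatility,
                         sep = "_")
  ch_raw <- trimws(as.character(raw$choice))
  blank <- is.na(raw$choice) | ch_raw == "" | toupper(ch_raw) == "NA"
  choice <- suppressWarnings(as.integer(ch_raw))
  bad_choice <- !blank & (is.na(choice) | !choice %in% c(0L, 1L))
  if (any(bad_choice)) {
    warning(sum(bad_choice), " row(s) with unparseable choice marked missing")
  }
  choice[blank | bad_choice] <- NA_integer_
  raw$choice <- choice
  raw$missing <- is.na(choice)
  raw$outcome <- as.integer(raw$outcome)

  subjects <- unique(raw$subject_id)
  flagged <- character(0)
  sessions <- lapply(subjects, function(sid) {
    tr <- raw[raw$subject_id == sid, ]
    tr <- tr[order(tr$global_trial), ]
    if (mean(tr$missing) > 0.1) flagged <<- c(flagged, sid)
    new_session(tr, config, .rebuild_schedule(tr, config))
  })
  names(sessions) <- subjects
  if (length(flagged))
    message("subject(s) with >10% missing trials (review before analysis): ",
            paste(flagged, collapse = ", "))
  attr(sessions, "flagged_subjects") <- flagged
  sessions
}

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()] (used when no `sessions_file` is given).
#' @param sessions_file optional CSV of real sessions to ingest instead of
#'   simulating.
#' @param models model ids to fit and compare.
#' @param fit a [fit_config()].
#' @param grid a [grid_spec()] (set `run_volatility = FALSE` to skip).
#' @param run_volatility whether to run the volatility observer.
#' @param n_perm permutations for the interaction test.
#' @param out_dir output directory for all artifacts.
#' @param seed global seed fanned out to every stage.
#' @return a `run_config` object.
#' @export
run_config <- function(cohort = cohort_spec(), sessions_file = NULL,
                       models = c("M1", "M2"), fit = fit_config(),
                       grid = grid_spec(), run_volatility = TRUE,
                       n_perm = 2000L, out_dir = tempfile("fearvol_run_"),
                       seed = 1L) {
  bad <- setdiff(models, names(model_spec()))
  if (length(bad)) stop("unknown model id(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  structure(list(cohort = cohort, sessions_file = sessions_file,
                 models = models, fit = fit, grid = grid,
                 run_volatility = run_volatility,
                 n_perm = as.integer(n_perm), out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or ingest) -> fit all requested models -> compare -> validate
#' the winner (reversal curves, WSLS, third-trial accuracy, posterior
#' predictive) -> trial-wise subjective volatility -> bias statistics.
#' Every table is written as CSV and every report as JSON under
#' `config$out_dir`, together with a snapshot of the seeds used.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all stage results.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- character(0)
  say <- function(...) {
    line <- sprintf("[%.1fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    paste0(...))
    message(line)
    log_lines <<- c(log_lines, line)
  }

  # stage 1: data
  if (is.null(config$sessions_file)) {
    cs <- config$cohort
    cs$seed <- config$seed
    say("simulating cohort of ", cs$n_subjects, " subjects from ",
        cs$model_id)
    gen <- generate_cohort(cs)
    sessions <- gen$sessions
    truth <- gen$true_params
    covariate <- gen$covariate
    jsonlite::write_json(as.data.frame(truth),
                         file.path(config$out_dir, "truth.json"),
                         digits = NA)
  } else {
    say("reading sessions from ", config$sessions_file)
    sessions <- read_sessions(config$sessions_file, config$cohort$task)
    truth <- NULL; covariate <- NULL
  }
  write_sessions(sessions, file.path(config$out_dir, "sessions.csv"))

  # stage 2: fit + compare
  fits <- list()
  for (id in config$models) {
    say("fitting ", id, " (", config$fit$backend, ")")
    cfg <- config$fit
    cfg$seed <- config$seed + match(id, config$models)
    fits[[id]] <- if (cfg$backend == "map")
      fit_cohort_map(model_spec(id), sessions, cfg)
    else fit_hierarchical(model_spec(id), sessions, cfg)
  }
  comparison <- compare_models(fits)
  winner <- attr(comparison, "winner")
  say("winner: ", winner)
  write.csv(comparison, file.path(config$out_dir, "comparison.csv"),
            row.names = FALSE)
  write.csv(data.frame(subject = rownames(fits[[winner]]$estimates),
                       fits[[winner]]$estimates, check.names = FALSE),
            file.path(config$out_dir, "estimates.csv"), row.names = FALSE)

  # stage 3: validation of the winner
  say("validating ", winner)
  curves <- do.call(rbind, lapply(CONDITIONS, function(cd) {
    cv <- reversal_curve(sessions, cd)
    cv$condition <- cd
    cv
  }))
  write.csv(curves, file.path(config$out_dir, "reversal_curve.csv"),
            row.names = FALSE)
  wsls <- do.call(rbind, lapply(sessions, function(s) {
    w <- wsls_rate(s)
    data.frame(subject = s$trials$subject_id[1], win_stay = w$win_stay,
               loss_switch = w$loss_switch, wsls_sum = w$wsls_sum)
  }))
  write.csv(wsls, file.path(config$out_dir, "wsls.csv"), row.names = FALSE)
  ppc <- posterior_predictive(fits[[winner]], sessions, n_rep = 50L,
                              seed = config$seed + 17L)

  # stage 4: subjective volatility
  vol <- NULL
  if (isTRUE(config$run_volatility)) {
    say("running volatility observer")
    vol <- do.call(rbind, lapply(sessions, function(s) {
      do.call(rbind, lapply(CONDITIONS, function(cd) {
        v <- filter_sequence(s, cd, config$grid)
        v$subject_id <- s$trials$subject_id[1]
        v
      }))
    }))
    write.csv(vol, file.path(config$out_dir, "volatility.csv"),
              row.names = FALSE)
  }

  # stage 5: bias statistics
  stats_report <- NULL
  if (all(paste0("alpha.", CONDITIONS) %in% colnames(fits[[winner]]$estimates))) {
    say("bias statistics")
    if (inherits(fits[[winner]], "cohort_fit")) {
      bw <- cohort_bias_weighted(fits[[winner]])
      bias <- bw$bias
      perm <- permutation_interaction_test(bias, n_perm = config$n_perm,
                                           seed = config$seed + 23L,
                                           weights = bw$weights)
    } else {
      bias <- cohort_bias(fits[[winner]]$estimates)
      perm <- permutation_interaction_test(bias, n_perm = config$n_perm,
                                           seed = config$seed + 23L)
    }
    stats_report <- list(bias = bias, permutation = perm)
    if (!is.null(covariate)) {
      stats_report$covariate <- covariate_correlation(bias, covariate)
    }
    jsonlite::write_json(list(mean_bias = perm$observed,
                              p_value = perm$p_value,
                              n_perm = perm$n_perm,
                              covariate_r = stats_report$covariate$r,
                              covariate_p = stats_report$covariate$p,
                              seed = config$seed),
                         file.path(config$out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  say("done")
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  jsonlite::write_json(list(seed = config$seed, models = config$models,
                            backend = config$fit$backend,
                            n_subjects = length(sessions)),
                       file.path(config$out_dir, "run_config.json"),
                       auto_unbox = TRUE)
  invisible(list(sessions = sessions, truth = truth, fits = fits,
                 comparison = comparison, winner = winner, curves = curves,
                 wsls = wsls, ppc = ppc, volatility = vol,
                 stats = stats_report))
}
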