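#' Learning-rate bias index
#'
#' The double difference `(alpha[fear,freq] - alpha[fear,infreq]) -
#' (alpha[neut,freq] - alpha[neut,infreq])`: how much less the learning
#' rate adapts to volatility under fearful than under neutral cues. A
#' negative value means fear suppressed the volatility adjustment.
#'
#' @param alphas named numeric vector containing the four condition
#'   learning rates; names may be the condition labels or the
#'   `alpha.<condition>` free-parameter names.
#' @return signed double difference.
#' @export
bias_index <- function(alphas) {
  names(alphas) <- sub("^alpha\\.", "", names(alphas))
  miss <- setdiff(CONDITIONS, names(alphas))
  if (length(miss))
    stop("missing learning rate for condition(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  unname((alphas["fear_freq"] - alphas["fear_infreq"]) -
           (alphas["neut_freq"] - alphas["neut_infreq"]))
}

#' Per-subject bias indices from a cohort estimates matrix
#'
#' @param estimates subjects x parameters matrix with `alpha.<condition>`
#'   columns (as produced by the cohort fitters).
#' @export
cohort_bias <- function(estimates) {
  apply(estimates, 1, function(row) bias_index(row[grep("^alpha\\.", names(row))]))
}

#' Permutation test of the cue-by-volatility interaction
#'
#' The null hypothesis of no interaction is built by independently swapping
#' the cue labels within each subject (which flips the sign of that
#' subject's bias index); the two-sided p-value is the smoothed proportion
#' of permuted |mean bias| values at least as large as the observed one.
#' With `weights`, the statistic is the weighted mean (e.g. inverse-variance
#' weights from per-subject estimation uncertainty, the random-effects
#' meta-analytic estimator); sign-flipping remains exact under the
#' within-subject exchangeability of cue labels.
#'
#' @param bias per-subject bias indices (>= 5 subjects).
#' @param n_perm number of permutations (default 10000; below 100 a warning
#'   is issued).
#' @param seed integer seed.
#' @param weights optional nonnegative per-subject weights (normalized
#'   internally; default equal).
#' @return list with `observed` (weighted) mean bias, `p_value`, `n_perm`,
#'   `seed`.
#' @export
permutation_interaction_test <- function(bias, n_perm = 10000L, seed = 1L,
                                         weights = NULL) {
  n <- length(bias)
  if (n < 5) stop("permutation test needs at least 5 subjects", call. = FALSE)
  if (n_perm < 100) warning("fewer than 100 permutations; p-value is coarse")
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(length(weights) == n, all(weights >= 0), sum(weights) > 0)
  w <- weights / sum(weights)
  obs <- sum(w * bias)
  set.seed(seed)
  flips <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n_perm, n)
  perm <- abs(flips %*% (w * bias))
  p <- (1 + sum(perm >= abs(obs))) / (n_perm + 1)
  list(observed = obs, p_value = p, n_perm = as.integer(n_perm),
       seed = as.integer(seed))
}

#' Per-subject bias indices with random-effects precision weights
#'
#' Extracts each subject's bias index and its posterior variance from the
#' Laplace draws of a MAP cohort fit, and forms inverse-variance weights
#' `1 / (se2 + tau2)` with the between-subject component `tau2` estimated
#' by moments (floored at a small positive value).
#'
#' @param fit a `cohort_fit` with per-subject draws.
#' @return list `bias`, `se2`, `tau2`, `weights`.
#' @export
cohort_bias_weighted <- function(fit) {
  a <- paste0("alpha.", CONDITIONS)
  if (!all(a %in% colnames(fit$estimates)))
    stop("fit lacks per-condition learning rates", call. = FALSE)
  bias <- cohort_bias(fit$estimates)
  se2 <- vapply(fit$subject_fits, function(f)
    var((f$draws[, a[1]] - f$draws[, a[2]]) -
          (f$draws[, a[3]] - f$draws[, a[4]])), 0)
  tau2 <- max(var(bias) - mean(se2), 0.002)
  w <- 1 / (se2 + tau2)
  list(bias = bias, se2 = se2, tau2 = tau2, weights = w / sum(w))
}

#' Correlation between the bias index and a per-subject covariate
#'
#' @param bias per-subject bias indices.
#' @param covariate per-subject trait scores (e.g. an alexithymia total).
#' @param method correlation method (default Pearson).
#' @return list `r`, `p`, `n`, `degenerate` (TRUE when either input has
#'   zero variance, in which case r and p are `NA`).
#' @export
covariate_correlation <- function(bias, covariate, method = "pearson") {
  ok <- stats::complete.cases(bias, covariate)
  x <- bias[ok]; y <- covariate[ok]
  if (length(x) < 4) stop("need at least 4 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x), degenerate = TRUE))
  ct <- cor.test(x, y, method = method)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       degenerate = FALSE)
}

#' Bias-covariate correlations for a family of covariates
#'
#' Benjamini-Hochberg adjusted p-values are added when more than one
#' covariate is tested.
#'
#' @param bias per-subject bias indices.
#' @param covariates data frame or matrix of per-subject covariates.
#' @return data frame `covariate`, `r`, `p` (and `p_adj` when several are
#'   tested).
#' @export
covariate_correlations <- function(bias, covariates) {
  covariates <- as.data.frame(covariates)
  out <- do.call(rbind, lapply(names(covariates), function(nm) {
    res <- covariate_correlation(bias, covariates[[nm]])
    data.frame(covariate = nm, r = res$r, p = res$p,
               stringsAsFactors = FALSE)
  }))
  if (nrow(out) > 1) out$p_adj <- p.adjust(out$p, method = "BH")
  out
}
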