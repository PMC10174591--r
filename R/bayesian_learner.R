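#' @title Grid-based Bayesian observer of reward probability and volatility
#' @description
#' The observer tracks three coupled quantities on a discrete grid: the
#' reward probability of a tracked option (V), the log transition width of
#' that probability (SV, the subjective volatility), and a static
#' meta-parameter k governing how fast SV itself may drift. Between trials
#' SV diffuses through a Normal kernel with sd `exp(k)` and V diffuses
#' through a Beta kernel with mean `V_t` and variance `exp(SV)` (capped
#' just below the feasible Beta variance `V_t (1 - V_t)`; larger SV, wider
#' transitions); the binary outcome then reweights the joint mass by the
#' Bernoulli likelihood. Trial-wise subjective volatility is the posterior
#' marginal mean of SV.
#'
#' The width parameter enters as the transition *variance* rather than as
#' an inverse concentration: with an inverse-concentration width the kernel
#' narrows sharply near the probability boundaries, which lets high-SV
#' hypotheses commit tightly to extreme reward probabilities and -
#' perversely - accumulate *more* evidence from stable outcome runs than
#' low-SV hypotheses, inverting the volatility signal. The kernel is
#' additionally constrained to stay unimodal: when the requested variance
#' is infeasible at the current mean, the transition mean is shrunk toward
#' 0.5 (in the wide limit the kernel becomes a uniform redraw of the
#' reward probability, i.e. a changepoint-style transition). Under these
#' choices sequences with more frequent reversals support higher
#' subjective volatility, as they should.
#' @name bayesian_learner
NULL

#' Grid specification for the volatility observer
#'
#' @param n_v number of reward-probability cells; the grid holds the
#'   midpoints of `n_v` equal bins of `(0, 1)`.
#' @param n_sv,sv_range cells and range of the log transition-variance
#'   grid; the default upper end sits just below the largest variance a
#'   Beta transition can express.
#' @param n_k,k_range cells and range of the static drift parameter grid
#'   (`exp(k)` is the sd of the SV random walk).
#' @return a `grid_spec` with precomputed, row-stochastic transition
#'   kernels.
#' @export
grid_spec <- function(n_v = 50L, n_sv = 30L, sv_range = c(-8, -2),
                      n_k = 15L, k_range = c(-6, 1)) {
  stopifnot(n_v >= 2, n_sv >= 2, n_k >= 1,
            sv_range[1] < sv_range[2], k_range[1] < k_range[2])
  v_edges <- seq(0, 1, length.out = n_v + 1)
  v <- (v_edges[-1] + v_edges[-(n_v + 1)]) / 2
  sv <- seq(sv_range[1], sv_range[2], length.out = n_sv)
  kg <- seq(k_range[1], k_range[2], length.out = n_k)

  # SV random-walk kernels, one per k cell: mass of N(sv_i, exp(k)) in the
  # bin around sv_j (outer bins absorb the tails)
  sv_inner <- (sv[-1] + sv[-n_sv]) / 2
  lo <- c(-Inf, sv_inner); hi <- c(sv_inner, Inf)
  T_sv <- lapply(kg, function(k1) {
    K <- exp(k1)
    m <- t(vapply(sv, function(mu)
      pnorm(hi, mu, K) - pnorm(lo, mu, K), numeric(n_sv)))
    m / rowSums(m)
  })

  # V transition kernels, one per SV cell: Beta with mean v and variance
  # exp(SV), constrained to unimodal shapes (concentration >= 2); when the
  # variance is infeasible at mean v the mean is shrunk toward 0.5, and in
  # the wide limit (variance >= 1/12) the kernel is the uniform redraw.
  # Two numerical safeguards keep the filter resolution-independent:
  # - the source value is integrated over its bin (3-point Gauss-Legendre)
  #   rather than taken at the midpoint, since the Beta shape changes
  #   steeply within a bin near the probability boundaries;
  # - when the kernel is narrower than a bin, naive bin-mass
  #   discretization makes the chain's effective diffusion scale with the
  #   bin width; such rows are replaced by a tridiagonal kernel matched to
  #   the continuous kernel's variance.
  gl_nodes <- c(-sqrt(3 / 5), 0, sqrt(3 / 5)) / 2
  gl_w <- c(5, 8, 5) / 18
  bin_w <- 1 / n_v
  beta_shape <- function(mu, s) {
    if (mu * (1 - mu) / 3 >= s) {
      cc <- mu * (1 - mu) / s - 1
      c(mu * cc, (1 - mu) * cc)
    } else if (s >= 1 / 12) {
      c(1, 1)                      # widest unimodal member: uniform redraw
    } else {
      disc <- sqrt(1 - 12 * s)     # shrink the mean until s is feasible
      mp <- min(max(mu, (1 - disc) / 2), (1 + disc) / 2)
      c(2 * mp, 2 * (1 - mp))
    }
  }
  beta_row <- function(mu, s) {
    ab <- beta_shape(mu, s)
    d <- pbeta(v_edges[-1], ab[1], ab[2]) -
      pbeta(v_edges[-(n_v + 1)], ab[1], ab[2])
    if (sum(d) <= 0) { d <- numeric(n_v); d[which.min(abs(v - mu))] <- 1 }
    d
  }
  T_v <- lapply(sv, function(sv1) {
    s <- exp(sv1)
    m <- t(vapply(seq_len(n_v), function(i) {
      mid <- v[i]
      sd_k <- sqrt(min(s, 1 / 12))
      if (sd_k < bin_w / 2) {
        d <- numeric(n_v)
        p_step <- sd_k^2 / (2 * bin_w^2)
        d[i] <- 1 - 2 * p_step
        if (i > 1) d[i - 1] <- p_step else d[i] <- d[i] + p_step
        if (i < n_v) d[i + 1] <- p_step else d[i] <- d[i] + p_step
        return(d)
      }
      dif <- numeric(n_v)
      for (q in 1:3) {
        dif <- dif + gl_w[q] * beta_row(mid + gl_nodes[q] * bin_w, s)
      }
      dif
    }, numeric(n_v)))
    m / rowSums(m)
  })

  structure(list(v = v, sv = sv, k = kg, n_v = as.integer(n_v),
                 n_sv = as.integer(n_sv), n_k = as.integer(n_k),
                 T_sv = T_sv, T_v = T_v),
            class = "grid_spec")
}

#' Uniform joint prior over the grid
#'
#' @param grid a [grid_spec()].
#' @return a normalized array of dimension `(n_v, n_sv, n_k)`.
#' @export
init_prior <- function(grid) {
  array(1 / (grid$n_v * grid$n_sv * grid$n_k),
        dim = c(grid$n_v, grid$n_sv, grid$n_k))
}

.check_mass <- function(post) {
  if (abs(sum(post) - 1) > 1e-8)
    stop("joint posterior is not normalized", call. = FALSE)
}

#' One between-trial diffusion step of the joint posterior
#'
#' SV diffuses first (Normal kernel, sd `exp(k)`), then V diffuses with the
#' Beta kernel indexed by the post-diffusion SV cell; k is static.
#'
#' @param post joint posterior array.
#' @param grid a [grid_spec()].
#' @return diffused joint posterior (mass conserved).
#' @export
propagate <- function(post, grid) {
  .check_mass(post)
  for (kk in seq_len(grid$n_k)) {
    post[, , kk] <- post[, , kk] %*% grid$T_sv[[kk]]
  }
  for (j in seq_len(grid$n_sv)) {
    post[, j, ] <- crossprod(grid$T_v[[j]], post[, j, ])
  }
  post / sum(post)
}

#' Bayesian update of the joint posterior for one binary outcome
#'
#' @param post joint posterior array.
#' @param y binary latent outcome of the tracked option.
#' @param grid a [grid_spec()].
#' @export
observe <- function(post, y, grid) {
  stopifnot(y %in% c(0, 1))
  lik <- if (y == 1) grid$v else 1 - grid$v
  post <- post * lik
  post / sum(post)
}

#' Latent outcome of the tracked option
#'
#' The two options pay off anticorrelated rewards, so the outcome of the
#' chosen option identifies the outcome the tracked option would have
#' given: equal to the observed outcome when the tracked option was chosen,
#' its complement otherwise; `NA` for missing trials.
#'
#' @param choice 0, 1, or `NA`.
#' @param outcome binary reward.
#' @param tracked_option option id whose reward probability is tracked.
#' @export
infer_latent_outcome <- function(choice, outcome, tracked_option = 1L) {
  ifelse(is.na(choice), NA_integer_,
         ifelse(choice == tracked_option, outcome, 1L - outcome))
}

.marginal_means <- function(post, grid) {
  c(v = sum(apply(post, 1, sum) * grid$v),
    sv = sum(apply(post, 2, sum) * grid$sv))
}

#' Run the volatility observer over one condition of a session
#'
#' The filter runs independently per condition (each has its own
#' contingency) in condition-local time: each trial is a diffusion step
#' followed, when the trial has a response, by an outcome update. Missing
#' trials diffuse without observing.
#'
#' @param session a `session_data`.
#' @param condition condition label.
#' @param grid a [grid_spec()].
#' @param tracked_option option whose reward probability is tracked
#'   (default 1).
#' @return a `volatility_trace` data frame: `condition`, `condition_trial`,
#'   `v_mean`, `sv_mean`, `y`.
#' @export
filter_sequence <- function(session, condition, grid = grid_spec(),
                            tracked_option = 1L) {
  tr <- session$trials[session$trials$condition == condition, ]
  if (nrow(tr) == 0) stop("condition not present: ", condition, call. = FALSE)
  tr <- tr[order(tr$condition_trial), ]
  y_seq <- infer_latent_outcome(tr$choice, tr$outcome, tracked_option)
  out <- filter_outcomes(y_seq, grid)
  out$condition <- condition
  out$condition_trial <- tr$condition_trial
  out[, c("condition", "condition_trial", "v_mean", "sv_mean", "y")]
}

#' Run the volatility observer over a raw latent-outcome sequence
#'
#' @param y_seq vector of binary outcomes (`NA` = missing, diffusion only).
#' @param grid a [grid_spec()].
#' @return a `volatility_trace` data frame with `v_mean`, `sv_mean`, `y`.
#' @export
filter_outcomes <- function(y_seq, grid = grid_spec()) {
  post <- init_prior(grid)
  n <- length(y_seq)
  vm <- numeric(n); svm <- numeric(n)
  for (t in seq_len(n)) {
    post <- propagate(post, grid)
    if (!is.na(y_seq[t])) post <- observe(post, y_seq[t], grid)
    mm <- .marginal_means(post, grid)
    vm[t] <- mm["v"]; svm[t] <- mm["sv"]
  }
  structure(data.frame(v_mean = vm, sv_mean = svm, y = y_seq),
            class = c("volatility_trace", "data.frame"))
}
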