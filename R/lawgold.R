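#' Sample an MT population
#'
#' Each model MT neuron is characterized by five parameters drawn
#' uniformly at random: preferred direction `theta_pref ~ U(-180, 180)`
#' degrees, zero-coherence response `k0 ~ U(0, 20)`, preferred-direction
#' gain `kp ~ U(0, 50)`, null-direction gain `kn ~ U(-k0, 0)` (bounded
#' below by `-k0` so mean rates never go negative) and Fano factor
#' `fano ~ U(1, 5)`. The tuning width `sigma_theta = 30` degrees is shared
#' by all neurons.
#'
#' @param n Number of neurons (full-scale runs use 7200; the scaled-down
#'   default for interactive work is 720).
#' @param sigma_theta Shared tuning width in degrees.
#' @return A list of class `mt_population` with parameter vectors
#'   `theta_pref`, `k0`, `kp`, `kn`, `fano` and scalar `sigma_theta`.
#' @export
sample_mt_population <- function(n = 720, sigma_theta = 30) {
  stopifnot(n >= 2)
  k0 <- stats::runif(n, 0, 20)
  structure(list(
    theta_pref = stats::runif(n, -180, 180),
    k0 = k0,
    kp = stats::runif(n, 0, 50),
    kn = stats::runif(n, -k0, 0),
    fano = stats::runif(n, 1, 5),
    sigma_theta = sigma_theta,
    n = n
  ), class = "mt_population")
}

#' Random-dot-motion stimulus specification
#'
#' @param direction Motion direction in degrees, `-90` (left) or `+90`
#'   (right).
#' @param coh Motion coherence in `(0, 1]`.
#' @param duration Stimulus duration in seconds (default 1).
#' @return A list of class `stimulus_spec`.
#' @export
stimulus_spec <- function(direction, coh, duration = 1) {
  stopifnot(direction %in% c(-90, 90), coh > 0, coh <= 1, duration > 0)
  structure(list(direction = direction, coh = coh, duration = duration),
            class = "stimulus_spec")
}

# Circular difference wrapped to [-180, 180).
angle_diff <- function(a, b) {
  d <- (a - b) %% 360
  d - 360 * (d >= 180)
}

#' Mean MT spike counts for a stimulus
#'
#' `m_i = T * (k0 + COH * (kn + (kp - kn) * f(theta | Theta_i)))` with the
#' Gaussian direction-tuning curve
#' `f(theta | Theta_i) = exp(-(theta - Theta_i)^2 / (2 sigma_theta^2))`
#' (angular difference wrapped to the circle). Non-negative under the
#' population parameter constraints.
#'
#' @param pop An [sample_mt_population()] object.
#' @param stim A [stimulus_spec()].
#' @return Vector of expected spike counts, one per neuron.
#' @export
mt_mean_rate <- function(pop, stim) {
  stopifnot(inherits(pop, "mt_population"), inherits(stim, "stimulus_spec"))
  f <- exp(-angle_diff(stim$direction, pop$theta_pref)^2 /
             (2 * pop$sigma_theta^2))
  stim$duration * (pop$k0 + stim$coh * (pop$kn + (pop$kp - pop$kn) * f))
}

#' Sample noisy MT population activity
#'
#' Spike counts are rectified Gaussian samples with variance
#' `v_i = fano_i * m_i` around the mean count `m_i`.
#'
#' @inheritParams mt_mean_rate
#' @return Non-negative activity vector `x`.
#' @export
mt_activity <- function(pop, stim) {
  m <- mt_mean_rate(pop, stim)
  pmax(0, stats::rnorm(pop$n, m, sqrt(pop$fano * m)))
}

#' MT-to-LIP readout state
#'
#' The decision variable is `h = w . x + eps` with `eps` zero-mean
#' Gaussian endogenous noise that learning cannot remove. The squared
#' weight norm is constrained to `w_amp` after every update. Initial
#' weights are a small random direction rescaled to the constraint (zero
#' initial weights would make `h` pure noise and the reward-prediction fit
#' degenerate).
#'
#' @param n_neurons Number of MT inputs.
#' @param w_amp Squared-norm constraint (default 0.02).
#' @param eta Learning rate (1e-7 at the full 7200-neuron scale; scaled-
#'   down runs co-scale `eta` and `n_neurons` so per-trial weight change
#'   stays comparable).
#' @param eps_sigma Standard deviation of the endogenous decision noise
#'   (default 0).
#' @return A list of class `readout_state`.
#' @export
readout_state <- function(n_neurons, w_amp = 0.02, eta = 1e-6,
                          eps_sigma = 0) {
  stopifnot(n_neurons >= 2, w_amp > 0, eta > 0, eps_sigma >= 0)
  w <- stats::rnorm(n_neurons)
  w <- w * sqrt(w_amp / sum(w^2))
  structure(list(w = w, w_amp = w_amp, eta = eta, eps_sigma = eps_sigma),
            class = "readout_state")
}

#' LIP decision from MT activity
#'
#' @param readout A [readout_state()].
#' @param x MT activity vector.
#' @return A list with decision variable `h`, choice `C` (+1 right, -1
#'   left; fair coin at `h = 0`).
#' @export
lip_decide <- function(readout, x) {
  stopifnot(inherits(readout, "readout_state"),
            length(x) == length(readout$w))
  h <- sum(readout$w * x) +
    if (readout$eps_sigma > 0) stats::rnorm(1, 0, readout$eps_sigma) else 0
  C <- if (h > 0) 1L else if (h < 0) -1L else
    (if (stats::runif(1) < 0.5) 1L else -1L)
  list(h = h, C = C)
}

#' Predicted reward from the decision-variable magnitude
#'
#' `E[r] = 1 / (1 + exp(-B |h|))`: confidence grows with the distance of
#' the decision variable from the boundary, scaled by the online-estimated
#' proportionality constant `B`.
#'
#' @param h Decision variable.
#' @param B Non-negative proportionality constant.
#' @return Predicted reward in `[0.5, 1)`.
#' @export
predicted_reward <- function(h, B) {
  stopifnot(B >= 0)
  1 / (1 + exp(-B * abs(h)))
}

#' Online estimate of the reward-prediction slope B
#'
#' Intercept-free logistic regression of trial correctness on `|h|` over
#' the trailing history window, matching the functional form of
#' [predicted_reward()]. Negative estimates are clipped to zero; if the
#' history is degenerate (all correct or all error) the estimate
#' saturates and is flagged; if the fit fails the previous value is
#' returned.
#'
#' @param h_abs Vector of `|h|` values from recent trials.
#' @param correct Logical/0-1 vector of the same length.
#' @param B_prev Fallback value if the fit fails.
#' @param B_max Upper clip.
#' @return Estimated `B >= 0`.
#' @export
estimate_B <- function(h_abs, correct, B_prev = 0, B_max = 50) {
  if (length(h_abs) == 0) return(B_prev)
  fit <- tryCatch(
    logit_slope(h_abs, as.numeric(correct), lower = 0, upper = B_max),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit)) return(B_prev)
  as.numeric(fit)
}

#' Reward-prediction-error weight update with norm constraint
#'
#' `w <- w + eta * C * (r - E[r]) * x`, followed by rescaling to the
#' squared-norm constraint `sum(w^2) = w_amp`.
#'
#' @inheritParams lip_decide
#' @param C Choice, -1 or +1.
#' @param r Reward, 0 or 1.
#' @param E_r Predicted reward.
#' @return The updated `readout_state`.
#' @export
update_weights <- function(readout, x, C, r, E_r) {
  stopifnot(C %in% c(-1L, 1L), r %in% c(0, 1), E_r >= 0, E_r <= 1)
  w <- readout$w + readout$eta * C * (r - E_r) * x
  nrm2 <- sum(w^2)
  if (nrm2 == 0) {
    warning("weight vector collapsed to zero; re-initializing direction")
    w <- stats::rnorm(length(w))
    nrm2 <- sum(w^2)
  }
  readout$w <- w * sqrt(readout$w_amp / nrm2)
  readout
}

#' Coherence staircase on logit scale
#'
#' The first `init_trials` trials use a fixed coherence of
#' `init_coh = 0.9`. Thereafter the logit-coherence state is updated as
#' `Gamma_{t+1} = Gamma_t + d_gamma * (A_target - A_L)` with `A_L` the
#' accuracy over the last `min(300, t)` trials, and
#' `COH = logistic(Gamma)`. `Gamma` is seeded at `logit(init_coh)` when
#' the staircase takes over, so coherence is continuous across the
#' initialization boundary.
#'
#' @param A_target Target training accuracy.
#' @param d_gamma Step size (default 0.1).
#' @param init_trials Length of the fixed-coherence initialization phase.
#' @param init_coh Coherence during initialization.
#' @param window Maximum accuracy-window length (default 300).
#' @return A list of class `coherence_staircase`.
#' @export
coherence_staircase <- function(A_target, d_gamma = 0.1, init_trials = 50,
                                init_coh = 0.9, window = 300) {
  stopifnot(A_target > 0.5, A_target < 1, d_gamma > 0,
            init_coh > 0, init_coh < 1)
  structure(list(A_target = A_target, d_gamma = d_gamma,
                 init_trials = init_trials, init_coh = init_coh,
                 window = window,
                 gamma = log(init_coh / (1 - init_coh)),
                 flags = logical(0)),
            class = "coherence_staircase")
}

#' @rdname coherence_staircase
#' @param stair A `coherence_staircase`.
#' @param correct Logical: was trial `t` correct?
#' @param t Trial index just completed.
#' @return `staircase_coherence()` returns the updated staircase with
#'   element `coh`, the coherence for trial `t + 1`.
#' @export
staircase_coherence <- function(stair, correct, t) {
  stopifnot(inherits(stair, "coherence_staircase"), t >= 1)
  flags <- c(stair$flags, correct)
  if (length(flags) > stair$window) {
    flags <- flags[(length(flags) - stair$window + 1):length(flags)]
  }
  stair$flags <- flags
  if (t >= stair$init_trials) {
    A_L <- mean(flags)
    stair$gamma <- stair$gamma + stair$d_gamma * (stair$A_target - A_L)
  }
  stair$coh <- if (t + 1 <= stair$init_trials) stair$init_coh
               else 1 / (1 + exp(-stair$gamma))
  stair
}

#' Psychometric precision of a trained readout
#'
#' Simulates the trained network (learning disabled) on a grid of
#' logarithmically spaced coherences, `n_rep` trials per coherence with
#' random direction, and fits the intercept-free logistic psychometric
#' function `ACC ~ 1/(1 + exp(-beta * COH))` to the per-trial correctness
#' by logistic regression. The fitted slope `beta` is the precision
#' estimate for the trained model.
#'
#' @param readout A trained [readout_state()].
#' @param pop The [sample_mt_population()] the readout was trained on.
#' @param coh_grid Test coherences (default 20 log-spaced in
#'   `[1e-3, 1]`).
#' @param n_rep Trials per coherence (default 100).
#' @return Fitted precision `beta >= 0`, with attribute `accuracy_table`
#'   (tibble of per-coherence empirical accuracy).
#' @export
fit_psychometric <- function(readout, pop,
                             coh_grid = 10^seq(-3, 0, length.out = 20),
                             n_rep = 100) {
  stopifnot(inherits(readout, "readout_state"),
            inherits(pop, "mt_population"))
  coh_all <- rep(coh_grid, each = n_rep)
  correct <- logical(length(coh_all))
  for (i in seq_along(coh_all)) {
    dir <- if (stats::runif(1) < 0.5) 90 else -90
    stim <- stimulus_spec(dir, coh_all[i])
    x <- mt_activity(pop, stim)
    dec <- lip_decide(readout, x)
    correct[i] <- dec$C == sign(dir)
  }
  b <- logit_slope(coh_all, as.numeric(correct), lower = 0, upper = 1e3)
  if (isFALSE(attr(b, "converged")) && !isTRUE(attr(b, "degenerate"))) {
    tab <- tibble::tibble(coh = coh_grid,
                          accuracy = tapply(correct, rep(seq_along(coh_grid),
                                                         each = n_rep), mean))
    stop(paste0("psychometric fit failed to converge; accuracy table:\n",
                paste(utils::capture.output(print(tab)), collapse = "\n")),
         call. = FALSE)
  }
  acc <- tapply(correct, rep(seq_along(coh_grid), each = n_rep), mean)
  structure(as.numeric(b),
            accuracy_table = tibble::tibble(coh = coh_grid,
                                            accuracy = as.numeric(acc)))
}

#' Train the MT/LIP model at a clamped target accuracy
#'
#' Full reinforcement-learning loop: on every trial a random direction
#' (+/-90 degrees) is shown at the staircased coherence, MT activity is
#' sampled, the LIP readout decides, reward is delivered for a correct
#' choice, the reward-prediction slope `B` is re-estimated from the last
#' `min(300, t)` trials (held at 0 for the first `b_warmup` trials), and
#' the weights are updated by the reward-prediction error and
#' renormalized. After training, precision is measured with
#' [fit_psychometric()].
#'
#' @param A_target Target training accuracy in `(0.5, 1)`.
#' @param n_trials Training trials (default 3000).
#' @param pop Optional pre-sampled [sample_mt_population()]; if `NULL` a
#'   fresh population of `n_neurons` is drawn.
#' @param n_neurons Population size when `pop` is `NULL`.
#' @param eta Learning rate.
#' @param eps_sigma Endogenous decision-noise standard deviation.
#' @param b_warmup Trials before the first `B` fit.
#' @param n_rep_test Test trials per coherence for the psychometric fit.
#' @return A list with the trained `readout`, `pop`, `beta`
#'   (psychometric precision), `empirical_er` (training error rate after
#'   the initialization phase), `A_target`, and per-trial vectors `coh`,
#'   `correct`, `B`.
#' @export
run_lawgold_training <- function(A_target, n_trials = 3000, pop = NULL,
                                 n_neurons = 720, eta = 1e-6,
                                 eps_sigma = 0, b_warmup = 10,
                                 n_rep_test = 100) {
  stopifnot(A_target > 0.5, A_target < 1, n_trials >= 1)
  if (is.null(pop)) pop <- sample_mt_population(n_neurons)
  readout <- readout_state(pop$n, eta = eta, eps_sigma = eps_sigma)
  stair <- coherence_staircase(A_target)
  coh <- stair$init_coh
  correct <- logical(n_trials)
  coh_hist <- numeric(n_trials)
  B_hist <- numeric(n_trials)
  h_abs_hist <- numeric(n_trials)
  B <- 0
  max_norm_dev <- 0
  for (t in seq_len(n_trials)) {
    dir <- if (stats::runif(1) < 0.5) 90 else -90
    stim <- stimulus_spec(dir, coh)
    x <- mt_activity(pop, stim)
    dec <- lip_decide(readout, x)
    correct[t] <- dec$C == sign(dir)
    coh_hist[t] <- coh
    h_abs_hist[t] <- abs(dec$h)
    # reward is predicted from B fitted on trials 1..t-1: prediction
    # precedes the outcome of the current trial
    if (t > b_warmup) {
      L <- min(300, t - 1)
      B <- estimate_B(h_abs_hist[(t - L):(t - 1)], correct[(t - L):(t - 1)],
                      B_prev = B)
    }
    B_hist[t] <- B
    E_r <- predicted_reward(dec$h, B)
    r <- as.numeric(correct[t])
    readout <- update_weights(readout, x, dec$C, r, E_r)
    norm_dev <- abs(sum(readout$w^2) - readout$w_amp)
    if (norm_dev > max_norm_dev) max_norm_dev <- norm_dev
    stair <- staircase_coherence(stair, correct[t], t)
    coh <- stair$coh
  }
  beta <- fit_psychometric(readout, pop, n_rep = n_rep_test)
  post_init <- seq(stair$init_trials + 1, n_trials)
  list(readout = readout, pop = pop, beta = as.numeric(beta),
       accuracy_table = attr(beta, "accuracy_table"),
       empirical_er = mean(!correct[post_init]),
       max_norm_dev = max_norm_dev,
       A_target = A_target, coh = coh_hist, correct = correct, B = B_hist)
}

#' Sweep the MT/LIP model over target training error rates
#'
#' Runs `n_runs` training sessions per target. The same `n_runs` MT
#' populations are reused across all targets (replicate sub-seeds shared
#' across conditions -- a paired design that removes population-level
#' variability from between-target comparisons).
#'
#' @param er_grid Target training error rates (accuracy targets are
#'   `1 - er_grid`).
#' @param n_runs Runs per target.
#' @param n_trials,n_neurons,eta,eps_sigma Passed to
#'   [run_lawgold_training()].
#' @param seed Master seed.
#' @return A tibble with one row per (target, run): `er_target`,
#'   `run`, `beta`, `empirical_er`.
#' @export
lawgold_sweep <- function(er_grid = c(0.06, 0.11, 0.16, 0.21, 0.26, 0.31,
                                      0.38, 0.44),
                          n_runs = 20, n_trials = 3000, n_neurons = 720,
                          eta = 1e-6, eps_sigma = 0, seed = 1) {
  stopifnot(all(er_grid > 0), all(er_grid < 0.5))
  rows <- vector("list", length(er_grid) * n_runs)
  k <- 0
  for (j in seq_len(n_runs)) {
    for (er in er_grid) {
      set.seed(derive_seed(seed, j))
      res <- run_lawgold_training(1 - er, n_trials = n_trials,
                                  n_neurons = n_neurons, eta = eta,
                                  eps_sigma = eps_sigma)
      k <- k + 1
      rows[[k]] <- tibble::tibble(er_target = er, run = j,
                                  beta = res$beta,
                                  empirical_er = res$empirical_er,
                                  max_norm_dev = res$max_norm_dev)
    }
  }
  dplyr::bind_rows(rows)
}
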