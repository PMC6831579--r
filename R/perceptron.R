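#' Teacher perceptron
#'
#' Ground-truth labels for the perceptron experiments are generated by a
#' teacher perceptron with unit-norm weight vector `e`: a stimulus `x` is
#' labeled 1 iff `e . x > 0`, and its difficulty is the distance to the
#' boundary, `Delta = |e . x|`.
#'
#' @param d Stimulus dimension (default 100).
#' @return A list of class `teacher_weights` with unit-norm element `e`.
#' @export
teacher_weights <- function(d = 100) {
  stopifnot(d >= 2)
  e <- stats::rnorm(d)
  structure(list(e = e / sqrt(sum(e^2))), class = "teacher_weights")
}

student_from_w <- function(w, e) {
  nw <- sqrt(sum(w^2))
  ct <- sum(w * e) / nw
  ct <- min(max(ct, -1), 1)
  theta <- acos(ct)
  beta <- if (theta == 0) Inf else 1 / tan(theta)
  structure(list(w = w, theta = theta, beta = beta), class = "student_state")
}

#' Initialize a student perceptron at a controlled angle to the teacher
#'
#' The student weight vector is drawn with a random direction in the plane
#' orthogonal to the teacher and its component along the teacher set so
#' that the angle `theta` between student and teacher is uniform on
#' `theta_range`. The upper default of 1.5 rad keeps the initial precision
#' `beta = cot(theta)` positive, mimicking a modest degree of initial
#' training.
#'
#' @param teacher A [teacher_weights()].
#' @param theta_range Interval from which the initial angle is drawn
#'   uniformly (radians).
#' @return A `student_state`: list with weight vector `w`, angle `theta`
#'   and precision `beta = cot(theta)`.
#' @export
init_student <- function(teacher, theta_range = c(0.05, 1.5)) {
  stopifnot(inherits(teacher, "teacher_weights"),
            length(theta_range) == 2, theta_range[1] > 0,
            theta_range[2] < pi, theta_range[1] < theta_range[2])
  e <- teacher$e
  theta <- stats::runif(1, theta_range[1], theta_range[2])
  g <- stats::rnorm(length(e))
  g <- g - sum(g * e) * e
  g <- g / sqrt(sum(g^2))
  student_from_w(cos(theta) * e + sin(theta) * g, e)
}

#' Difficulty that clamps the single-trial error rate
#'
#' With unit-norm teacher and i.i.d. standard-normal stimuli, the noise
#' projected onto the student's off-teacher direction is standard normal,
#' so the student's single-trial error probability at angle `theta` and
#' difficulty `Delta` is `F(-Delta * cot(theta))`. Setting
#' `Delta = |F^{-1}(er_target)| * tan(theta)` therefore clamps the error
#' rate at `er_target` exactly. For an anti-aligned student
#' (`theta >= pi/2`) the clamp is undefined; the configured maximum
#' difficulty is returned with attribute `flagged = TRUE`.
#'
#' @param theta Student-teacher angle in radians.
#' @param er_target Target error rate in `(0, 0.5)`.
#' @inheritParams error_rate
#' @param delta_max Difficulty returned when the clamp is undefined.
#' @return The difficulty for the next trial (`>= 0`).
#' @export
clamp_difficulty <- function(theta, er_target, noise = gaussian_noise(),
                             delta_max = 100) {
  stopifnot(er_target > 0, er_target < 0.5, theta > 0)
  if (theta >= pi / 2) {
    return(structure(delta_max, flagged = TRUE))
  }
  abs(noise$icdf(er_target)) * tan(theta)
}

#' Generate one perceptron trial at a prescribed difficulty
#'
#' The label is a fair coin; the stimulus is standard normal in the
#' subspace orthogonal to the teacher with its teacher component set to
#' `(2t - 1) * delta`, so that `|e . x| = delta` exactly while the
#' off-teacher noise remains standard normal in every direction.
#'
#' @inheritParams init_student
#' @param delta Difficulty `>= 0`.
#' @return A list of class `perceptron_trial` with `x`, `t_label` and
#'   `delta`.
#' @export
make_trial <- function(teacher, delta) {
  stopifnot(inherits(teacher, "teacher_weights"), delta >= 0)
  e <- teacher$e
  t_label <- as.integer(stats::runif(1) < 0.5)
  z <- stats::rnorm(length(e))
  x <- z + ((2 * t_label - 1) * delta - sum(e * z)) * e
  structure(list(x = x, t_label = t_label, delta = delta),
            class = "perceptron_trial")
}

#' One perceptron learning step
#'
#' Predicts `y = 1[h > 0]` with `h = w . x` (fair coin at `h = 0`) and
#' applies the mistake-driven update `w <- w + (t - y) x`: the weights only
#' move when the prediction is wrong. The angle to the teacher and the
#' precision `beta = cot(theta)` are recomputed after the update.
#'
#' @param student A `student_state` (see [init_student()]).
#' @param trial A `perceptron_trial` (see [make_trial()]).
#' @inheritParams init_student
#' @return The updated `student_state`, with attributes `y` (the predicted
#'   label) and `correct`.
#' @export
perceptron_step <- function(student, trial, teacher) {
  stopifnot(inherits(student, "student_state"),
            inherits(trial, "perceptron_trial"),
            inherits(teacher, "teacher_weights"))
  h <- sum(student$w * trial$x)
  y <- if (h > 0) 1L else if (h < 0) 0L else as.integer(stats::runif(1) < 0.5)
  if (y != trial$t_label) {
    out <- student_from_w(student$w + (trial$t_label - y) * trial$x,
                          teacher$e)
  } else {
    out <- student
  }
  attr(out, "y") <- y
  attr(out, "correct") <- y == trial$t_label
  out
}

#' Run one error-clamped perceptron training session
#'
#' Repeats, for `n_trials` trials: clamp the difficulty to the target
#' error rate given the current angle, draw a trial, classify, update on
#' mistakes. This is an optimized loop that is random-stream equivalent to
#' composing [init_student()], [clamp_difficulty()], [make_trial()] and
#' [perceptron_step()] (verified in the test suite).
#'
#' @param er_target Clamped training error rate in `(0, 0.5)`.
#' @param n_trials Number of trials (default 1000).
#' @param d Stimulus dimension (default 100).
#' @inheritParams error_rate
#' @inheritParams init_student
#' @inheritParams clamp_difficulty
#' @return A list with `beta` (trajectory, length `n_trials`, the precision
#'   after each trial), `beta_final`, `correct` (logical per trial),
#'   `n_flagged` (trials on which the clamp was undefined) and `student`.
#' @export
perceptron_run <- function(er_target, n_trials = 1000, d = 100,
                           noise = gaussian_noise(),
                           theta_range = c(0.05, 1.5), delta_max = 100) {
  stopifnot(er_target > 0, er_target < 0.5, n_trials >= 0, d >= 2)
  teacher <- teacher_weights(d)
  e <- teacher$e
  student <- init_student(teacher, theta_range)
  w <- student$w
  we <- sum(w * e)
  nw2 <- sum(w * w)
  q <- abs(noise$icdf(er_target))
  beta_tr <- numeric(n_trials)
  correct <- logical(n_trials)
  n_flagged <- 0L
  for (i in seq_len(n_trials)) {
    ct <- min(max(we / sqrt(nw2), -1), 1)
    if (ct <= 0) {
      delta <- delta_max
      n_flagged <- n_flagged + 1L
    } else {
      delta <- q * sqrt(1 - ct^2) / ct  # q * tan(theta)
    }
    t_label <- as.integer(stats::runif(1) < 0.5)
    z <- stats::rnorm(d)
    s <- 2 * t_label - 1
    a <- s * delta - sum(e * z)       # x = z + a * e
    h <- sum(w * z) + a * we
    y <- if (h > 0) 1L else if (h < 0) 0L else as.integer(stats::runif(1) < 0.5)
    if (y != t_label) {
      # w <- w + s * x  (t - y = 2t - 1 = s on a mistake)
      w <- w + s * z + (s * a) * e
      we <- sum(w * e)
      nw2 <- sum(w * w)
      correct[i] <- FALSE
    } else {
      correct[i] <- TRUE
    }
    ct <- min(max(we / sqrt(nw2), -1), 1)
    beta_tr[i] <- ct / sqrt(max(1 - ct^2, .Machine$double.eps))
  }
  list(beta = beta_tr, beta_final = beta_tr[n_trials], correct = correct,
       n_flagged = n_flagged,
       student = student_from_w(w, e))
}

#' Sweep the perceptron over a grid of clamped training error rates
#'
#' Runs `n_sims` independent training sessions at every error rate in
#' `er_grid`. Replicate sub-seeds are derived from the master seed by a
#' counter scheme and shared across error rates (a paired design: replicate
#' `j` uses the same seed in every condition, which removes
#' replicate-level variability from between-condition comparisons while
#' leaving each condition's marginal distribution untouched).
#'
#' @param er_grid Error-rate grid, subset of `(0, 0.5)`. Default: 0.01 to
#'   0.50 in steps of 0.01.
#' @param n_sims Simulations per error rate.
#' @param n_trials Trials per simulation.
#' @param d Stimulus dimension.
#' @param seed Master seed.
#' @inheritParams error_rate
#' @return A list of class `perceptron_sweep`: `summary` (tibble with
#'   per-condition mean/sd of final precision and the empirical training
#'   error rate), `mean_beta` (matrix `n_trials x length(er_grid)` of mean
#'   precision trajectories) and `final_beta` (`n_sims x length(er_grid)`).
#' @export
perceptron_sweep <- function(er_grid = seq(0.01, 0.5, by = 0.01),
                             n_sims = 100, n_trials = 1000, d = 100,
                             seed = 1, noise = gaussian_noise()) {
  stopifnot(all(er_grid > 0), all(er_grid <= 0.5), n_sims >= 1)
  er_grid[er_grid == 0.5] <- 0.4999  # clamp is defined on the open interval
  n_er <- length(er_grid)
  mean_beta <- matrix(0, n_trials, n_er)
  final_beta <- matrix(NA_real_, n_sims, n_er)
  err_count <- numeric(n_er)
  for (k in seq_len(n_er)) {
    for (j in seq_len(n_sims)) {
      set.seed(derive_seed(seed, j))
      run <- perceptron_run(er_grid[k], n_trials = n_trials, d = d,
                            noise = noise)
      mean_beta[, k] <- mean_beta[, k] + run$beta
      final_beta[j, k] <- run$beta_final
      err_count[k] <- err_count[k] + sum(!run$correct)
    }
  }
  mean_beta <- mean_beta / n_sims
  summary <- tibble::tibble(
    er_target = er_grid,
    mean_final_beta = colMeans(final_beta),
    sd_final_beta = apply(final_beta, 2, stats::sd),
    empirical_er = err_count / (n_sims * n_trials)
  )
  structure(list(summary = summary, mean_beta = mean_beta,
                 final_beta = final_beta, n_sims = n_sims,
                 n_trials = n_trials, seed = seed),
            class = "perceptron_sweep")
}
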