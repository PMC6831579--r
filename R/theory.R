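#' Error rate of a binary classifier with noisy evidence
#'
#' A decision is taken on the sign of a subjective decision variable
#' `h = Delta + n/beta`, where `Delta >= 0` is the true decision variable
#' (the objective difficulty: smaller is harder), `beta = 1/sigma` is the
#' precision of the representation, and `n` is standardized noise. The
#' probability of an error is `F(-beta * Delta)` with `F` the noise cdf.
#'
#' @param delta True decision variable, `>= 0` (vectorized).
#' @param beta Precision `1/sigma`, `> 0`.
#' @param noise A [noise_model()].
#' @return Error probability in `[0, 0.5]` for symmetric noise.
#' @examples
#' error_rate(1, 1, gaussian_noise())   # ~0.1587
#' error_rate(1, 1, cauchy_noise())     # 0.25
#' @export
error_rate <- function(delta, beta, noise = gaussian_noise()) {
  assert_noise(noise)
  if (any(beta <= 0)) stop("`beta` must be positive", call. = FALSE)
  if (any(delta < 0)) stop("`delta` must be non-negative", call. = FALSE)
  noise$cdf(-beta * delta)
}

#' Learning gradient of the error rate with respect to precision
#'
#' Differentiating `ER = F(-beta * Delta)` in `beta` gives
#' `dER/dbeta = -Delta * p(-beta * Delta)`: error rate falls as precision
#' grows. Gradient-descent learning on the error rate improves precision at
#' a rate proportional to the *magnitude* `Delta * p(-beta * Delta)`, which
#' is what training-difficulty optimization maximizes.
#'
#' @inheritParams error_rate
#' @return `learning_gradient()` returns the signed derivative
#'   `-Delta * p(-beta * Delta)` (non-positive); `gradient_magnitude()`
#'   returns its absolute value.
#' @examples
#' gradient_magnitude(1, 1, gaussian_noise())  # dnorm(1)
#' @export
learning_gradient <- function(delta, beta, noise = gaussian_noise()) {
  -gradient_magnitude(delta, beta, noise)
}

#' @rdname learning_gradient
#' @export
gradient_magnitude <- function(delta, beta, noise = gaussian_noise()) {
  assert_noise(noise)
  if (any(beta <= 0)) stop("`beta` must be positive", call. = FALSE)
  if (any(delta < 0)) stop("`delta` must be non-negative", call. = FALSE)
  delta * noise$pdf(-beta * delta)
}

# Scaled optimal difficulty u* = beta * Delta*: root of the stationarity
# condition d/du [u p(-u)] = p(-u) - u p'(-u) = 0, with a golden-section
# fallback when the derivative-based bracket fails (e.g. a custom model
# with a kinked density).
optimal_scaled_difficulty <- function(noise) {
  assert_noise(noise)
  g <- function(u) noise$pdf(-u) - u * noise$dpdf(-u)
  lo <- 1e-6; hi <- 50
  glo <- g(lo); ghi <- g(hi)
  if (is.finite(glo) && is.finite(ghi) && glo * ghi < 0) {
    r <- stats::uniroot(g, c(lo, hi), tol = 1e-12)
    return(r$root)
  }
  # fallback: maximize u * p(-u) directly
  opt <- stats::optimize(function(u) u * noise$pdf(-u), c(lo, hi),
                         maximum = TRUE, tol = 1e-12)
  if (!is.finite(opt$maximum) || opt$maximum <= lo * 2 ||
      opt$maximum >= hi * 0.99) {
    stop(sprintf(
      "optimal difficulty search failed for noise model '%s': g(%g)=%g, g(%g)=%g",
      noise$name, lo, glo, hi, ghi), call. = FALSE)
  }
  opt$maximum
}

#' Optimal training difficulty
#'
#' The difficulty `Delta*` that maximizes the learning-gradient magnitude
#' `Delta * p(-beta * Delta)` at precision `beta`. The product
#' `beta * Delta*` depends only on the noise model (it solves
#' `u = p(-u)/p'(-u)`), so the optimal difficulty scales as `1/beta`:
#' training must get objectively harder as the learner improves. For
#' Gaussian noise `Delta* = 1/beta` exactly.
#'
#' @inheritParams error_rate
#' @return Optimal difficulty `Delta*` (scalar).
#' @examples
#' optimal_difficulty(2, gaussian_noise())  # 0.5
#' @export
optimal_difficulty <- function(beta, noise = gaussian_noise()) {
  if (length(beta) != 1 || beta <= 0) {
    stop("`beta` must be a single positive number", call. = FALSE)
  }
  optimal_scaled_difficulty(noise) / beta
}

#' Optimal training error rate
#'
#' The error rate induced by training at the optimal difficulty,
#' `ER* = F(-beta * Delta*)`. Because `beta * Delta*` is a constant of the
#' noise model, `ER*` is independent of the learner's precision: optimal
#' learning is achieved by clamping the training error rate at `ER*`
#' throughout training. For Gaussian noise `ER* ~= 0.1587` (accuracy ~85%),
#' for Laplace noise `ER* = exp(-1)/2 ~= 0.1839`, for Cauchy noise
#' `ER* = 0.25`.
#'
#' @inheritParams error_rate
#' @return Optimal training error rate in `(0, 0.5)`.
#' @examples
#' optimal_error_rate(gaussian_noise())
#' @export
optimal_error_rate <- function(noise = gaussian_noise()) {
  assert_noise(noise)
  noise$cdf(-optimal_scaled_difficulty(noise))
}

#' Learning-rate constant of error-clamped training
#'
#' When the training error rate is clamped at `er_f`, precision grows as
#' `beta(t) = sqrt(beta0^2 + 2 * eta * K_f * (t - t0))` with
#' `K_f = -F^{-1}(er_f) * p(F^{-1}(er_f))`. `K_f` is maximized at the
#' optimal training error rate, where it equals `p(-u*)`.
#'
#' @param er_f Clamped training error rate, in `(0, 0.5]`.
#' @inheritParams error_rate
#' @return `K_f >= 0` (vectorized over `er_f`).
#' @examples
#' k_f(optimal_error_rate(), gaussian_noise())  # dnorm(1)
#' @export
k_f <- function(er_f, noise = gaussian_noise()) {
  assert_noise(noise)
  if (any(er_f <= 0 | er_f > 0.5)) {
    stop("`er_f` must lie in (0, 0.5]", call. = FALSE)
  }
  q <- noise$icdf(er_f)
  -q * noise$pdf(q)
}

#' Training schedules for learning-dynamics analysis
#'
#' A schedule fixes either the training error rate (`mode =
#' "fixed_error_rate"`, difficulty is adjusted online so the error rate
#' stays at `er_f`) or the objective difficulty (`mode =
#' "fixed_difficulty"`, the error rate then falls over time), together with
#' the learning rate `eta`, initial precision `beta0` and initial time
#' `t0`.
#'
#' @param mode `"fixed_error_rate"` or `"fixed_difficulty"`.
#' @param er_f Clamped error rate in `(0, 0.5)` (fixed-error-rate mode).
#' @param delta_f Fixed difficulty `> 0` (fixed-difficulty mode).
#' @param eta Learning rate `> 0`.
#' @param beta0 Initial precision `> 0`.
#' @param t0 Initial time.
#' @return An object of class `training_schedule`.
#' @export
training_schedule <- function(mode = c("fixed_error_rate", "fixed_difficulty"),
                              er_f = NULL, delta_f = NULL,
                              eta = 1, beta0 = 1, t0 = 0) {
  mode <- match.arg(mode)
  if (mode == "fixed_error_rate") {
    if (is.null(er_f) || !is.null(delta_f)) {
      stop("fixed_error_rate mode requires `er_f` and no `delta_f`",
           call. = FALSE)
    }
    stopifnot(er_f > 0, er_f < 0.5)
  } else {
    if (is.null(delta_f) || !is.null(er_f)) {
      stop("fixed_difficulty mode requires `delta_f` and no `er_f`",
           call. = FALSE)
    }
    if (delta_f <= 0) stop("`delta_f` must be positive", call. = FALSE)
  }
  stopifnot(eta > 0, beta0 > 0)
  structure(list(mode = mode, er_f = er_f, delta_f = delta_f,
                 eta = eta, beta0 = beta0, t0 = t0),
            class = "training_schedule")
}

#' @export
print.training_schedule <- function(x, ...) {
  cat("<training_schedule:", x$mode, "| ",
      if (x$mode == "fixed_error_rate") paste0("er_f=", x$er_f)
      else paste0("delta_f=", x$delta_f),
      " eta=", x$eta, " beta0=", x$beta0, " t0=", x$t0, ">\n")
  invisible(x)
}

#' Precision dynamics under clamped error rate
#'
#' Closed-form solution of `dbeta/dt = eta * K_f / beta`:
#' `beta(t) = sqrt(beta0^2 + 2 * eta * K_f * (t - t0))`. Precision grows as
#' the square root of training time, with rate set by [k_f()].
#'
#' @param t Time point(s), `>= t0`.
#' @param schedule A [training_schedule()] with `mode = "fixed_error_rate"`.
#' @inheritParams error_rate
#' @return `beta(t)`, vectorized over `t`.
#' @export
beta_fixed_error_rate <- function(t, schedule, noise = gaussian_noise()) {
  stopifnot(inherits(schedule, "training_schedule"))
  if (schedule$mode != "fixed_error_rate") {
    stop("schedule mode must be fixed_error_rate", call. = FALSE)
  }
  if (any(t < schedule$t0)) stop("`t` must be >= t0", call. = FALSE)
  K <- k_f(schedule$er_f, noise)
  sqrt(schedule$beta0^2 + 2 * schedule$eta * K * (t - schedule$t0))
}

# Right-hand side of dbeta/dt = eta * |dER/dbeta| for ODE integration.
# A floor on beta avoids the 1/beta singularity of the fixed-ER case.
dynamics_rhs <- function(schedule, noise) {
  if (schedule$mode == "fixed_error_rate") {
    K <- k_f(schedule$er_f, noise)
    function(t, y, parms) {
      list(schedule$eta * K / max(y[1], 1e-12))
    }
  } else {
    d <- schedule$delta_f
    function(t, y, parms) {
      list(schedule$eta * d * noise$pdf(-max(y[1], 1e-12) * d))
    }
  }
}

#' Precision dynamics by numeric ODE integration
#'
#' Integrates `dbeta/dt = -eta * dER/dbeta` with an adaptive Runge-Kutta
#' method ([deSolve::ode()], `rtol = 1e-8`). Serves as the independent
#' cross-check for the closed forms of [beta_fixed_error_rate()] and
#' [beta_fixed_difficulty()].
#'
#' @inheritParams beta_fixed_error_rate
#' @param rtol,atol Integration tolerances.
#' @return `beta(t)` at the requested times.
#' @export
beta_ode <- function(t, schedule, noise = gaussian_noise(),
                     rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(schedule, "training_schedule"))
  if (any(t < schedule$t0)) stop("`t` must be >= t0", call. = FALSE)
  times <- sort(unique(c(schedule$t0, t)))
  sol <- deSolve::ode(y = c(beta = schedule$beta0), times = times,
                      func = dynamics_rhs(schedule, noise), parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("ODE integration of the learning dynamics failed", call. = FALSE)
  }
  sol[match(t, sol[, "time"]), "beta"]
}

# E(y) = int_0^y exp(x^2) dx, the Dawson-type integral entering the
# implicit Gaussian fixed-difficulty solution.
exp_sq_integral <- function(y) sqrt(pi) / 2 * pracma::erfi(y)

#' Precision dynamics under clamped difficulty
#'
#' With the objective difficulty fixed at `delta_f` the error rate falls
#' over time and learning slows dramatically. The solution of
#' `dbeta/dt = eta * delta_f * p(-beta * delta_f)` depends on the noise
#' model:
#' \itemize{
#'   \item Gaussian: implicit closed form
#'     `E(beta*Delta/sqrt(2)) = E(beta0*Delta/sqrt(2)) +
#'      eta*Delta^2*(t - t0)/(2*sqrt(pi))` with `E(y) = int_0^y exp(x^2) dx`,
#'     solved by bracketed root-finding; asymptotically
#'     `beta = O(sqrt(log t))`, exponentially slower than error-clamped
#'     training.
#'   \item Laplace: `beta(t) = log(exp(beta0*Delta) +
#'     eta*Delta^2*(t - t0)/2) / Delta`.
#'   \item Cauchy: `beta` is the root of the cubic
#'     `Delta^2 beta^3/3 + beta = Delta^2 beta0^3/3 + beta0 +
#'      eta*Delta*(t - t0)/pi`, so `beta` grows as the cube root of `t`.
#' }
#' `method = "ode"` forces numeric integration instead (available for every
#' model and used as the independent check).
#'
#' @inheritParams beta_fixed_error_rate
#' @param schedule A [training_schedule()] with `mode = "fixed_difficulty"`.
#' @param method `"closed"` (default) or `"ode"`.
#' @return `beta(t)`, vectorized over `t`.
#' @export
beta_fixed_difficulty <- function(t, schedule, noise = gaussian_noise(),
                                  method = c("closed", "ode")) {
  stopifnot(inherits(schedule, "training_schedule"))
  method <- match.arg(method)
  if (schedule$mode != "fixed_difficulty") {
    stop("schedule mode must be fixed_difficulty", call. = FALSE)
  }
  if (any(t < schedule$t0)) stop("`t` must be >= t0", call. = FALSE)
  if (method == "ode") return(beta_ode(t, schedule, noise))
  d <- schedule$delta_f; b0 <- schedule$beta0
  eta <- schedule$eta; dt <- t - schedule$t0
  if (noise$name == "laplace") {
    return(log(exp(b0 * d) + 0.5 * eta * d^2 * dt) / d)
  }
  if (noise$name == "cauchy") {
    rhs <- d^2 * b0^3 / 3 + b0 + eta * d * dt / pi
    return(vapply(rhs, function(r) {
      f <- function(b) d^2 * b^3 / 3 + b - r
      hi <- max(b0, (3 * r / d^2)^(1 / 3), r) + 1
      stats::uniroot(f, c(0, hi), tol = 1e-12)$root
    }, numeric(1)))
  }
  if (noise$name == "gaussian") {
    rhs <- exp_sq_integral(b0 * d / sqrt(2)) + eta * d^2 * dt / (2 * sqrt(pi))
    return(vapply(rhs, function(r) {
      f <- function(y) exp_sq_integral(y) - r
      # E(y) >= y bounds the root below y = r for small r; for large r,
      # E(y) ~ exp(y^2)/(2y) puts it just above sqrt(log r) -- a tight
      # bracket keeps erfi() far from overflow
      hi <- max(min(r, 2), sqrt(log1p(r)) + 2, b0 * d / sqrt(2) + 0.1)
      y <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
      sqrt(2) * y / d
    }, numeric(1)))
  }
  # custom models: fall back to numeric integration
  beta_ode(t, schedule, noise)
}

#' Sub-square-root-log growth bound for Gaussian clamped-difficulty learning
#'
#' For `y = beta * Delta / sqrt(2) >= 1` the bound
#' `exp(y^2) <= 2 e y E(y)` (with `E(y) = int_0^y exp(x^2) dx`) implies
#' `y^2 <= log(E(y0) + eta*Delta^2*(t - t0)/(2*sqrt(pi))) + log(2 e y)`:
#' precision under clamped difficulty grows no faster than a
#' `sqrt(log t)`-proportional envelope, exponentially slower than the
#' `sqrt(t)` growth of error-clamped training.
#'
#' @inheritParams beta_fixed_difficulty
#' @param beta Observed precision at time `t` (e.g. from integration).
#' @return The bound on `y^2 = (beta * Delta)^2 / 2`; the inequality
#'   `y^2 <= bound` holds whenever `y >= 1`.
#' @export
gaussian_logtime_bound <- function(t, beta, schedule) {
  stopifnot(inherits(schedule, "training_schedule"),
            schedule$mode == "fixed_difficulty")
  d <- schedule$delta_f
  y <- beta * d / sqrt(2)
  rhs <- exp_sq_integral(schedule$beta0 * d / sqrt(2)) +
    schedule$eta * d^2 * (t - schedule$t0) / (2 * sqrt(pi))
  log(rhs) + log(2 * exp(1) * y)
}

#' Precision trajectory under a training schedule
#'
#' Evaluates `beta(t)` on a grid of times under the given schedule, using
#' the closed forms where available.
#'
#' @param times Ordered vector of times, starting at or after `t0`.
#' @inheritParams beta_fixed_error_rate
#' @return A `precision_trajectory`: a tibble with columns `time` and
#'   `beta`, carrying the schedule as an attribute.
#' @export
precision_trajectory <- function(times, schedule, noise = gaussian_noise()) {
  stopifnot(inherits(schedule, "training_schedule"))
  times <- sort(times)
  beta <- if (schedule$mode == "fixed_error_rate") {
    beta_fixed_error_rate(times, schedule, noise)
  } else {
    beta_fixed_difficulty(times, schedule, noise)
  }
  out <- tibble::tibble(time = times, beta = beta)
  attr(out, "schedule") <- schedule
  class(out) <- c("precision_trajectory", class(out))
  out
}

#' Combine reducible and irreducible precision
#'
#' When the decision variable carries endogenous noise that learning cannot
#' remove (precision `beta_eps`) in addition to representational noise that
#' it can (precision `beta_n`), the overall Gaussian precision obeys
#' `1/beta^2 = 1/beta_n^2 + 1/beta_eps^2`. Either component may be `Inf` to
#' encode the absence of that noise source. The optimal training error rate
#' is unchanged by endogenous noise (the gradient with respect to `beta_n`
#' factorizes through the gradient with respect to `beta`).
#'
#' @param beta_n Reducible (representational) precision, `> 0` or `Inf`.
#' @param beta_eps Irreducible (endogenous) precision, `> 0` or `Inf`.
#' @return Overall precision `beta <= min(beta_n, beta_eps)`.
#' @export
combined_precision <- function(beta_n, beta_eps = Inf) {
  if (any(beta_n <= 0) || any(beta_eps <= 0)) {
    stop("precisions must be positive (Inf allowed)", call. = FALSE)
  }
  inv2 <- ifelse(is.infinite(beta_n), 0, 1 / beta_n^2) +
    ifelse(is.infinite(beta_eps), 0, 1 / beta_eps^2)
  ifelse(inv2 == 0, Inf, 1 / sqrt(inv2))
}

#' Learning-rate and accuracy surfaces over skill and challenge
#'
#' Formalizes the flow/boredom/anxiety diagram: over a grid of skill
#' (precision `beta`) and challenge (`1/Delta`), computes the normalized
#' learning-gradient magnitude and the accuracy `1 - ER`. The gradient
#' surface is scaled to a maximum of 1; its ridge lies along
#' `beta * Delta = u*` (skill equals challenge for Gaussian noise), where
#' learning is fastest: high learning with high accuracy ("flow"), versus
#' low learning at high accuracy ("boredom", skill >> challenge) or low
#' accuracy ("anxiety", challenge >> skill).
#'
#' @param skill_grid Vector of precisions `beta > 0`.
#' @param challenge_grid Vector of challenges `1/Delta > 0`.
#' @inheritParams error_rate
#' @return A list of class `flow_surface` with `skill`, `challenge`,
#'   `learning` (matrix, skill x challenge, max 1) and `accuracy`.
#' @export
flow_surfaces <- function(skill_grid, challenge_grid,
                          noise = gaussian_noise()) {
  stopifnot(all(skill_grid > 0), all(challenge_grid > 0))
  delta <- 1 / challenge_grid
  grad <- outer(skill_grid, delta,
                function(b, d) gradient_magnitude(d, b, noise))
  acc <- outer(skill_grid, delta,
               function(b, d) 1 - error_rate(d, b, noise))
  structure(list(skill = skill_grid, challenge = challenge_grid,
                 learning = grad / max(grad), accuracy = acc),
            class = "flow_surface")
}

#' Optimal error rates and accuracies for the built-in noise models
#'
#' @return A tibble with one row per noise model: the optimal training
#'   error rate `er_star`, optimal training accuracy `acc_star`
#'   (proportion) and the accuracy rounded to the nearest whole percent
#'   `acc_pct`.
#' @examples
#' theory_table()
#' @export
theory_table <- function() {
  noises <- c("gaussian", "laplace", "cauchy")
  er <- vapply(noises, function(n) optimal_error_rate(noise_model(n)),
               numeric(1))
  tibble::tibble(noise = noises,
                 er_star = unname(er),
                 acc_star = 1 - unname(er),
                 acc_pct = round(100 * (1 - unname(er))))
}
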