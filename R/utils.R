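#' Derive a reproducible sub-seed from a master seed
#'
#' Sweeps derive one sub-seed per replicate from a single master seed with a
#' counter-based linear-congruential mix, so that any individual run can be
#' reproduced without re-running the whole sweep. Values stay within the
#' 32-bit signed integer range accepted by [set.seed()].
#'
#' @param master Master seed (integer).
#' @param counter Replicate counter (non-negative integer, may be a vector).
#' @return Integer seed(s) in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, counter) {
  stopifnot(is.numeric(master), length(master) == 1, is.numeric(counter))
  m <- 2147483647  # 2^31 - 1 (Mersenne prime)
  s <- (as.numeric(master) %% m) + 1
  # two mixing rounds keep nearby (master, counter) pairs decorrelated
  v <- (s * 48271 + as.numeric(counter) * 16807 + 12345) %% m
  as.integer((v * 69621 + 7) %% m)
}

#' Intercept-free logistic slope estimator
#'
#' Fits `P(y = 1 | x) = 1 / (1 + exp(-b * x))` by Newton-Raphson maximum
#' likelihood. This one-parameter fit is the workhorse behind the online
#' reward-prediction slope of the perceptual-learning model and the
#' psychometric precision estimate, where a full [stats::glm()] call per
#' trial would be needlessly slow; the two agree to optimizer tolerance
#' (checked in the test suite).
#'
#' @param x Covariate vector (e.g. `|h|` or coherence), non-negative in the
#'   intended uses.
#' @param y 0/1 response vector.
#' @param lower,upper Clipping bounds for the returned slope.
#' @param start Starting value.
#' @param max_iter,tol Newton iteration controls.
#' @return The fitted slope, clipped to `[lower, upper]`, with attribute
#'   `converged` (logical) and `degenerate` (TRUE when the likelihood is
#'   unbounded, e.g. all responses identical with positive covariates).
#' @export
logit_slope <- function(x, y, lower = -Inf, upper = 1e3, start = 0,
                        max_iter = 50, tol = 1e-10) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  degenerate <- FALSE
  if (length(x) == 0 || all(x == 0)) {
    b <- 0
    degenerate <- TRUE
  } else if (all(y == y[1]) && all(x >= 0)) {
    # unbounded likelihood: saturate at the relevant clip
    b <- if (y[1] == 1) upper else lower
    if (!is.finite(b)) b <- if (y[1] == 1) 1e3 else -1e3
    degenerate <- TRUE
  } else {
    b <- start
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      p <- 1 / (1 + exp(-b * x))
      score <- sum(x * (y - p))
      info <- sum(x^2 * p * (1 - p))
      if (info < .Machine$double.eps) break
      step <- score / info
      # damp large steps to keep the iteration stable
      step <- sign(step) * min(abs(step), 10)
      b <- b + step
      if (abs(step) < tol) { converged <- TRUE; break }
    }
    b_out <- min(max(b, lower), upper)
    out <- structure(b_out, converged = converged, degenerate = FALSE)
    return(out)
  }
  structure(min(max(b, lower), upper), converged = TRUE,
            degenerate = degenerate)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)
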