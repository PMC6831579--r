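# Shared fixtures and independent oracles for the test suite.

# Brute-force grid maximization of the learning-gradient magnitude over
# the scaled difficulty u = beta * Delta: the independent oracle for the
# optimal error rate (never calls optimal_difficulty()).
brute_force_optimal_er <- function(noise, n_grid = 1e5, u_max = 10) {
  u <- seq(u_max / n_grid, u_max, length.out = n_grid)
  g <- u * noise$pdf(-u)
  noise$cdf(-u[which.max(g)])
}

# One teacher-rated synthetic dataset, built once per test session and
# shared by the two-layer tests (teacher training is the expensive step).
.fixture_env <- new.env(parent = emptyenv())
shared_rated <- function() {
  if (is.null(.fixture_env$rated)) {
    withr::with_seed(4242, {
      ds <- generate_synthetic_images(n = 3000)
      .fixture_env$rated <- train_teacher(ds, "A")
    })
  }
  .fixture_env$rated
}

# Monte-Carlo error rate of a fixed (not learning) student at angle theta
# classifying trials of difficulty delta.
mc_error_rate <- function(theta, delta, d = 100, n = 2e4) {
  teacher <- teacher_weights(d)
  e <- teacher$e
  g <- stats::rnorm(d)
  g <- g - sum(g * e) * e
  g <- g / sqrt(sum(g^2))
  w <- cos(theta) * e + sin(theta) * g
  errs <- 0L
  for (i in seq_len(n)) {
    tr <- make_trial(teacher, delta)
    h <- sum(w * tr$x)
    y <- if (h > 0) 1L else if (h < 0) 0L else 1L
    errs <- errs + as.integer(y != tr$t_label)
  }
  errs / n
}
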