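test_that("error rate is the noise cdf at minus the scaled difficulty", {
  expect_equal(error_rate(0, 1), 0.5)
  expect_equal(round(error_rate(1, 1), 4), 0.1587)
  expect_equal(error_rate(1, 1, cauchy_noise()), 0.25)
  # decreasing in both difficulty and precision
  d <- seq(0, 5, by = 0.25)
  expect_true(all(diff(error_rate(d, 1)) < 0))
  b <- seq(0.5, 5, by = 0.25)
  expect_true(all(diff(error_rate(1, b, laplace_noise())) < 0))
  expect_error(error_rate(1, 0), "positive")
  expect_error(error_rate(-1, 1), "non-negative")
})

test_that("learning gradient: sign, magnitude, and optimum location", {
  expect_equal(gradient_magnitude(0, 2), 0)
  expect_equal(gradient_magnitude(1, 1), dnorm(1))
  expect_equal(learning_gradient(1, 1), -dnorm(1))
  # the optimum over difficulty at unit precision is Delta* = 1 (Gaussian)
  opt <- optimize(function(d) gradient_magnitude(d, 1), c(1e-4, 10),
                  maximum = TRUE, tol = 1e-10)
  expect_equal(opt$maximum, 1, tolerance = 1e-6)
})

test_that("optimal difficulty scales as 1/beta with noise-specific constant", {
  expect_equal(optimal_difficulty(2, gaussian_noise()), 0.5,
               tolerance = 1e-8)
  expect_equal(optimal_difficulty(1, laplace_noise()), 1, tolerance = 1e-8)
  expect_equal(optimal_difficulty(4, cauchy_noise()), 0.25,
               tolerance = 1e-6)
  # beta * Delta* is constant in beta for every model
  for (nm in list(gaussian_noise(), laplace_noise(), cauchy_noise())) {
    u <- vapply(c(0.5, 1, 5), function(b) b * optimal_difficulty(b, nm),
                numeric(1))
    expect_lt(max(u) - min(u), 1e-8)
  }
})

test_that("optimal error rates match closed forms and brute-force search", {
  expect_equal(round(optimal_error_rate(gaussian_noise()), 4), 0.1587)
  expect_equal(round(optimal_error_rate(laplace_noise()), 4), 0.1839)
  expect_equal(optimal_error_rate(cauchy_noise()), 0.25, tolerance = 1e-8)
  expect_equal(optimal_error_rate(laplace_noise()), exp(-1) / 2,
               tolerance = 1e-8)
  for (nm in list(gaussian_noise(), laplace_noise(), cauchy_noise())) {
    expect_equal(optimal_error_rate(nm), brute_force_optimal_er(nm),
                 tolerance = 1e-4, info = nm$name)
  }
})

test_that("K_f is the clamped-training rate constant, maximal at ER*", {
  expect_equal(k_f(0.5, gaussian_noise()), 0)
  expect_equal(k_f(optimal_error_rate(gaussian_noise()), gaussian_noise()),
               dnorm(1), tolerance = 1e-8)
  # direct evaluation for the Laplace model at a non-optimal rate
  q <- log(2 * 0.1587)
  expect_equal(k_f(0.1587, laplace_noise()), -q * 0.5 * exp(q),
               tolerance = 1e-12)
  expect_lt(k_f(0.1587, laplace_noise()),
            k_f(optimal_error_rate(laplace_noise()), laplace_noise()))
  expect_error(k_f(0.6), "0.5")
  # unimodality with maximum at the optimal error rate
  for (nm in list(gaussian_noise(), laplace_noise(), cauchy_noise())) {
    er <- seq(0.0001, 0.4999, length.out = 1e4)
    kv <- k_f(er, nm)
    peak <- which.max(kv)
    expect_equal(er[peak], optimal_error_rate(nm), tolerance = 1e-3,
                 info = nm$name)
    expect_true(all(diff(kv[seq_len(peak)]) > 0), info = nm$name)
    expect_true(all(diff(kv[peak:length(kv)]) < 0), info = nm$name)
  }
})

test_that("training_schedule enforces exactly one clamped quantity", {
  expect_error(training_schedule("fixed_error_rate"), "er_f")
  expect_error(training_schedule("fixed_error_rate", er_f = 0.1,
                                 delta_f = 1), "er_f")
  expect_error(training_schedule("fixed_difficulty", delta_f = -1),
               "positive")
  s <- training_schedule("fixed_difficulty", delta_f = 2, beta0 = 0.5)
  expect_s3_class(s, "training_schedule")
})

test_that("error-clamped precision grows as sqrt(time)", {
  s <- training_schedule("fixed_error_rate",
                         er_f = optimal_error_rate(gaussian_noise()),
                         eta = 1, beta0 = 1)
  expect_equal(beta_fixed_error_rate(0, s), 1)
  expect_equal(beta_fixed_error_rate(1, s), sqrt(1 + 2 * dnorm(1)),
               tolerance = 1e-10)
  # doubling elapsed time exactly doubles beta^2 - beta0^2
  b1 <- beta_fixed_error_rate(7, s)
  b2 <- beta_fixed_error_rate(14, s)
  expect_equal((b2^2 - 1) / (b1^2 - 1), 2, tolerance = 1e-12)
  expect_error(beta_fixed_error_rate(-1, s), "t0")
  # agrees with independent numeric integration
  tt <- c(0.5, 5, 50, 500)
  expect_equal(beta_ode(tt, s), beta_fixed_error_rate(tt, s),
               tolerance = 1e-6)
})

test_that("difficulty-clamped closed forms agree with ODE integration", {
  tt <- c(0, 1, 10, 100, 1000)
  for (nm in list(gaussian_noise(), laplace_noise(), cauchy_noise())) {
    s <- training_schedule("fixed_difficulty", delta_f = 1.3, eta = 0.7,
                           beta0 = 0.8)
    closed <- beta_fixed_difficulty(tt, s, nm)
    ode <- beta_fixed_difficulty(tt, s, nm, method = "ode")
    expect_equal(closed[1], 0.8, info = nm$name)
    expect_equal(closed, ode, tolerance = 1e-5, info = nm$name)
    expect_true(all(diff(closed) > 0), info = nm$name)
  }
  # Laplace closed form, evaluated directly
  s <- training_schedule("fixed_difficulty", delta_f = 1, eta = 1,
                         beta0 = 1)
  expect_equal(beta_fixed_difficulty(10, s, laplace_noise()),
               log(exp(1) + 0.5 * 10), tolerance = 1e-10)
})

test_that("Cauchy difficulty-clamped precision grows as the cube root of time", {
  s <- training_schedule("fixed_difficulty", delta_f = 1, eta = 1,
                         beta0 = 1)
  tt <- 10^seq(4, 6, length.out = 25)
  bb <- beta_fixed_difficulty(tt, s, cauchy_noise())
  slope <- coef(lm(log(bb) ~ log(tt)))[[2]]
  expect_equal(slope, 1 / 3, tolerance = 0.02)
})

test_that("error-clamped training eventually dominates difficulty-clamped", {
  # same learning rate and start; difficulty fixed at the initially
  # optimal value
  b0 <- 1
  s_er <- training_schedule("fixed_error_rate",
                            er_f = optimal_error_rate(gaussian_noise()),
                            eta = 0.5, beta0 = b0)
  s_df <- training_schedule("fixed_difficulty",
                            delta_f = optimal_difficulty(b0,
                                                         gaussian_noise()),
                            eta = 0.5, beta0 = b0)
  tt <- 10^seq(0, 5, length.out = 30)
  b_er <- beta_fixed_error_rate(tt, s_er)
  b_df <- beta_fixed_difficulty(tt, s_df)
  gap <- b_er - b_df
  crossed <- which(gap > 0)
  expect_gt(length(crossed), 0)
  # once ahead, stays ahead
  expect_true(all(gap[min(crossed):length(gap)] > 0))
  # and the gap widens without bound on this horizon
  expect_gt(gap[length(gap)], 10 * gap[min(crossed)])
})

test_that("combined precision follows the inverse-square law", {
  expect_equal(combined_precision(2, Inf), 2)
  expect_equal(combined_precision(1, 1), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(combined_precision(Inf, 3), 3)
  b <- combined_precision(1.7, 2.2)
  expect_equal(1 / b^2, 1 / 1.7^2 + 1 / 2.2^2, tolerance = 1e-12)
  expect_lte(b, min(1.7, 2.2))
  expect_error(combined_precision(-1, 1), "positive")
})

test_that("endogenous noise leaves the optimal training error rate unchanged", {
  er_star <- optimal_error_rate(gaussian_noise())
  for (beta_eps in c(2, 5, Inf)) {
    beta_n <- 1
    beta <- combined_precision(beta_n, beta_eps)
    # optimizing over difficulty at the combined precision: the induced
    # training error rate at the optimum is ER* regardless of beta_eps
    opt <- optimize(function(d) gradient_magnitude(d, beta, gaussian_noise()),
                    c(1e-4, 20), maximum = TRUE, tol = 1e-10)
    expect_equal(error_rate(opt$maximum, beta), er_star, tolerance = 1e-6)
  }
})

test_that("precision trajectories start at beta0 and never decrease", {
  tt <- seq(0, 200, by = 5)
  s1 <- training_schedule("fixed_error_rate", er_f = 0.2, beta0 = 0.3)
  s2 <- training_schedule("fixed_difficulty", delta_f = 0.5, beta0 = 0.3)
  for (s in list(s1, s2)) {
    tr <- precision_trajectory(tt, s, laplace_noise())
    expect_equal(tr$beta[1], 0.3)
    expect_true(all(diff(tr$beta) >= 0))
  }
})

test_that("flow surfaces: normalized ridge along matched skill and challenge", {
  skill <- seq(0.5, 4, length.out = 30)
  challenge <- seq(0.5, 4, length.out = 35)
  fs <- flow_surfaces(skill, challenge)
  expect_equal(max(fs$learning), 1)
  # as challenge -> infinity (difficulty -> 0) accuracy -> 0.5 at all skill
  fs2 <- flow_surfaces(skill, c(1e6, 1e7))
  expect_true(all(abs(fs2$accuracy - 0.5) < 1e-4))
  # Gaussian ridge: for each skill row the gradient is maximal where
  # challenge = skill (beta * Delta = 1)
  for (i in c(5, 15, 25)) {
    j_star <- which.max(fs$learning[i, ])
    expect_equal(challenge[j_star], skill[i], tolerance = 0.15)
  }
})

test_that("theory table lists all built-in models with exact optima", {
  tt <- theory_table()
  expect_equal(tt$noise, c("gaussian", "laplace", "cauchy"))
  expect_equal(tt$acc_star, 1 - tt$er_star)
  expect_equal(tt$er_star[3], 0.25, tolerance = 1e-8)
})
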