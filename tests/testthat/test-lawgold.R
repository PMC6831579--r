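test_that("MT population parameters stay inside the sampling ranges", {
  set.seed(20)
  pop <- sample_mt_population(7200)
  expect_true(all(pop$theta_pref >= -180 & pop$theta_pref <= 180))
  expect_true(all(pop$k0 >= 0 & pop$k0 <= 20))
  expect_true(all(pop$kp >= 0 & pop$kp <= 50))
  expect_true(all(pop$kn >= -pop$k0 & pop$kn <= 0))
  expect_true(all(pop$fano >= 1 & pop$fano <= 5))
  expect_lt(abs(mean(pop$kp) - 25), 1)
  # preferred directions cover both task hemifields
  pop2 <- sample_mt_population(720)
  near <- function(dir) mean(abs(traindiff:::angle_diff(dir,
                                                        pop2$theta_pref)) < 90)
  expect_gt(near(90), 0.4)
  expect_gt(near(-90), 0.4)
})

test_that("mean MT rates follow the coherence-scaled tuning curve", {
  pop <- structure(list(theta_pref = c(90, 60, -90), k0 = c(10, 5, 8),
                        kp = c(40, 30, 20), kn = c(-5, -2, -8),
                        fano = c(2, 2, 2), sigma_theta = 30, n = 3),
                   class = "mt_population")
  # zero coherence collapses to the baseline response
  m0 <- mt_mean_rate(pop, stimulus_spec(90, 1e-12))
  expect_equal(m0, pop$k0, tolerance = 1e-9)
  # at the preferred direction the tuning factor is 1
  m1 <- mt_mean_rate(pop, stimulus_spec(90, 0.5))
  expect_equal(m1[1], 10 + 0.5 * 40)
  # 30 degrees off preferred: tuning factor exp(-1/2)
  f <- (m1[2] - 5 - 0.5 * (-2)) / (0.5 * (30 - (-2)))
  expect_equal(f, exp(-1 / 2), tolerance = 1e-12)
  # rates never go negative under the parameter constraints
  set.seed(21)
  big <- sample_mt_population(1e5)
  for (coh in c(0.01, 0.5, 1)) {
    expect_true(all(mt_mean_rate(big, stimulus_spec(-90, coh)) >= 0))
  }
})

test_that("MT activity is rectified with Fano-scaled variance", {
  set.seed(22)
  pop <- structure(list(theta_pref = 90, k0 = 10, kp = 40, kn = -5,
                        fano = 3, sigma_theta = 30, n = 1),
                   class = "mt_population")
  stim <- stimulus_spec(90, 0.4)
  m <- mt_mean_rate(pop, stim)
  draws <- replicate(1e5, mt_activity(pop, stim))
  expect_true(all(draws >= 0))
  # rectification barely bites here, so the sample variance ~ fano * m
  expect_lt(abs(var(draws) - 3 * m) / (3 * m), 0.05)
  # zero mean rate gives identically zero activity
  pop0 <- structure(list(theta_pref = 90, k0 = 0, kp = 0, kn = 0,
                         fano = 2, sigma_theta = 30, n = 1),
                    class = "mt_population")
  expect_true(all(replicate(100, mt_activity(pop0, stim)) == 0))
})

test_that("LIP decisions follow the sign of the weighted MT activity", {
  set.seed(23)
  pop <- sample_mt_population(720)
  ro <- readout_state(720, eps_sigma = 0)
  x <- mt_activity(pop, stimulus_spec(90, 0.5))
  dec <- lip_decide(ro, x)
  expect_equal(dec$C, if (dec$h > 0) 1L else -1L)
  # sign equivariance
  ro_neg <- ro; ro_neg$w <- -ro$w
  expect_equal(lip_decide(ro_neg, x)$h, -dec$h, tolerance = 1e-12)
  # readout aligned with the direction contrast is highly accurate
  m_diff <- mt_mean_rate(pop, stimulus_spec(90, 0.9)) -
    mt_mean_rate(pop, stimulus_spec(-90, 0.9))
  ro$w <- m_diff * sqrt(0.02 / sum(m_diff^2))
  correct <- replicate(1000, {
    dir <- if (runif(1) < 0.5) 90 else -90
    x <- mt_activity(pop, stimulus_spec(dir, 0.9))
    lip_decide(ro, x)$C == sign(dir)
  })
  expect_gt(mean(correct), 0.9)
})

test_that("predicted reward is a confidence-calibrated logistic", {
  expect_equal(predicted_reward(0, 5), 0.5)
  expect_equal(predicted_reward(3, 0), 0.5)
  h <- seq(0, 5, by = 0.5)
  expect_true(all(diff(predicted_reward(h, 2)) > 0))
  expect_true(all(predicted_reward(-h, 2) == predicted_reward(h, 2)))
})

test_that("the reward-prediction slope estimator recovers planted values", {
  set.seed(24)
  h <- abs(rnorm(1e4))
  y <- as.numeric(runif(1e4) < 1 / (1 + exp(-5 * h)))
  expect_lt(abs(estimate_B(h, y) - 5), 0.5)
  # agrees with the glm maximum-likelihood fit
  g <- suppressWarnings(glm(y ~ h - 1, family = binomial))
  expect_equal(estimate_B(h, y), unname(coef(g)), tolerance = 1e-6)
  # correctness unrelated to |h|: slope near zero
  y0 <- as.numeric(runif(1e4) < 0.5)
  expect_lt(abs(estimate_B(h, y0)), 0.2)
  # degenerate single-trial history stays finite and non-negative
  b1 <- estimate_B(1.3, 1)
  expect_true(is.finite(b1) && b1 >= 0)
  # empty history falls back to the previous estimate
  expect_equal(estimate_B(numeric(0), numeric(0), B_prev = 2.5), 2.5)
})

test_that("weight updates preserve the squared-norm constraint", {
  set.seed(25)
  ro <- readout_state(300)
  expect_equal(sum(ro$w^2), 0.02, tolerance = 1e-12)
  worst <- 0
  for (i in 1:1e4) {
    x <- abs(rnorm(300, 10, 5))
    C <- sample(c(-1L, 1L), 1)
    r <- rbinom(1, 1, 0.7)
    ro <- update_weights(ro, x, C, r, E_r = 0.6)
    worst <- max(worst, abs(sum(ro$w^2) - 0.02))
  }
  expect_lt(worst, 1e-10)
  # zero prediction error only rescales: direction unchanged
  ro2 <- readout_state(50)
  ro3 <- update_weights(ro2, abs(rnorm(50)), 1L, 1, E_r = 1)
  expect_equal(ro3$w, ro2$w, tolerance = 1e-12)
  # the pre-normalization update follows eta * C * delta * x
  ro4 <- readout_state(50, eta = 1e-3)
  x4 <- abs(rnorm(50))
  ro5 <- update_weights(ro4, x4, 1L, 1, E_r = 0.6)
  raw <- ro4$w + 1e-3 * 1 * 0.4 * x4
  expect_equal(ro5$w, raw * sqrt(0.02 / sum(raw^2)), tolerance = 1e-12)
})

test_that("coherence staircase: fixed initialization then logit tracking", {
  st <- coherence_staircase(A_target = 0.83)
  # during initialization the coherence stays at 0.9
  for (t in 1:49) st <- staircase_coherence(st, TRUE, t)
  expect_equal(st$coh, 0.9)
  # gamma = 0 maps to coherence 0.5
  st$gamma <- 0
  st2 <- st; st2$flags <- rep(c(TRUE, FALSE), 50)  # A_L = 0.5 after update
  out <- staircase_coherence(st2, TRUE, 60)
  expect_equal(out$coh, 1 / (1 + exp(-out$gamma)))
  # accuracy at target: gamma unchanged
  st3 <- coherence_staircase(A_target = 0.8)
  st3$flags <- c(rep(TRUE, 79), FALSE)  # becomes 80/100 after next update
  g0 <- st3$gamma
  out3 <- staircase_coherence(st3, FALSE, 99)
  expect_equal(out3$gamma, g0 + 0.1 * (0.8 - mean(out3$flags)))
})

test_that("training holds accuracy near target and yields a psychometric fit", {
  set.seed(26)
  ers <- vapply(1:5, function(i) {
    run_lawgold_training(0.83, n_trials = 3000)$empirical_er
  }, numeric(1))
  expect_lt(median(abs((1 - ers) - 0.83)), 0.05)
})

test_that("psychometric precision estimation is calibrated and stable", {
  set.seed(27)
  coh <- rep(10^seq(-3, 0, length.out = 20), each = 100)
  fits <- replicate(5, {
    y <- as.numeric(runif(length(coh)) < 1 / (1 + exp(-8 * coh)))
    as.numeric(logit_slope(coh, y, lower = 0))
  })
  expect_lt(abs(mean(fits) - 8), 1)
  # chance-level accuracy at every coherence: slope pinned near zero
  y0 <- as.numeric(runif(length(coh)) < 0.5)
  expect_lt(as.numeric(logit_slope(coh, y0, lower = 0)), 0.5)
  # doubling the repetition count moves the estimate by < 10%
  set.seed(28)
  pop <- sample_mt_population(720)
  m_diff <- mt_mean_rate(pop, stimulus_spec(90, 0.5)) -
    mt_mean_rate(pop, stimulus_spec(-90, 0.5))
  ro <- readout_state(720)
  ro$w <- m_diff * sqrt(0.02 / sum(m_diff^2))
  b100 <- as.numeric(fit_psychometric(ro, pop, n_rep = 100))
  b200 <- as.numeric(fit_psychometric(ro, pop, n_rep = 200))
  expect_lt(abs(b200 - b100) / b100, 0.1)
})

test_that("trained accuracy rises with coherence up to Monte-Carlo error", {
  set.seed(29)
  res <- run_lawgold_training(0.84, n_trials = 3000)
  tab <- res$accuracy_table
  se_pair <- sqrt(tab$accuracy * (1 - tab$accuracy) / 100 + 1e-6)
  strict_viol <- sum(diff(tab$accuracy) < -2 * (se_pair[-1] + se_pair[-20]))
  expect_lte(strict_viol, 2)
  expect_gt(tail(tab$accuracy, 1), 0.95)
})

test_that("endogenous decision noise does not move the optimal target bin", {
  grid <- c(0.11, 0.16, 0.21, 0.26, 0.31)
  sw0 <- lawgold_sweep(er_grid = grid, n_runs = 6, n_trials = 1500,
                       eps_sigma = 0, seed = 30)
  sw1 <- lawgold_sweep(er_grid = grid, n_runs = 6, n_trials = 1500,
                       eps_sigma = 0.5, seed = 30)
  m0 <- tapply(sw0$beta, sw0$er_target, mean)
  m1 <- tapply(sw1$beta, sw1$er_target, mean)
  expect_lte(abs(which.max(m0) - which.max(m1)), 1)
})
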