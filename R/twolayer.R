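#' Two-layer sigmoidal classifier
#'
#' A network with `n_input` inputs, one hidden layer of `n_hidden`
#' logistic units and a single logistic output:
#' `a = S(w1 x)`, `h = w2 . a`, `y = S(h)` with
#' `S(z) = 1/(1 + exp(-z))`. The predicted label is `1[y > 0.5]`, i.e. the
#' sign of the decision variable `h`, matching the perceptron convention.
#' Weights are initialized from a standard normal; `scale_by_fanin = TRUE`
#' optionally rescales each layer by `1/sqrt(fan-in)`.
#'
#' @param n_input,n_hidden Layer sizes (defaults 400 and 50).
#' @param lr Backpropagation learning rate (default 0.1).
#' @param scale_by_fanin Rescale initial weights by `1/sqrt(fan-in)`.
#' @return A list of class `twolayer_params` with `w1`
#'   (`n_hidden x n_input`), `w2` (`n_hidden`) and `lr`.
#' @export
twolayer_params <- function(n_input = 400, n_hidden = 50, lr = 0.1,
                            scale_by_fanin = FALSE) {
  stopifnot(n_input >= 1, n_hidden >= 1, lr > 0)
  w1 <- matrix(stats::rnorm(n_hidden * n_input), n_hidden, n_input)
  w2 <- stats::rnorm(n_hidden)
  if (scale_by_fanin) {
    w1 <- w1 / sqrt(n_input)
    w2 <- w2 / sqrt(n_hidden)
  }
  structure(list(w1 = w1, w2 = w2, lr = lr), class = "twolayer_params")
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass of the two-layer network
#'
#' @param x Input vector (length `n_input`).
#' @param params A [twolayer_params()].
#' @return A list with hidden activity `a`, decision variable `h`, output
#'   `y = S(h)` and the predicted `label = 1[y > 0.5]`.
#' @export
twolayer_forward <- function(x, params) {
  stopifnot(inherits(params, "twolayer_params"))
  if (length(x) != ncol(params$w1)) {
    stop(sprintf("input has length %d, expected %d",
                 length(x), ncol(params$w1)), call. = FALSE)
  }
  a <- sigmoid(drop(params$w1 %*% x))
  h <- sum(params$w2 * a)
  y <- sigmoid(h)
  list(a = a, h = h, y = y, label = as.integer(y > 0.5))
}

#' Single-example backpropagation update
#'
#' Stochastic gradient descent on the squared error `(t - y)^2 / 2` of one
#' example: the teaching signal `e = t - y` is scaled by the output
#' sigmoid's slope and propagated back through the hidden layer, and both
#' weight matrices move down the exact gradient with step `lr` (gradient
#' checked against central finite differences in the test suite).
#'
#' @param x Input vector.
#' @param t_label Target label, 0 or 1.
#' @inheritParams twolayer_forward
#' @return Updated `twolayer_params`, with attribute `y` (the pre-update
#'   output for this example).
#' @export
backprop_step <- function(x, t_label, params) {
  stopifnot(t_label %in% c(0, 1))
  fw <- twolayer_forward(x, params)
  e <- t_label - fw$y
  d_out <- e * fw$y * (1 - fw$y)
  d_hid <- d_out * params$w2 * fw$a * (1 - fw$a)
  params$w2 <- params$w2 + params$lr * d_out * fw$a
  params$w1 <- params$w1 + params$lr * tcrossprod(d_hid, x)
  attr(params, "y") <- fw$y
  params
}

# Vectorized forward pass over the rows of a stimulus matrix.
forward_batch <- function(X, params) {
  A <- sigmoid(tcrossprod(X, params$w1))  # n x n_hidden
  drop(A %*% params$w2)
}

# Minibatch backpropagation update (mean gradient over the batch) used to
# train the teacher quickly; the student always learns online, one example
# at a time.
backprop_batch <- function(X, t_labels, params) {
  A <- sigmoid(tcrossprod(X, params$w1))
  h <- drop(A %*% params$w2)
  y <- sigmoid(h)
  d_out <- (t_labels - y) * y * (1 - y)
  d_hid <- (d_out %o% params$w2) * A * (1 - A)  # n x n_hidden
  n <- nrow(X)
  params$w2 <- params$w2 + params$lr * drop(crossprod(A, d_out)) / n
  params$w1 <- params$w1 + params$lr * crossprod(d_hid, X) / n
  params
}

batch_accuracy <- function(X, labels, params) {
  mean(as.integer(forward_batch(X, params) > 0) == labels)
}

#' Synthetic image-like stimuli with graded difficulty
#'
#' Generates a synthetic stand-in for a corpus of labeled digit images:
#' `side^2`-pixel stimuli in `[0, 1]` carrying two correlated binary label
#' tracks, A and B, each defined as the sign of a latent margin projected
#' into pixel space along a task-specific pattern. The margins span a wide
#' range, so teacher-rated difficulty varies smoothly from trivially easy
#' to near-boundary -- a prerequisite for accuracy staircasing -- and are
#' generated in matched `+/-` pairs, so both labels are present in equal
#' numbers at every difficulty level (as in a real digit corpus, where
#' both classes contain easy and hard exemplars; without this symmetry an
#' accuracy staircase can settle in a label-imbalanced difficulty stratum
#' that a constant predictor satisfies). Pixel noise relative to the
#' signal scale sets the Bayes error (about 1% at the defaults); the
#' signal scale also controls how fast a network learns the task, and its
#' default is chosen so that a 5000-trial online run is still in the
#' rising part of its learning curve. The generating margins are stored
#' for validation of teacher-assigned difficulty ratings.
#'
#' @param n Number of stimuli (`>= 500`; rounded up to even).
#' @param side Image side length; stimuli are `side^2`-dimensional.
#' @param margin_spread Standard deviation of the latent task margins.
#' @param label_cor Correlation between the two tasks' latent margins.
#' @param signal_scale Pixel-space amplitude of one unit of margin.
#' @param sigma_pix Per-pixel Gaussian noise standard deviation.
#' @param train_frac Fraction of stimuli assigned to the training split.
#' @return A list of class `rated_dataset` with `stimuli` (`n x side^2`
#'   matrix), `labels` (`n x 2` matrix, columns `A`, `B`), `margins`
#'   (`n x 2`, the latent signed margins), `train`/`test` index vectors,
#'   and `difficulty = NULL` until rated by [train_teacher()].
#' @export
generate_synthetic_images <- function(n = 12000, side = 20,
                                      margin_spread = 1, label_cor = 0.5,
                                      signal_scale = 0.2,
                                      sigma_pix = 0.006,
                                      train_frac = 5 / 6) {
  stopifnot(n >= 500, side >= 4, margin_spread > 0, signal_scale > 0,
            sigma_pix >= 0, abs(label_cor) < 1)
  n <- 2 * ceiling(n / 2)
  d <- side^2
  pA <- stats::rnorm(d); pA <- pA / sqrt(sum(pA^2))
  pB <- stats::rnorm(d); pB <- pB - sum(pB * pA) * pA
  pB <- pB / sqrt(sum(pB^2))
  gA_half <- stats::rnorm(n / 2, 0, margin_spread)
  eps_half <- stats::rnorm(n / 2, 0, margin_spread)
  gA <- c(gA_half, -gA_half)  # difficulty-matched +/- pairs
  gB <- label_cor * gA + sqrt(1 - label_cor^2) * c(eps_half, -eps_half)
  base <- 0.2
  X <- base + signal_scale * (outer(gA, pA) + outer(gB, pB)) +
    matrix(stats::rnorm(n * d, 0, sigma_pix), n, d)
  X <- clip01(X)
  labels <- cbind(A = as.integer(gA > 0), B = as.integer(gB > 0))
  margins <- cbind(A = gA, B = gB)
  n_train <- round(train_frac * n)
  idx <- sample.int(n)
  structure(list(stimuli = X, labels = labels, margins = margins,
                 train = sort(idx[seq_len(n_train)]),
                 test = sort(idx[-seq_len(n_train)]),
                 difficulty = NULL, teacher = NULL, task = NULL),
            class = "rated_dataset")
}

#' Train a teacher network and rate stimulus difficulty
#'
#' Trains a network of the same architecture on the training split of one
#' task by single-example backpropagation until its training accuracy
#' reaches `stop_acc`, then rates every stimulus by the absolute teacher
#' decision variable `|h_teacher|`: large values mark easy stimuli, values
#' near zero mark stimuli close to the teacher's decision boundary.
#'
#' @param dataset A `rated_dataset` from [generate_synthetic_images()].
#' @param task `"A"` or `"B"`.
#' @param stop_acc Training-accuracy stopping threshold in `(0.9, 1)`.
#' @param lr Teacher learning rate (per-batch, mean gradient).
#' @param n_hidden Teacher hidden-layer size.
#' @param max_epochs Epoch budget before giving up.
#' @param batch_size Minibatch size for teacher training.
#' @return The dataset with `difficulty` (vector `|h_teacher|` over all
#'   stimuli), `teacher` (its `twolayer_params`) and `task` filled in.
#' @export
train_teacher <- function(dataset, task = c("A", "B"), stop_acc = 0.99,
                          lr = 2, n_hidden = 50, max_epochs = 400,
                          batch_size = 25, scale_by_fanin = TRUE) {
  stopifnot(inherits(dataset, "rated_dataset"),
            stop_acc > 0.9, stop_acc < 1)
  task <- match.arg(task)
  X <- dataset$stimuli[dataset$train, , drop = FALSE]
  lab <- dataset$labels[dataset$train, task]
  params <- twolayer_params(n_input = ncol(X), n_hidden = n_hidden, lr = lr,
                            scale_by_fanin = scale_by_fanin)
  n <- nrow(X)
  reached <- FALSE
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    for (s in starts) {
      b <- ord[s:min(s + batch_size - 1, n)]
      params <- backprop_batch(X[b, , drop = FALSE], lab[b], params)
    }
    if (batch_accuracy(X, lab, params) >= stop_acc) { reached <- TRUE; break }
  }
  if (!reached) {
    stop(sprintf(paste0(
      "teacher failed to reach training accuracy %.3f within %d epochs ",
      "(reached %.3f); consider easier synthetic parameters ",
      "(larger margin_spread or smaller sigma_pix)"),
      stop_acc, max_epochs, batch_accuracy(X, lab, params)), call. = FALSE)
  }
  dataset$difficulty <- abs(forward_batch(dataset$stimuli, params))
  dataset$teacher <- params
  dataset$task <- task
  dataset
}

#' Accuracy staircase on teacher-rated difficulty
#'
#' Holds training accuracy near a target by adjusting a target difficulty
#' `h_target` after every trial:
#' `h_target <- h_target + D * (A_target - A_av)`, where `A_av` is the
#' running mean of the correctness flags from the last `window` trials.
#' Below-target accuracy raises `h_target` (easier stimuli get selected),
#' above-target accuracy lowers it.
#'
#' @param h_target Initial target difficulty (in `|h_teacher|` units).
#' @param A_target Target training accuracy.
#' @param D Step size (default 1).
#' @param window Length of the correctness ring buffer (default 50).
#' @return A list of class `staircase_state`.
#' @export
staircase_state <- function(h_target, A_target, D = 1, window = 50) {
  stopifnot(is.finite(h_target), A_target > 0, A_target < 1, D > 0,
            window >= 1)
  structure(list(h_target = h_target, A_target = A_target, D = D,
                 window = window, flags = logical(0)),
            class = "staircase_state")
}

#' @rdname staircase_state
#' @param state A `staircase_state`.
#' @param correct Logical: was the last trial classified correctly?
#' @export
staircase_update <- function(state, correct) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct))
  flags <- c(state$flags, correct)
  if (length(flags) > state$window) {
    flags <- flags[(length(flags) - state$window + 1):length(flags)]
  }
  state$flags <- flags
  state$h_target <- state$h_target +
    state$D * (state$A_target - mean(flags))
  state
}

#' Select the eligible stimulus nearest a target difficulty
#'
#' Returns the index (into `difficulty`) of the stimulus whose rated
#' difficulty `|h_teacher|` is closest to `h_target`, among stimuli that
#' have not been presented within the last `window` trials. Ties break to
#' the lowest index.
#'
#' @param difficulty Vector of rated difficulties for the candidate pool.
#' @param h_target Current target difficulty.
#' @param last_used Vector of the trial index at which each candidate was
#'   last presented (`-Inf` if never).
#' @param trial_idx Current trial index.
#' @param window Re-use exclusion window (default 50).
#' @return The selected index.
#' @export
select_stimulus <- function(difficulty, h_target, last_used, trial_idx,
                            window = 50) {
  stopifnot(length(difficulty) == length(last_used))
  eligible <- (trial_idx - last_used) > window
  if (!any(eligible)) {
    stop("no eligible stimulus: training pool too small for the re-use window",
         call. = FALSE)
  }
  idx <- which(eligible)
  idx[which.min(abs(difficulty[idx] - h_target))]
}

#' Train a student network with accuracy-staircased stimulus selection
#'
#' Full training loop on a teacher-rated dataset: on each trial, select the
#' eligible training stimulus whose rated difficulty is nearest the current
#' target, run the forward pass, score correctness against the true label,
#' apply a backpropagation update, and adjust the target difficulty by the
#' accuracy staircase. After `n_trials` trials the student is evaluated on
#' the held-out test split. The initial target difficulty is the median
#' rated difficulty of the training pool.
#'
#' @param rated A `rated_dataset` that has been rated by [train_teacher()].
#' @param A_target Target training accuracy in `(0.5, 1)`.
#' @param n_trials Number of training trials (default 5000).
#' @param lr Student learning rate.
#' @param n_hidden Student hidden-layer size.
#' @param D,window Staircase step size and window (see [staircase_state()]).
#' @param scale_by_fanin Use fan-in-scaled initial weights (default TRUE;
#'   unscaled variance-1 initialization saturates the sigmoids and can
#'   trap the network in a constant-output state).
#' @return A list with the trained `params`, `test_accuracy`,
#'   `train_accuracy_last` (empirical accuracy over the last
#'   `min(n_trials, 1000)` trials), `correct` (per-trial flags),
#'   `h_target` (per-trial staircase trajectory) and `selected` (per-trial
#'   pool indices).
#' @export
run_twolayer_experiment <- function(rated, A_target, n_trials = 5000,
                                    lr = 0.1, n_hidden = 50, D = 1,
                                    window = 50, scale_by_fanin = TRUE) {
  stopifnot(inherits(rated, "rated_dataset"), A_target > 0.5, A_target < 1)
  if (is.null(rated$difficulty)) {
    stop("dataset has not been rated; call train_teacher() first",
         call. = FALSE)
  }
  task <- rated$task
  pool <- rated$train
  X <- rated$stimuli[pool, , drop = FALSE]
  lab <- rated$labels[pool, task]
  diff <- rated$difficulty[pool]
  params <- twolayer_params(n_input = ncol(X), n_hidden = n_hidden, lr = lr,
                            scale_by_fanin = scale_by_fanin)
  stair <- staircase_state(h_target = stats::median(diff),
                           A_target = A_target, D = D, window = window)
  last_used <- rep(-Inf, length(pool))
  correct <- logical(n_trials)
  h_hist <- numeric(n_trials)
  sel_hist <- integer(n_trials)
  # inlined hot loop over local weight copies: equivalent to composing
  # select_stimulus / backprop_step / staircase_update (see test suite)
  # but avoids per-trial copies of the parameter list
  w1 <- params$w1; w2 <- params$w2
  h_target <- stair$h_target
  n_correct_win <- 0L
  win_flags <- logical(0)
  for (tr in seq_len(n_trials)) {
    eligible <- (tr - last_used) > window
    idx <- which(eligible)
    i <- idx[which.min(abs(diff[idx] - h_target))]
    last_used[i] <- tr
    sel_hist[tr] <- i
    x <- X[i, ]
    a <- 1 / (1 + exp(-drop(w1 %*% x)))
    y <- 1 / (1 + exp(-sum(w2 * a)))
    d_out <- (lab[i] - y) * y * (1 - y)
    d_hid <- d_out * w2 * a * (1 - a)
    w2 <- w2 + lr * d_out * a
    w1 <- w1 + lr * tcrossprod(d_hid, x)
    correct[tr] <- (y > 0.5) == (lab[i] == 1)
    win_flags <- c(win_flags, correct[tr])
    if (length(win_flags) > window) win_flags <- win_flags[-1]
    h_target <- h_target + D * (A_target - mean(win_flags))
    h_hist[tr] <- h_target
  }
  params$w1 <- w1; params$w2 <- w2
  test_acc <- batch_accuracy(rated$stimuli[rated$test, , drop = FALSE],
                             rated$labels[rated$test, task], params)
  last_n <- min(n_trials, 1000)
  list(params = params,
       test_accuracy = test_acc,
       train_accuracy_last = if (n_trials > 0) {
         mean(correct[(n_trials - last_n + 1):n_trials])
       } else NA_real_,
       correct = correct, h_target = h_hist, selected = sel_hist)
}

#' Sweep the two-layer network over a grid of target training accuracies
#'
#' Repeats the grid experiment `n_reps` times (a "grid replication"): one
#' synthetic dataset and teacher rating per replication, then `n_repeats`
#' student runs per target accuracy with replicate sub-seeds shared across
#' targets (paired design; see [perceptron_sweep()]).
#'
#' @param A_grid Target training-accuracy grid (default 0.70 to 0.95 in
#'   steps of 0.05, i.e. training error 30% down to 5%).
#' @param n_reps Number of grid replications.
#' @param n_repeats Student runs per target within a replication.
#' @param n_trials Trials per run.
#' @param n_stimuli Synthetic corpus size per replication.
#' @param task Task track to train on.
#' @param seed Master seed.
#' @param ... Passed to [generate_synthetic_images()].
#' @return A tibble with one row per (replication, target, repeat):
#'   `replication`, `A_target`, `repeat_idx`, `test_accuracy`,
#'   `train_accuracy_last`.
#' @export
twolayer_sweep <- function(A_grid = seq(0.70, 0.95, by = 0.05),
                           n_reps = 1, n_repeats = 3, n_trials = 5000,
                           n_stimuli = 12000, task = "A", seed = 1, ...) {
  stopifnot(all(A_grid > 0.5), all(A_grid < 1))
  rows <- vector("list", n_reps * length(A_grid) * n_repeats)
  k <- 0
  for (rep_i in seq_len(n_reps)) {
    set.seed(derive_seed(seed, 100000 + rep_i))
    rated <- train_teacher(
      generate_synthetic_images(n = n_stimuli, ...), task = task)
    for (j in seq_len(n_repeats)) {
      for (a in A_grid) {
        set.seed(derive_seed(seed, rep_i * 1000 + j))
        res <- run_twolayer_experiment(rated, A_target = a,
                                       n_trials = n_trials)
        k <- k + 1
        rows[[k]] <- tibble::tibble(
          replication = rep_i, A_target = a, repeat_idx = j,
          test_accuracy = res$test_accuracy,
          train_accuracy_last = res$train_accuracy_last)
      }
    }
  }
  dplyr::bind_rows(rows)
}
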