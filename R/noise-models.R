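#' Standardized noise models
#'
#' A noise model describes the standardized (zero-median, unit-scale)
#' distribution of the representational noise that corrupts the decision
#' variable in a binary classification task. Every analytic result in the
#' package -- error rates, learning gradients, optimal difficulty and the
#' optimal training error rate -- is driven by the four functions bundled
#' here: the density `pdf`, its derivative `dpdf`, the cumulative
#' distribution `cdf`, and the quantile function `icdf`.
#'
#' Built-in models:
#' \describe{
#'   \item{gaussian}{standard normal, `p(x) = exp(-x^2/2)/sqrt(2*pi)`}
#'   \item{laplace}{double exponential, `p(x) = exp(-|x|)/2`}
#'   \item{cauchy}{standard Cauchy, `p(x) = 1/(pi*(1+x^2))`}
#' }
#' All three use closed-form quantile functions so that downstream
#' quantities such as [k_f()] are exact to machine precision.
#'
#' @param name Model name, one of `"gaussian"`, `"laplace"`, `"cauchy"`.
#' @param pdf,dpdf,cdf,icdf Vectorized functions defining a custom model.
#'
#' @return An object of class `noise_model`: a list with elements `name`,
#'   `pdf`, `dpdf`, `cdf` and `icdf`.
#' @examples
#' g <- gaussian_noise()
#' g$cdf(-1)            # error rate at unit scaled difficulty
#' noise_model("cauchy")$icdf(0.25)
#' @export
noise_model <- function(name = c("gaussian", "laplace", "cauchy")) {
  name <- match.arg(name)
  switch(name,
    gaussian = gaussian_noise(),
    laplace  = laplace_noise(),
    cauchy   = cauchy_noise()
  )
}

#' @rdname noise_model
#' @export
new_noise_model <- function(name, pdf, dpdf, cdf, icdf) {
  stopifnot(is.character(name), length(name) == 1,
            is.function(pdf), is.function(dpdf),
            is.function(cdf), is.function(icdf))
  structure(list(name = name, pdf = pdf, dpdf = dpdf, cdf = cdf, icdf = icdf),
            class = "noise_model")
}

#' @rdname noise_model
#' @export
gaussian_noise <- function() {
  new_noise_model(
    "gaussian",
    pdf  = stats::dnorm,
    dpdf = function(x) -x * stats::dnorm(x),
    cdf  = stats::pnorm,
    icdf = stats::qnorm
  )
}

#' @rdname noise_model
#' @export
laplace_noise <- function() {
  new_noise_model(
    "laplace",
    pdf  = function(x) 0.5 * exp(-abs(x)),
    dpdf = function(x) -sign(x) * 0.5 * exp(-abs(x)),
    cdf  = function(x) ifelse(x < 0, 0.5 * exp(x), 1 - 0.5 * exp(-x)),
    icdf = function(q) ifelse(q < 0.5, log(2 * q), -log(2 * (1 - q)))
  )
}

#' @rdname noise_model
#' @export
cauchy_noise <- function() {
  new_noise_model(
    "cauchy",
    pdf  = stats::dcauchy,
    dpdf = function(x) -2 * x / (pi * (1 + x^2)^2),
    cdf  = stats::pcauchy,
    icdf = stats::qcauchy
  )
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model:", x$name, ">\n")
  invisible(x)
}

is_noise_model <- function(x) inherits(x, "noise_model")

assert_noise <- function(noise) {
  if (!is_noise_model(noise)) {
    stop("`noise` must be a noise_model object (see `noise_model()`)",
         call. = FALSE)
  }
  invisible(noise)
}
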