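#' @title External-validation growth laws
#' @name growth_laws
#' @description
#' Three phenomenological laws used to validate simulated traces against
#' the tumor-biology literature:
#' \describe{
#'   \item{Gompertz tumor growth}{`n(t) = n0 * exp[(alpha/beta) * (1 - exp(-beta t))]`
#'     -- decelerating sigmoid growth of the cancerous-cell population;
#'     `alpha` (1/time) is the initial specific growth rate and `beta`
#'     (1/time) how rapidly the curve departs from a simple exponential.
#'     Clinically fitted human-tumor values lie in
#'     `alpha` in \[0.005, 0.016\] and `beta` in \[0.121, 0.390\].}
#'   \item{Sigmoid vessel growth}{`g(t) = g0 + alpha / (1 + exp(-(t - t_half)/beta))`
#'     -- total vascular length; `alpha` is the range (top minus bottom),
#'     `t_half` the midpoint time, `beta` the slope scale.}
#'   \item{Exponential branching}{`b(t) = b0 + alpha * exp(beta t)` --
#'     number of vessel branch points; experimentally determined
#'     `alpha = 2.62`, `beta = 0.105`.}
#' }
#' All three are monotone non-decreasing on `t >= 0` for valid parameters.
NULL

#' @rdname growth_laws
#' @param t time (>= 0); vectorized.
#' @param n0,alpha,beta Gompertz parameters (all > 0).
#' @return model value at `t`.
#' @examples
#' gompertz(0, 100, 0.01, 0.3)   # 100
#' branching(0, 0, 2.62, 0.105)  # 2.62
#' sigmoid_growth(Inf, 0, 58500, 62, 360)  # 58500
#' @export
gompertz <- function(t, n0, alpha, beta) {
  stopifnot(n0 > 0, alpha > 0, beta > 0, all(t >= 0))
  n0 * exp(alpha / beta * (1 - exp(-beta * t)))
}

#' @rdname growth_laws
#' @param g0 initial vessel length (>= 0).
#' @param t_half midpoint time (> 0).
#' @export
sigmoid_growth <- function(t, g0, alpha, beta, t_half) {
  stopifnot(g0 >= 0, alpha > 0, beta > 0, t_half > 0)
  out <- g0 + alpha / (1 + exp(-(t - t_half) / beta))
  out[is.infinite(t) & t > 0] <- g0 + alpha
  out
}

#' @rdname growth_laws
#' @param b0 initial number of branch points (>= 0).
#' @export
branching <- function(t, b0, alpha, beta) {
  stopifnot(b0 >= 0, alpha > 0, beta > 0, all(t >= 0))
  b0 + alpha * exp(beta * t)
}

#' Forecast-error metrics between two series
#'
#' Root mean square error, mean absolute deviation of the errors, and mean
#' absolute percentage error. MAPE is computed only over points where the
#' actual series is non-zero; the number of skipped points is reported.
#'
#' @param pred predicted series.
#' @param actual reference series of the same length.
#' @return list with `rmse`, `mad`, `mape` (percent), `mape_skipped`.
#' @examples
#' error_metrics(c(1, 2), c(1, 4))  # rmse sqrt(2), mad 1, mape 25
#' @export
error_metrics <- function(pred, actual) {
  if (length(pred) != length(actual))
    stop("series length mismatch: ", length(pred), " vs ", length(actual),
         call. = FALSE)
  stopifnot(length(pred) >= 1L)
  e <- pred - actual
  nz <- actual != 0
  list(rmse = sqrt(mean(e^2)),
       mad = mean(abs(e)),
       mape = if (any(nz)) mean(abs(e[nz] / actual[nz])) * 100 else NA_real_,
       mape_skipped = sum(!nz))
}

#' Fit a growth law to a time series by nonlinear least squares
#'
#' Levenberg-Marquardt least squares ([minpack.lm::nlsLM]) from a grid of
#' data-driven multi-start initial guesses; the best-converged start (lowest
#' residual sum of squares) is returned. The Gompertz law is fitted in log
#' space for numerical stability, which requires `y > 0`. For Gompertz fits
#' the result also flags whether `alpha` and `beta` fall inside the
#' clinically observed ranges \[0.005, 0.016\] and \[0.121, 0.390\] (in the
#' reciprocal of the unit of `t`).
#'
#' @param t,y the series (at least 4 points).
#' @param law `"gompertz"`, `"sigmoid"`, or `"branching"`.
#' @return a `growth_fit` list: `law`, `params` (named vector), `fitted`,
#'   `errors` (an [error_metrics()] report of fitted vs observed),
#'   `converged`, and for Gompertz `alpha_in_range` / `beta_in_range`.
#' @export
fit_growth_law <- function(t, y, law = c("gompertz", "sigmoid", "branching")) {
  law <- match.arg(law)
  stopifnot(length(t) == length(y), length(t) >= 4L, all(is.finite(t)),
            all(is.finite(y)))
  fits <- switch(law,
    gompertz = fit_gompertz(t, y),
    sigmoid = fit_sigmoid(t, y),
    branching = fit_branching(t, y))
  if (is.null(fits$fit))
    stop("growth-law fit did not converge from any start (law = ", law,
         "); starts tried: ", fits$tried, call. = FALSE)
  params <- fits$params
  pred <- switch(law,
    gompertz = gompertz(t, params["n0"], params["alpha"], params["beta"]),
    sigmoid = sigmoid_growth(t, params["g0"], params["alpha"],
                             params["beta"], params["t_half"]),
    branching = branching(t, params["b0"], params["alpha"], params["beta"]))
  out <- list(law = law, params = params, fitted = pred,
              errors = error_metrics(pred, y), converged = TRUE)
  if (law == "gompertz") {
    out$alpha_in_range <- params[["alpha"]] >= 0.005 && params[["alpha"]] <= 0.016
    out$beta_in_range <- params[["beta"]] >= 0.121 && params[["beta"]] <= 0.390
  }
  class(out) <- "growth_fit"
  out
}

try_starts <- function(formula, data, starts, lower, upper) {
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nlsLM(formula, data = data, start = st, lower = lower,
                        upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(f)) {
      rss <- sum(residuals(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  list(fit = best$fit, tried = length(starts))
}

fit_gompertz <- function(t, y) {
  if (any(y <= 0)) stop("Gompertz fitting requires y > 0", call. = FALSE)
  d <- data.frame(t = t, ly = log(y))
  A <- max(log(max(y) / y[which.min(t)]), 1e-6)
  starts <- lapply(c(0.005, 0.02, 0.05, 0.1, 0.3, 1),
                   function(b) list(ln0 = log(y[which.min(t)]),
                                    alpha = max(A * b, 1e-6), beta = b))
  r <- try_starts(ly ~ ln0 + (alpha / beta) * (1 - exp(-beta * t)), d, starts,
                  lower = c(ln0 = -Inf, alpha = 1e-10, beta = 1e-8),
                  upper = c(ln0 = Inf, alpha = Inf, beta = Inf))
  if (is.null(r$fit)) return(r)
  cf <- coef(r$fit)
  list(fit = r$fit,
       params = c(n0 = unname(exp(cf["ln0"])), alpha = unname(cf["alpha"]),
                  beta = unname(cf["beta"])))
}

fit_sigmoid <- function(t, y) {
  d <- data.frame(t = t, y = y)
  rng <- max(y) - min(y)
  if (rng <= 0) rng <- max(abs(y), 1)
  mid <- t[which.min(abs(y - (min(y) + rng / 2)))]
  span <- diff(range(t))
  starts <- list()
  for (b in span * c(0.02, 0.05, 0.15, 0.4))
    starts <- c(starts, list(list(g0 = min(y), alpha = rng,
                                  t_half = mid, beta = b)))
  r <- try_starts(y ~ g0 + alpha / (1 + exp(-(t - t_half) / beta)), d, starts,
                  lower = c(g0 = 0, alpha = 1e-10, t_half = 1e-8, beta = 1e-8),
                  upper = rep(Inf, 4))
  if (is.null(r$fit)) return(r)
  cf <- coef(r$fit)
  list(fit = r$fit, params = cf[c("g0", "alpha", "beta", "t_half")])
}

fit_branching <- function(t, y) {
  d <- data.frame(t = t, y = y)
  span <- diff(range(t))
  bgrid <- c(0.5, 1, 2, 5) / max(span, 1)
  # crude slope-based guess from endpoint ratio above the minimum
  y0 <- min(y)
  starts <- list()
  for (b in unique(c(bgrid, 0.105))) {
    a <- max((max(y) - y0) / max(exp(b * max(t)) - 1, 1e-8), 1e-6)
    starts <- c(starts, list(list(b0 = max(y0, 0), alpha = a, beta = b)))
  }
  r <- try_starts(y ~ b0 + alpha * exp(beta * t), d, starts,
                  lower = c(b0 = 0, alpha = 1e-10, beta = 1e-8),
                  upper = rep(Inf, 3))
  if (is.null(r$fit)) return(r)
  cf <- coef(r$fit)
  list(fit = r$fit, params = cf[c("b0", "alpha", "beta")])
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit: %s>\n", x$law))
  print(signif(x$params, 6))
  cat(sprintf("RMSE %.4g | MAD %.4g | MAPE %.3g%%\n",
              x$errors$rmse, x$errors$mad, x$errors$mape))
  if (!is.null(x$alpha_in_range))
    cat(sprintf("alpha in [0.005, 0.016]: %s; beta in [0.121, 0.390]: %s\n",
                x$alpha_in_range, x$beta_in_range))
  invisible(x)
}
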