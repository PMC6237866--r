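#' Fit the linear-rise/tri-exponential plasma model
#'
#' Least-squares fit of the total-plasma curve: a straight line through zero
#' up to the peak sample, then a sum of three decaying exponentials anchored
#' at the peak (the peak value is the sum of the amplitudes, so the fitted
#' curve is continuous). Rates and amplitudes are log-parameterized to
#' enforce positivity and the optimizer is restarted from several spread-out
#' initializations; the best sum of squares wins.
#'
#' @param samples A [tac] of plasma samples spanning the peak and the tail.
#' @param n_starts Number of multi-start initializations.
#' @param weighted If `TRUE`, residuals are weighted by 1/max(value, eps)
#'   (relative error); default unweighted.
#' @param seed Seed for the start jitter.
#' @return An [aif_params] with attributes `rms` (residual RMS, kBq/mL) and
#'   `t_max` (last sample time fitted).
#' @export
fit_plasma_triexp <- function(samples, n_starts = 5, weighted = FALSE,
                              seed = 1L) {
  stopifnot(inherits(samples, "tac"))
  if (length(samples$times) < 8)
    stop("underdetermined: need at least 8 plasma samples")
  pk <- which.max(samples$activity)
  peak_val <- samples$activity[pk]
  if (peak_val <= 0) stop("fit failure: plasma samples are all zero")
  t_peak <- samples$times[pk]
  tt <- samples$times
  yy <- samples$activity
  w <- if (weighted) 1 / pmax(yy, 0.01 * peak_val) else rep(1, length(yy))

  model <- function(theta, t) {
    A <- exp(theta[1:3]); lam <- exp(theta[4:6])
    out <- numeric(length(t))
    rise <- t <= t_peak
    out[rise] <- sum(A) * t[rise] / t_peak
    td <- t[!rise] - t_peak
    out[!rise] <- colSums(A * exp(-outer(lam, td)))
    out
  }
  resid_fn <- function(theta) w * (model(theta, tt) - yy)

  starts <- withr::with_seed(seed, {
    base <- c(log(peak_val * c(0.75, 0.2, 0.05)), log(c(4, 0.5, 0.02)))
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) base else base + stats::rnorm(6, 0, 0.5)
    })
  })
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best))
    stop("fit failure: plasma tri-exponential fit did not converge")
  th <- best$fit$par
  A <- exp(th[1:3]); lam <- exp(th[4:6])
  ord <- order(lam, decreasing = TRUE)
  out <- aif_params(t_peak, A[ord], lam[ord])
  attr(out, "rms") <- sqrt(mean((model(th, tt) - yy)^2))
  attr(out, "t_max") <- max(tt)
  out
}

#' Fit the Hill parent-fraction model
#'
#' Bounded least squares of `f(t) = 1 - a t^b / (t^b + c)` to measured
#' parent fractions, with `a` logit- and `b`, `c` log-parameterized so that
#' `0 <= a <= 1`, `b > 0`, `c > 0`; the fitted curve is monotone
#' non-increasing by construction.
#'
#' @param times Sample times, minutes; at least one sample must be >= 5 min.
#' @param fractions Measured parent fractions, all in \[0, 1\].
#' @param n_starts Number of multi-start initializations.
#' @param seed Seed for the start jitter.
#' @return A [hill_params] with attribute `rms`.
#' @export
fit_parent_hill <- function(times, fractions, n_starts = 5, seed = 1L) {
  if (length(times) != length(fractions) || length(times) < 3)
    stop("need at least 3 (time, fraction) samples")
  if (any(fractions < 0 | fractions > 1))
    stop("fractions must be in [0, 1]")
  if (!any(times >= 5))
    stop("need at least one sample at 5 min or later")
  model <- function(theta, t) {
    a <- stats::plogis(theta[1]); b <- exp(theta[2]); cc <- exp(theta[3])
    tb <- t^b
    1 - a * tb / (tb + cc)
  }
  resid_fn <- function(theta) model(theta, times) - fractions
  starts <- withr::with_seed(seed, {
    base <- c(stats::qlogis(0.5), log(1), log(10))
    lapply(seq_len(n_starts), function(i)
      if (i == 1) base else base + stats::rnorm(3, 0, 0.7))
  })
  best <- NULL
  for (th0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(fit$fvec^2)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("fit failure: Hill fit did not converge")
  th <- best$fit$par
  out <- hill_params(stats::plogis(th[1]), exp(th[2]), exp(th[3]))
  attr(out, "rms") <- sqrt(best$sse / length(times))
  out
}

#' Metabolite-corrected arterial input model
#'
#' Bundles a fitted plasma model and a fitted parent-fraction model; the
#' corrected input is their pointwise product, which is non-negative and
#' never exceeds the plasma fit.
#'
#' @param aif_fit An [aif_params] (typically from [fit_plasma_triexp()]).
#' @param hill_fit A [hill_params] (typically from [fit_parent_hill()]).
#' @param t_max Last fitted sample time; evaluation beyond it warns.
#' @return An object of class `arterial_input_model`.
#' @export
arterial_input_model <- function(aif_fit, hill_fit,
                                 t_max = attr(aif_fit, "t_max") %||% 60) {
  stopifnot(inherits(aif_fit, "aif_params"), inherits(hill_fit, "hill_params"))
  structure(list(aif_fit = aif_fit, hill_fit = hill_fit, t_max = t_max,
                 diagnostics = list(plasma_rms = attr(aif_fit, "rms"),
                                    parent_rms = attr(hill_fit, "rms"))),
            class = "arterial_input_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname arterial_input_model
#' @param model An `arterial_input_model`.
#' @param times Evaluation times, minutes.
#' @return `corrected_input()`: a [tac] of metabolite-corrected plasma
#'   activity.
#' @export
corrected_input <- function(model, times) {
  stopifnot(inherits(model, "arterial_input_model"))
  if (any(times > model$t_max + 1e-9))
    warning("extrapolating the input model beyond the fitted span (",
            signif(model$t_max, 3), " min)")
  tac(times, corrected_input_fun(model)(times), label = "corrected input")
}

#' @rdname arterial_input_model
#' @return `corrected_input_fun()`: a function of time (minutes) evaluating
#'   the corrected input analytically.
#' @export
corrected_input_fun <- function(model) {
  stopifnot(inherits(model, "arterial_input_model"))
  corrected_input_from(model$aif_fit, model$hill_fit)
}

#' @rdname arterial_input_model
#' @param blood A list with `plasma` (a [tac]) and `parent` (data frame with
#'   `time`, `fraction`), as produced by [simulate_blood_data()].
#' @return `fit_input_model()`: an `arterial_input_model` fitted to the blood
#'   data.
#' @export
fit_input_model <- function(blood, weighted = FALSE) {
  aif <- fit_plasma_triexp(blood$plasma, weighted = weighted)
  hill <- fit_parent_hill(blood$parent$time, blood$parent$fraction)
  arterial_input_model(aif, hill)
}
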