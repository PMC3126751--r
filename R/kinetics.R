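#' Half-life from a first-order rate constant
#'
#' @param k rate constant (per hour), > 0.
#' @return `ln(2) / k` in hours; e.g. `k = 0.13` gives 5.3 h.
#' @export
half_life <- function(k) {
  if (!is.numeric(k) || any(!is.finite(k)) || any(k <= 0))
    stop("k must be positive and finite", call. = FALSE)
  log(2) / k
}

kinetic_fit_result <- function(form, pars, times, values, fitted,
                               converged, note = NA_character_) {
  ss_res <- sum((values - fitted)^2)
  ss_tot <- sum((values - mean(values))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else if (ss_res == 0) 1 else NA_real_
  k <- unname(pars[["k"]])
  structure(list(
    model_form = form, parameters = pars,
    r_squared = r2,
    half_life = if (isTRUE(converged) && is.finite(k) && k > 0)
      half_life(k) else NA_real_,
    times = times, values = values, fitted = fitted,
    converged = converged, note = note), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  amp <- setdiff(names(x$parameters), "k")
  cat(sprintf("%s fit: %s = %.3f, k = %.3f /h, R^2 = %.3f, t1/2 = %.1f h%s\n",
              x$model_form, amp, x$parameters[[amp]], x$parameters[["k"]],
              x$r_squared, x$half_life,
              if (!x$converged) paste0("  [NOT CONVERGED: ", x$note, "]")
              else ""))
  invisible(x)
}

validate_kinetic_input <- function(times, values) {
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) < 3L)
    stop("need at least 3 points for a kinetic fit", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0) || any(diff(times) <= 0))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  if (any(!is.finite(values)))
    stop("values must be finite", call. = FALSE)
  list(times = times, values = values)
}

# shared nonlinear least-squares driver: nls with a log-linear start,
# falling back to Nelder-Mead on the SSE if nls fails to converge
fit_exponential <- function(times, values, form) {
  inp <- validate_kinetic_input(times, values)
  times <- inp$times; values <- inp$values
  decay <- form == "decay"

  if (max(values) - min(values) < 1e-12) {
    # constant series: amplitude identified, rate is not
    amp <- mean(values)
    pars <- if (decay) c(`I(0)` = amp, k = 0) else c(b = amp, k = 0)
    return(kinetic_fit_result(form, pars, times, values,
                              fitted = rep(amp, length(values)),
                              converged = FALSE,
                              note = "constant series; rate non-identifiable"))
  }

  # starting values: amplitude from the endpoints, k by log-linear regression
  amp0 <- if (decay) max(values[1], max(values) * 0.5, 1e-6)
          else max(values[length(values)], max(values), 1e-6)
  z <- if (decay) values / amp0 else 1 - values / amp0
  usable <- z > 1e-6
  k0 <- if (sum(usable) >= 2) {
    sl <- -coef(lm(log(z[usable]) ~ times[usable]))[[2]]
    if (is.finite(sl) && sl > 0) sl else 0.1
  } else 0.1

  predfun <- if (decay) function(a, k) a * exp(-k * times)
             else function(a, k) a * (1 - exp(-k * times))
  sse <- function(p) sum((values - predfun(p[1], p[2]))^2)

  fit <- tryCatch({
    df <- data.frame(t = times, y = values)
    m <- if (decay)
      nls(y ~ a * exp(-k * t), data = df, start = list(a = amp0, k = k0),
          control = list(maxiter = 200, warnOnly = FALSE))
    else
      nls(y ~ a * (1 - exp(-k * t)), data = df,
          start = list(a = amp0, k = k0),
          control = list(maxiter = 200, warnOnly = FALSE))
    as.list(coef(m))
  }, error = function(e) NULL)

  note <- NA_character_
  if (is.null(fit)) {
    o <- optim(c(amp0, k0), sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-12))
    fit <- list(a = o$par[1], k = o$par[2])
    note <- "nls failed; Nelder-Mead fallback"
  }
  a <- fit$a; k <- fit$k
  converged <- is.finite(a) && is.finite(k) && k > 0
  if (!converged && is.na(note)) note <- "non-positive rate estimate"
  pars <- if (decay) c(`I(0)` = a, k = k) else c(b = a, k = k)
  kinetic_fit_result(form, pars, times, values, fitted = predfun(a, k),
                     converged = converged, note = note)
}

#' Fit a single exponential decay to a timecourse
#'
#' Fits `I(t) = I(0) exp(-k t)` by nonlinear least squares, e.g. to the
#' disappearance of the unlabeled (m0) species after the switch to
#' 13C-labeled substrate.
#'
#' @param times sampling times in hours (>= 3 points, strictly increasing).
#' @param values mole fractions at those times.
#' @return a `kinetic_fit` with parameters `I(0)` and `k` (per hour),
#'   `r_squared`, `half_life` (= ln 2 / k), and a `converged` flag;
#'   non-convergence is flagged, not thrown.
#' @examples
#' t <- c(0, 3, 6, 11, 24, 34, 48)
#' fit_exponential_decay(t, 0.9 * exp(-0.1 * t))
#' @export
fit_exponential_decay <- function(times, values) {
  fit_exponential(times, values, "decay")
}

#' Fit a saturating exponential rise to a timecourse
#'
#' Fits `y(t) = b (1 - exp(-k t))`, the mono-exponential approach to a
#' plateau `b`, e.g. for the 13C-labeled ribose fraction of UDP-GlcNAc.
#'
#' @inheritParams fit_exponential_decay
#' @return a `kinetic_fit` with parameters `b` and `k`; see
#'   [fit_exponential_decay()].
#' @examples
#' t <- c(0, 3, 6, 11, 24, 34, 48)
#' fit_exponential_rise(t, 0.89 * (1 - exp(-0.13 * t)))
#' @export
fit_exponential_rise <- function(times, values) {
  fit_exponential(times, values, "rise")
}
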