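#' Exocytosis time series
#'
#' Normalised intracellular NP amounts over time during an exocytosis
#' experiment (no NPs in the extracellular medium at t = 0).  Amounts are
#' stored relative to the initial amount, so the first value is 1.
#'
#' @param times Observation times, strictly increasing, starting at 0.
#' @param amounts Intracellular amounts; normalised to the first value when
#'   `normalize = TRUE` (default).
#' @param cell_line,np_id Optional labels.
#' @param time_unit `"h"` (default) or `"s"`; stored internally in hours.
#' @param normalize Divide amounts by the first amount (default TRUE).  When
#'   FALSE the first amount must already be 1 within 0.1.
#' @return Object of class `exocytosis_series`.
#' @export
exocytosis_series <- function(times, amounts, cell_line = NA_character_,
                              np_id = NA_character_, time_unit = c("h", "s"),
                              normalize = TRUE) {
  time_unit <- match.arg(time_unit)
  times <- as.numeric(times)
  amounts <- as.numeric(amounts)
  if (length(times) != length(amounts) || length(times) < 2L)
    stop("need >= 2 paired (time, amount) observations", call. = FALSE)
  if (time_unit == "s") times <- times / 3600
  if (any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (times[1L] < 0) stop("times must start at t >= 0", call. = FALSE)
  if (anyNA(amounts) || any(amounts < 0))
    stop("`amounts` must be non-negative", call. = FALSE)
  if (normalize) {
    if (amounts[1L] <= 0)
      stop("first amount must be > 0 to normalise", call. = FALSE)
    amounts <- amounts / amounts[1L]
  } else if (abs(amounts[1L] - 1) > 0.1) {
    stop("first amount must be ~1 for a normalised series ",
         "(use normalize = TRUE)", call. = FALSE)
  }
  structure(list(times = times, amounts = amounts,
                 cell_line = cell_line, np_id = np_id),
            class = "exocytosis_series")
}

#' @export
print.exocytosis_series <- function(x, ...) {
  cat(sprintf("Exocytosis series (%s / %s): %d points over %.1f h, final %.3f\n",
              x$np_id, x$cell_line, length(x$times), max(x$times),
              x$amounts[length(x$amounts)]))
  invisible(x)
}

# relative range; used to reject unidentifiable flat series
.is_flat <- function(amounts) {
  (max(amounts) - min(amounts)) <= 1e-6 * max(abs(amounts), 1)
}

.rate_fit <- function(k_exo, np_eq, model, residual_norm, stderr_k, series) {
  structure(list(k_exo = k_exo, np_eq = np_eq, model = model,
                 residual_norm = residual_norm, stderr_k = stderr_k,
                 cell_line = series$cell_line, np_id = series$np_id),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  cat(sprintf("Exocytosis rate fit (%s): k_exo = %.4g /s (SE %.2g), plateau = %.3f\n",
              x$model, x$k_exo, x$stderr_k, x$np_eq))
  invisible(x)
}

#' Fit the plateau exocytosis curve
#'
#' Nonlinear least-squares fit of the exocytosis curve with an equilibrium
#' plateau, \deqn{a(t) = (a_0 - a_{eq})\,e^{-kt} + a_{eq},} with the initial
#' amount \eqn{a_0} fixed at the first observation.  \eqn{k} is bounded to
#' (0, 1] /s and the plateau \eqn{a_{eq}} to [0, 1]; starting values come
#' from a log-linear fit of the plateau-subtracted amounts.
#'
#' @param series [exocytosis_series()] with at least 4 points.
#' @return A `rate_fit` with `model = "plateau"`; `k_exo` in /s.
#' @examples
#' s <- generate_exocytosis_series(k = 2e-5, np_eq = 0.3, times = 0:24)
#' fit_plateau_decay(s)
#' @export
fit_plateau_decay <- function(series) {
  stopifnot(inherits(series, "exocytosis_series"))
  if (length(series$times) < 4L)
    stop("plateau fit needs >= 4 time points", call. = FALSE)
  if (.is_flat(series$amounts))
    stop("unidentifiable rate: series shows no decay", call. = FALSE)
  # fit k in /h for a well-conditioned Jacobian, report in /s
  t_h <- series$times
  a <- series$amounts
  a0 <- a[1L]

  eq0 <- max(min(a) - 0.01, 0)
  shifted <- pmax(a - eq0, 1e-8)
  k0 <- -stats::coef(stats::lm(log(shifted) ~ t_h))[[2L]]
  k0 <- min(max(k0, 1e-6), 3600)
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ (a0 - np_eq) * exp(-kh * t_h) + np_eq,
                      start = list(kh = k0, np_eq = eq0),
                      lower = c(kh = 1e-9, np_eq = 0),
                      upper = c(kh = 3600, np_eq = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("exocytosis curve fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["kh", "Std. Error"] / 3600,
                 error = function(e) NA_real_)
  .rate_fit(k_exo = co[["kh"]] / 3600, np_eq = co[["np_eq"]],
            model = "plateau",
            residual_norm = sqrt(sum(stats::resid(fit)^2)),
            stderr_k = se, series = series)
}

#' Fit the first-order exocytosis curve
#'
#' Least-squares fit of \eqn{a(t) = a_0 e^{-kt}} (plateau fixed at zero).
#' When all amounts are positive this is the log-linear regression through
#' the normalised data (no intercept, since \eqn{a_0 = 1} at \eqn{t = 0});
#' otherwise it falls back to a bounded nonlinear fit with a warning.
#'
#' @param series [exocytosis_series()] with at least 2 points.
#' @return A `rate_fit` with `model = "first_order"` and `np_eq = 0`.
#' @export
fit_first_order <- function(series) {
  stopifnot(inherits(series, "exocytosis_series"))
  if (.is_flat(series$amounts))
    stop("unidentifiable rate: series shows no decay", call. = FALSE)
  t_s <- series$times * 3600
  a <- series$amounts
  if (any(a <= 0)) {
    warning("amounts <= 0; falling back to nonlinear first-order fit")
    a0 <- a[1L]
    fit <- minpack.lm::nlsLM(a ~ a0 * exp(-k * t_s), start = list(k = 1e-5),
                             lower = c(k = 1e-12), upper = c(k = 1))
    k <- stats::coef(fit)[["k"]]
    se <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                   error = function(e) NA_real_)
    return(.rate_fit(k, 0, "first_order", sqrt(sum(stats::resid(fit)^2)),
                     se, series))
  }
  y <- log(a)                       # y = -k * t, through the origin
  k <- -sum(t_s * y) / sum(t_s^2)
  res <- y + k * t_s
  dof <- length(y) - 1L
  se <- if (dof > 0) sqrt(sum(res^2) / dof / sum(t_s^2)) else NA_real_
  .rate_fit(k, 0, "first_order",
            residual_norm = sqrt(sum((a - exp(-k * t_s))^2)),
            stderr_k = se, series = series)
}

#' Two-point exocytosis rate constant
#'
#' First-order rate constant from only the initial and final intracellular
#' amounts: \eqn{k = \ln(a_i/a_f)/\Delta t}, in /s.
#'
#' @param initial Initial intracellular amount (> 0).
#' @param final Final intracellular amount (> 0, <= initial).
#' @param duration Experiment duration in hours.
#' @return Rate constant, /s.
#' @examples
#' two_point_rate(1, 0.5, 24)  # log(2)/86400
#' @export
two_point_rate <- function(initial, final, duration) {
  if (!is.numeric(initial) || initial <= 0)
    stop("`initial` must be > 0", call. = FALSE)
  if (!is.numeric(duration) || duration <= 0)
    stop("`duration` must be > 0 (hours)", call. = FALSE)
  if (!is.numeric(final) || final < 0)
    stop("`final` must be >= 0", call. = FALSE)
  if (final == 0)
    stop("infinite rate: final amount is zero", call. = FALSE)
  if (final > initial)
    stop("negative rate: final amount exceeds initial ",
         "(exocytosis assumption violated)", call. = FALSE)
  log(initial / final) / (duration * 3600)
}
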