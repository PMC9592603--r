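# summary.lm warns on a numerically perfect fit; noiseless synthetic data
# make that case legitimate here, so muffle that specific warning only
.lm_summary_quiet <- function(fit) {
  withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

#' Fit the per-cell-line Arrhenius regression
#'
#' Ordinary least squares of \eqn{\ln k_{exo}} on the exocytosis energy
#' change: \deqn{\ln k_{exo} = \beta\,\Delta G(d) + \ln A.}  The slope
#' \eqn{\beta} (mol/kJ) is a free empirical parameter — fitted cell-line
#' slopes are two orders of magnitude shallower than the naive Boltzmann
#' value \eqn{-1/RT} — and the intercept gives the cell line's frequency
#' factor \eqn{A = e^{\ln A}} in /s.
#'
#' @param dg_change Exocytosis energy changes \eqn{\Delta G(d)}, kJ/mol.
#' @param k_exo Exocytosis rate constants, /s (> 0).
#' @param cell_line Label for the fitted cell line.
#' @return Object of class `cell_line_model`: `beta`, `ln_a`, `beta_se`,
#'   `ln_a_se`, `r2`, `p_value` (two-sided t test of the slope, n-2 df),
#'   `n`, `residual_variance`, `mean_dg`, `ss_dg`, `dg_range`.
#' @examples
#' dg <- c(100, 400, 800, 1200, 1600)
#' fit_cell_model(dg, exp(-0.002 * dg - 9), "demo")
#' @export
fit_cell_model <- function(dg_change, k_exo, cell_line = "cell") {
  dg <- as.numeric(dg_change)
  k <- as.numeric(k_exo)
  if (length(dg) != length(k))
    stop("`dg_change` and `k_exo` must have equal length", call. = FALSE)
  n <- length(dg)
  if (n < 3L)
    stop("insufficient data: need >= 3 points per cell line", call. = FALSE)
  if (anyNA(dg) || anyNA(k) || any(k <= 0))
    stop("all k_exo must be positive and non-missing", call. = FALSE)
  ss_dg <- sum((dg - mean(dg))^2)
  if (ss_dg == 0)
    stop("degenerate design: zero variance in dg_change", call. = FALSE)
  y <- log(k)
  fit <- stats::lm(y ~ dg)
  sm <- .lm_summary_quiet(fit)
  co <- sm$coefficients
  beta <- co["dg", "Estimate"]
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {                       # flat response: slope 0 by fiat
    beta <- 0; r2 <- 0; p <- 1
    beta_se <- 0; ln_a_se <- 0; rv <- 0
    ln_a <- mean(y)
  } else {
    r2 <- sm$r.squared
    p <- co["dg", "Pr(>|t|)"]
    beta_se <- co["dg", "Std. Error"]
    ln_a <- co["(Intercept)", "Estimate"]
    ln_a_se <- co["(Intercept)", "Std. Error"]
    rv <- sm$sigma^2
    if (!is.finite(rv)) rv <- 0            # n == 2 guarded above; safety
  }
  structure(list(cell_line = cell_line, beta = beta, ln_a = ln_a,
                 beta_se = beta_se, ln_a_se = ln_a_se, r2 = r2,
                 p_value = p, n = n, residual_variance = rv,
                 mean_dg = mean(dg), ss_dg = ss_dg, dg_range = range(dg)),
            class = "cell_line_model")
}

#' @export
print.cell_line_model <- function(x, ...) {
  cat(sprintf("Arrhenius cell-line model: %s (n = %d)\n", x$cell_line, x$n))
  cat(sprintf("  ln(k_exo) = %.4g * dG(d) %+.3g\n", x$beta, x$ln_a))
  cat(sprintf("  beta = %.4g +/- %.2g mol/kJ, A = %.3g /s\n",
              x$beta, x$beta_se, exp(x$ln_a)))
  cat(sprintf("  R^2 = %.3f, p = %.3g\n", x$r2, x$p_value))
  invisible(x)
}

#' Predict exocytosis rate constants with intervals
#'
#' Point prediction \eqn{\hat k = e^{\beta \Delta G + \ln A}} with a
#' mean-response (confidence) interval computed on the ln scale from the OLS
#' machinery — \eqn{SE = s\sqrt{1/n + (\Delta G - \bar{\Delta G})^2 /
#' SS_{\Delta G}}} with t quantiles on n-2 df — and exponentiated.  Interval
#' width grows with the distance of \eqn{\Delta G} from the training mean;
#' predictions outside the training range carry an extrapolation flag.  A
#' prediction-interval variant (adding the residual variance) is available
#' via `interval = "prediction"`.
#'
#' @param model [fit_cell_model()] result.
#' @param dg_change Energy change(s) to predict at, kJ/mol.
#' @param level Confidence level (default 0.95).
#' @param interval `"confidence"` (mean response, default) or
#'   `"prediction"`.
#' @return data.frame: `dg_change`, `k_exo` (point prediction, /s), `lower`,
#'   `upper`, `extrapolated`.
#' @export
predict_k_exo <- function(model, dg_change, level = 0.95,
                          interval = c("confidence", "prediction")) {
  if (!inherits(model, "cell_line_model"))
    stop("`model` must be a fitted cell_line_model", call. = FALSE)
  interval <- match.arg(interval)
  stopifnot(is.numeric(level), level > 0, level < 1)
  dg <- as.numeric(dg_change)
  mu <- model$beta * dg + model$ln_a
  extra <- if (interval == "prediction") 1 else 0
  se <- sqrt(model$residual_variance *
               (extra + 1 / model$n + (dg - model$mean_dg)^2 / model$ss_dg))
  tq <- stats::qt(1 - (1 - level) / 2, df = model$n - 2L)
  flag <- dg < model$dg_range[1L] | dg > model$dg_range[2L]
  data.frame(dg_change = dg, k_exo = exp(mu),
             lower = exp(mu - tq * se), upper = exp(mu + tq * se),
             extrapolated = flag)
}

#' Boltzmann fraction of vesicle-encapsulated NPs
#'
#' The equilibrium fraction of intracellular NPs bound to transport
#' vesicles, from the NP–vesicle interaction energy:
#' \deqn{[NP]_{vesicle}/[NP]_{total} = e^{-\Delta G_{np/v}/RT}.}
#' For the repulsive energies of coated NPs (hundreds of kJ/mol) this
#' fraction is astronomically small — which is why the regression slope
#' \eqn{\beta} is fitted empirically rather than pinned to \eqn{-1/RT}.
#'
#' @param dg_np_v NP–vesicle interaction energy, kJ/mol.
#' @param temperature K (default 310).
#' @return Fraction in (0, 1] for non-negative energies.  A negative energy
#'   yields a fraction above 1 with a warning (the repulsive-interaction
#'   assumption is violated).
#' @examples
#' vesicle_fraction(0)             # 1
#' vesicle_fraction(rt_kJ_mol())   # exp(-1)
#' @export
vesicle_fraction <- function(dg_np_v, temperature = 310) {
  stopifnot(is.numeric(temperature), temperature > 0)
  dg <- as.numeric(dg_np_v)
  if (any(dg < 0))
    warning("negative dg_np_v: vesicle fraction exceeds 1 ",
            "(repulsive-interaction assumption violated)")
  exp(-dg / rt_kJ_mol(temperature))
}

#' Decompose the fitted frequency factor over the vesicle partition
#'
#' The fitted cell-line frequency factor is the product of the intrinsic
#' vesicle-pathway frequency factor and the Boltzmann fraction of
#' vesicle-bound NPs: \eqn{A = A_{vesicle} \cdot
#' [NP]_{vesicle}/[NP]_{total}}.  Given a fitted model and an NP–vesicle
#' energy this returns both factors, always also on the log scale since the
#' fraction underflows for realistic energies.  When `dg_change` is
#' supplied, the combined mechanistic rate \eqn{k = f \cdot A_{vesicle}
#' \cdot e^{-\Delta G(d)/RT}} is reported as well.
#'
#' @param model [fit_cell_model()] result.
#' @param dg_np_v NP–vesicle interaction energy, kJ/mol.
#' @param temperature K (default 310).
#' @param dg_change Optional exocytosis energy change, kJ/mol.
#' @return Object of class `vesicle_partition`: `fraction`, `a_total`
#'   (= exp(ln_a)), `a_vesicle`, `ln_fraction`, `ln_a_vesicle`, `rt`, and
#'   optionally `ln_k_combined` / `k_combined`.
#' @export
decompose_frequency <- function(model, dg_np_v, temperature = 310,
                                dg_change = NULL) {
  if (!inherits(model, "cell_line_model"))
    stop("`model` must be a fitted cell_line_model", call. = FALSE)
  rt <- rt_kJ_mol(temperature)
  ln_fraction <- -as.numeric(dg_np_v) / rt
  ln_a_vesicle <- model$ln_a - ln_fraction
  out <- list(cell_line = model$cell_line,
              fraction = exp(ln_fraction),
              a_total = exp(model$ln_a),
              a_vesicle = exp(ln_a_vesicle),
              ln_fraction = ln_fraction,
              ln_a_vesicle = ln_a_vesicle,
              rt = rt)
  if (!is.null(dg_change)) {
    out$ln_k_combined <- ln_fraction + ln_a_vesicle -
      as.numeric(dg_change) / rt
    out$k_combined <- exp(out$ln_k_combined)
  }
  structure(out, class = "vesicle_partition")
}

#' @export
print.vesicle_partition <- function(x, ...) {
  cat(sprintf("Vesicle partition (%s, RT = %.3f kJ/mol)\n", x$cell_line, x$rt))
  cat(sprintf("  ln fraction = %.3g  (fraction = %.3g)\n",
              x$ln_fraction, x$fraction))
  cat(sprintf("  A = %.3g /s;  ln A_vesicle = %.3g\n", x$a_total,
              x$ln_a_vesicle))
  invisible(x)
}

#' Correlate a surface-energy component with hydrophobicity
#'
#' OLS of the octanol–water partition coefficient (log K_ow) of coating
#' compounds on one of their surface free-energy components, quantifying how
#' far the surface-energy description captures classical hydrophobicity.
#'
#' @param gamma_component Surface-energy component values, mJ/m^2.
#' @param log_kow Matching log K_ow (or log P) values.
#' @return Object of class `kow_regression`: `slope`, `intercept`, `r2`,
#'   `p_value`, `n`.
#' @export
gamma_kow_regression <- function(gamma_component, log_kow) {
  g <- as.numeric(gamma_component)
  k <- as.numeric(log_kow)
  if (length(g) != length(k) || length(g) < 3L)
    stop("need >= 3 paired (gamma, log K_ow) records", call. = FALSE)
  if (anyNA(g) || anyNA(k)) stop("missing values not allowed", call. = FALSE)
  if (stats::var(g) == 0)
    stop("degenerate design: zero variance in gamma", call. = FALSE)
  fit <- stats::lm(k ~ g)
  sm <- .lm_summary_quiet(fit)
  structure(list(slope = stats::coef(fit)[["g"]],
                 intercept = stats::coef(fit)[["(Intercept)"]],
                 r2 = sm$r.squared,
                 p_value = sm$coefficients["g", "Pr(>|t|)"],
                 n = length(g)),
            class = "kow_regression")
}

#' @export
print.kow_regression <- function(x, ...) {
  cat(sprintf("log K_ow ~ gamma: slope %.3g, intercept %.3g, R^2 = %.3f, p = %.3g (n = %d)\n",
              x$slope, x$intercept, x$r2, x$p_value, x$n))
  invisible(x)
}
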