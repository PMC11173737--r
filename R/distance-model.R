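#' Hyperbolic distance model of the water-induced free energy
#'
#' Evaluates `a + gamma * b / (r - r0)`: the water-induced potential of
#' mean force as a function of solute-solute distance `r`, with `r0` the
#' contact-minimum distance of the same solutes in vacuum and `gamma` the
#' geometric factor (1 before surface contact). The model is defined only
#' for `r > r0`.
#'
#' @param r separation(s), Angstrom; all strictly greater than `r0`.
#' @param a asymptotic offset, kJ/mol.
#' @param b amplitude, kJ/mol * Angstrom.
#' @param r0 vacuum contact-minimum distance, Angstrom.
#' @param gamma geometric factor in (0, 1].
#' @return kJ/mol, vectorised over `r`.
#' @seealso [fit_water_induced()] to estimate `a` and `b` from data.
#' @export
water_induced_model <- function(r, a, b, r0, gamma = 1) {
  if (!is.finite(gamma) || gamma <= 0 || gamma > 1)
    .stop_domain("'gamma' must lie in (0, 1]")
  if (any(!is.finite(r)) || any(r <= r0))
    .stop_domain("model defined only for r > r0")
  a + gamma * b / (r - r0)
}

#' Fit the hyperbolic distance model to water-induced free energies
#'
#' Least-squares estimation of the offset `a` and amplitude `b` of
#' `dG(r) = a + gamma * b / (r - r0)` with `r0` held fixed at the vacuum
#' contact minimum. The fit is linear in the transformed regressor
#' `x = 1 / (r - r0)`, so `a` is the intercept and `b` the slope divided
#' by `gamma`.
#'
#' @param r separations, Angstrom.
#' @param dG water-induced free energies, kJ/mol.
#' @param r0 fixed vacuum contact-minimum distance, Angstrom. Default 1.75.
#' @param gamma geometric factor held fixed during the fit. Default 1.
#' @return An object of class `wi_fit` with components `coefficients`
#'   (named `a`, `b`), `se` (standard errors), `r0`, `gamma`, `fitted`,
#'   `residuals`, `sigma` (residual standard deviation), `df.residual`
#'   and the data. Methods: [coef()], [predict()], [residuals()],
#'   [summary()], [print()], [simulate()].
#' @examples
#' r <- seq(2.5, 12, length.out = 50)
#' dG <- water_induced_model(r, a = -21.01, b = 27.62, r0 = 1.75)
#' fit <- fit_water_induced(r, dG)
#' coef(fit)
#' @export
fit_water_induced <- function(r, dG, r0 = 1.75, gamma = 1) {
  if (length(r) != length(dG))
    .stop_domain("'r' and 'dG' must have equal length")
  ok <- is.finite(r) & is.finite(dG) & r > r0
  if (sum(ok) < 3)
    .stop_domain("need at least 3 points with r > r0")
  if (!is.finite(gamma) || gamma <= 0 || gamma > 1)
    .stop_domain("'gamma' must lie in (0, 1]")
  r <- r[ok]; dG <- dG[ok]
  if (length(unique(r)) < 2)
    .stop_domain("degenerate fit: all separations equal")
  x <- 1 / (r - r0)
  fit <- stats::lm(dG ~ x)
  ## noiseless inputs are legitimate here; silence the perfect-fit note
  sm <- suppressWarnings(summary(fit))
  cf <- stats::coef(fit)
  se <- sm$coefficients[, "Std. Error"]
  structure(
    list(
      coefficients = c(a = unname(cf[1]), b = unname(cf[2]) / gamma),
      se = c(a = unname(se[1]), b = unname(se[2]) / gamma),
      r0 = r0, gamma = gamma,
      fitted = unname(stats::fitted(fit)),
      residuals = unname(stats::residuals(fit)),
      sigma = sm$sigma,
      df.residual = fit$df.residual,
      r = r, dG = dG
    ),
    class = "wi_fit"
  )
}

#' @export
coef.wi_fit <- function(object, ...) object$coefficients

#' @export
residuals.wi_fit <- function(object, ...) object$residuals

#' @rdname fit_water_induced
#' @param object,x an `wi_fit`.
#' @param newdata optional numeric vector of separations at which to
#'   evaluate the fitted model; defaults to the training separations.
#' @param ... unused.
#' @export
predict.wi_fit <- function(object, newdata = NULL, ...) {
  r <- if (is.null(newdata)) object$r else newdata
  water_induced_model(r, a = object$coefficients[["a"]],
                      b = object$coefficients[["b"]],
                      r0 = object$r0, gamma = object$gamma)
}

#' @export
print.wi_fit <- function(x, ...) {
  cat("Water-induced PMF distance model: dG(r) = a + gamma*b/(r - r0)\n")
  cat(sprintf("  a  = %9.3f (se %.3f) kJ/mol\n",
              x$coefficients[["a"]], x$se[["a"]]))
  cat(sprintf("  b  = %9.3f (se %.3f) kJ/mol*A\n",
              x$coefficients[["b"]], x$se[["b"]]))
  cat(sprintf("  r0 = %.3f A (fixed), gamma = %g (fixed)\n", x$r0, x$gamma))
  cat(sprintf("  residual sd %.4f kJ/mol on %d df, n = %d\n",
              x$sigma, x$df.residual, length(x$r)))
  invisible(x)
}

#' @export
summary.wi_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.wi_fit")
}

#' @export
print.summary.wi_fit <- function(x, ...) {
  print(x$fit)
  rs <- x$fit$residuals
  cat("Residuals (kJ/mol):\n")
  print(stats::quantile(rs, c(0, 0.25, 0.5, 0.75, 1)))
  invisible(x)
}

#' @rdname fit_water_induced
#' @param nsim number of response vectors to simulate.
#' @param seed optional integer seed.
#' @export
simulate.wi_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(object$r)
  out <- as.data.frame(replicate(
    nsim, object$fitted + stats::rnorm(n, sd = object$sigma),
    simplify = FALSE
  ))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}
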