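#' Weighted chi-squared statistic of a circuit model against a spectrum
#'
#' Residual statistic used throughout the EIS fitting stage. With modulus
#' weighting (the default) it is
#' \deqn{\chi^2_{raw} = \sum_i \frac{(Z'_i - \hat Z'_i)^2 +
#'       (Z''_i - \hat Z''_i)^2}{|Z_i|^2}}
#' and the reported statistic is \eqn{\chi^2_{raw} / (2N - p)} when a
#' parameter count `n_params` is supplied (as [fit_circuit()] does), or the
#' raw sum when not.
#'
#' @param spectrum Tibble with `freq_hz`, `z_real_ohm`, `z_imag_ohm`.
#' @param model A [circuit_model()] evaluated at the spectrum's frequencies.
#' @param weighting `"modulus"` (default), `"unit"`, or `"proportional"`
#'   (per-component weighting by `1/Z'^2` and `1/Z''^2`).
#' @param n_params If supplied, divide by the degrees of freedom `2N - p`.
#' @return A single non-negative number.
#' @export
chi_squared <- function(spectrum, model, weighting = c("modulus", "unit", "proportional"),
                        n_params = NULL) {
  weighting <- match.arg(weighting)
  check_spectrum(spectrum)
  zhat <- circuit_impedance(model, spectrum$freq_hz)
  r <- spectrum_residuals(spectrum, zhat, weighting)
  s <- sum(r^2)
  if (!is.null(n_params)) {
    dof <- 2 * nrow(spectrum) - n_params
    if (dof <= 0) {
      abort("degrees of freedom must be positive (2N > p).",
            class = "protoelec_insufficient_data")
    }
    s <- s / dof
  }
  s
}

check_spectrum <- function(spectrum) {
  need <- c("freq_hz", "z_real_ohm", "z_imag_ohm")
  if (!is.data.frame(spectrum) || !all(need %in% names(spectrum))) {
    abort("spectrum needs columns freq_hz, z_real_ohm, z_imag_ohm.",
          class = "protoelec_format_error")
  }
  if (nrow(spectrum) == 0) {
    abort("spectrum is empty.", class = "protoelec_insufficient_data")
  }
  if (any(spectrum$freq_hz <= 0)) {
    abort("spectrum frequencies must be positive.",
          class = "protoelec_format_error")
  }
  invisible(spectrum)
}

spectrum_residuals <- function(spectrum, zhat, weighting) {
  dre <- spectrum$z_real_ohm - zhat$z_real_ohm
  dim_ <- spectrum$z_imag_ohm - zhat$z_imag_ohm
  switch(weighting,
    unit = c(dre, dim_),
    modulus = {
      mod <- sqrt(spectrum$z_real_ohm^2 + spectrum$z_imag_ohm^2)
      mod[mod == 0] <- 1
      c(dre / mod, dim_ / mod)
    },
    proportional = {
      wr <- abs(spectrum$z_real_ohm); wr[wr == 0] <- 1
      wi <- abs(spectrum$z_imag_ohm); wi[wi == 0] <- 1
      c(dre / wr, dim_ / wi)
    }
  )
}

#' Fit a circuit model to an impedance spectrum
#'
#' Complex nonlinear least squares: both real and imaginary parts of the
#' spectrum enter the residual, weighted by the impedance modulus by default.
#' Parameters are optimised on a log scale (they are all positive magnitudes
#' spanning many decades), with box bounds, using Levenberg-Marquardt; the fit
#' is restarted from `n_restarts` log-uniform jitters of the initial values
#' (deterministic jitter seed) and the best optimum kept. Percent
#' uncertainties come from the curvature (Jacobian) at the optimum.
#'
#' @param spectrum Tibble with `freq_hz`, `z_real_ohm`, `z_imag_ohm`.
#' @param template A [circuit_model()] whose current parameter values are
#'   ignored except as structure; use `initial` to seed the fit.
#' @param initial Named numeric vector of starting values; names as produced
#'   by the template's parameter flattening (see the `params` column of the
#'   result, e.g. `n1.resistor.r`). Defaults to the template's own values.
#' @param lower,upper Named vectors of box bounds (same names); parameters
#'   without an entry default to `[1e-15, 1e15]`. CPE/O exponents are always
#'   additionally capped at 1.
#' @param weighting Residual weighting, see [chi_squared()].
#' @param n_restarts Number of jittered restarts (in addition to the supplied
#'   start).
#' @param restart_seed Seed for the restart jitter.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return An object of class `eis_fit` with elements `params` (named fitted
#'   values), `rel_uncertainty_pct`, `chi_squared` (modulus-weighted statistic
#'   divided by `2N - p`), `n_iterations`, `converged`, `at_bound` (logical
#'   per parameter), `model` (fitted circuit), and `spectrum`.
#'   [tidy()] and [glance()] methods are provided.
#' @examples
#' m <- build_named_circuit("actin")
#' sp <- circuit_impedance(m, 10^seq(-2, 5, length.out = 40))
#' fit <- fit_circuit(sp, m)
#' glance(fit)
#' @export
fit_circuit <- function(spectrum, template, initial = NULL,
                        lower = NULL, upper = NULL,
                        weighting = c("modulus", "unit", "proportional"),
                        n_restarts = 3, restart_seed = 1L, max_iter = 200) {
  weighting <- match.arg(weighting)
  check_spectrum(spectrum)
  theta0 <- circuit_free_params(template)
  p <- length(theta0)
  if (2 * nrow(spectrum) <= p) {
    abort("spectrum too small for the model: need 2N > number of parameters.",
          class = "protoelec_insufficient_data")
  }
  if (!is.null(initial)) {
    bad <- setdiff(names(initial), names(theta0))
    if (length(bad) > 0) {
      abort(sprintf("unknown initial parameter(s): %s", paste(bad, collapse = ", ")),
            class = "protoelec_invalid_spec")
    }
    theta0[names(initial)] <- initial
  }
  lo <- setNames(rep(1e-15, p), names(theta0))
  hi <- setNames(rep(1e+15, p), names(theta0))
  # exponents live in (0, 1]
  is_expo <- grepl("\\.(n)$", names(theta0))
  hi[is_expo] <- 1
  if (!is.null(lower)) lo[names(lower)] <- pmax(lower, 1e-300)
  if (!is.null(upper)) hi[names(upper)] <- upper
  hi[is_expo] <- pmin(hi[is_expo], 1)
  theta0 <- pmin(pmax(theta0, lo), hi)

  resid_fn <- function(log_theta) {
    m <- circuit_set_params(template, exp(log_theta))
    zhat <- circuit_impedance(m, spectrum$freq_hz)
    spectrum_residuals(spectrum, zhat, weighting)
  }

  starts <- list(log(theta0))
  if (n_restarts > 0) {
    jit <- with_seed(restart_seed, {
      lapply(seq_len(n_restarts), function(i) {
        log(theta0) + runif(p, min = -0.5, max = 0.5) * log(10)
      })
    })
    starts <- c(starts, lapply(jit, function(s) pmin(pmax(s, log(lo)), log(hi))))
  }

  best <- NULL
  total_iter <- 0
  for (s in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fn,
                         lower = log(lo), upper = log(hi),
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    total_iter <- total_iter + res$niter
    if (is.null(best) || res$deviance < best$deviance) best <- res
  }
  if (is.null(best)) {
    abort("all fit starts failed.", class = "protoelec_convergence_failure")
  }

  theta_hat <- exp(best$par)
  names(theta_hat) <- names(theta0)
  at_bound <- theta_hat <= lo * (1 + 1e-8) | theta_hat >= hi * (1 - 1e-8)
  dof <- 2 * nrow(spectrum) - p
  chi2 <- best$deviance / dof

  # Curvature-based uncertainties on the log scale translate directly to
  # relative (percent) uncertainties of the estimates.
  rel_pct <- rep(NA_real_, p)
  se_log <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                     error = function(e) rep(NA_real_, p))
  rel_pct <- as.numeric(se_log) * 100
  names(rel_pct) <- names(theta0)

  converged <- best$info %in% 1:4 && !any(!is.finite(theta_hat))
  structure(list(
    params = theta_hat,
    rel_uncertainty_pct = rel_pct,
    chi_squared = chi2,
    n_iterations = total_iter,
    converged = converged,
    at_bound = at_bound,
    message = best$message,
    weighting = weighting,
    model = circuit_set_params(template, theta_hat),
    spectrum = spectrum
  ), class = "eis_fit")
}

#' @export
print.eis_fit <- function(x, ...) {
  cat(sprintf("<eis_fit: %d parameters, chi-squared %.4g, %s in %d iterations>\n",
              length(x$params), x$chi_squared,
              if (x$converged) "converged" else "NOT converged", x$n_iterations))
  print(tidy(x))
  invisible(x)
}

#' Tidy an EIS fit
#'
#' @param x An `eis_fit` from [fit_circuit()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with `term`, `estimate`, `rel_uncertainty_pct`,
#'   `at_bound`; `glance()`: a one-row tibble with `chi_squared`,
#'   `n_iterations`, `converged`, `n_freq`, `n_params`.
#' @method tidy eis_fit
#' @export
tidy.eis_fit <- function(x, ...) {
  tibble(term = names(x$params),
         estimate = unname(x$params),
         rel_uncertainty_pct = unname(x$rel_uncertainty_pct),
         at_bound = unname(x$at_bound))
}

#' @rdname tidy.eis_fit
#' @method glance eis_fit
#' @export
glance.eis_fit <- function(x, ...) {
  tibble(chi_squared = x$chi_squared, n_iterations = x$n_iterations,
         converged = x$converged, n_freq = nrow(x$spectrum),
         n_params = length(x$params))
}

#' Nyquist-plane summary of a spectrum
#'
#' @param spectrum Tibble with `freq_hz`, `z_real_ohm`, `z_imag_ohm`.
#' @return One-row tibble with `z_real_min`, `z_real_max` (ohm) and
#'   `z_imag_peak`, the magnitude of the most negative imaginary part
#'   (reported positive; 0 if the spectrum never goes capacitive).
#' @export
nyquist_summary <- function(spectrum) {
  check_spectrum(spectrum)
  tibble(
    z_real_min = min(spectrum$z_real_ohm),
    z_real_max = max(spectrum$z_real_ohm),
    z_imag_peak = max(0, -min(spectrum$z_imag_ohm))
  )
}

#' Nyquist plot of a spectrum or fit
#'
#' @param spectrum Spectrum tibble; for `autoplot.eis_fit`, the fit object
#'   (data as points, fitted curve as a line).
#' @return A ggplot.
#' @export
plot_nyquist <- function(spectrum) {
  check_spectrum(spectrum)
  ggplot2::ggplot(spectrum, ggplot2::aes(x = .data$z_real_ohm, y = -.data$z_imag_ohm)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Z' (Ω)", y = "-Z'' (Ω)")
}

#' @param object An `eis_fit`.
#' @param ... Unused.
#' @rdname plot_nyquist
#' @method autoplot eis_fit
#' @export
autoplot.eis_fit <- function(object, ...) {
  fitted <- circuit_impedance(object$model, object$spectrum$freq_hz)
  ggplot2::ggplot(object$spectrum,
                  ggplot2::aes(x = .data$z_real_ohm, y = -.data$z_imag_ohm)) +
    ggplot2::geom_point(size = 0.8, colour = "grey30") +
    ggplot2::geom_path(data = fitted, colour = "firebrick") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Z' (Ω)", y = "-Z'' (Ω)",
                  title = sprintf("chi-squared = %.3g", object$chi_squared))
}
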