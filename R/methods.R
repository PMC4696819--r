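# S3 methods for fitted models: print, coef, vcov, logLik, fitted,
# residuals, plus broom-style tidy()/glance() and a ggplot2 autoplot().

#' @export
print.dr_fit <- function(x, ...) {
  cat("<dr_fit> ", x$model$name, " (", x$method, ", ",
      x$response_type, " response)\n", sep = "")
  if (!is.null(x$sharing)) {
    cat("  curves: ", paste(x$curves, collapse = ", "), "\n", sep = "")
  }
  print(tidy.dr_fit(x), n = Inf)
  if (is_ls_like(x)) {
    cat("residual standard error:", format(x$sigma, digits = 5),
        "on", x$df_residual, "degrees of freedom\n")
  }
  cat("log-likelihood:", format(x$loglik, digits = 6),
      if (!x$converged) " (NOT converged)" else "", "\n")
  invisible(x)
}

#' @export
coef.dr_fit <- function(object, ...) object$coefficients

#' @export
vcov.dr_fit <- function(object, ...) object$vcov

#' @export
logLik.dr_fit <- function(object, ...) {
  structure(object$loglik, df = fit_ic_df(object), nobs = object$n,
            class = "logLik")
}

#' @export
fitted.dr_fit <- function(object, ...) object$fitted

#' @export
residuals.dr_fit <- function(object, ...) object$residuals

#' @export
nobs.dr_fit <- function(object, ...) object$n

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' Tidy a dose-response fit into a coefficient table
#'
#' @param x a `dr_fit`.
#' @param conf.int include Wald confidence intervals.
#' @param conf.level confidence level.
#' @param ... unused.
#' @return tibble with one row per estimated parameter: term, estimate,
#'   std.error, statistic, p.value.
#' @export
tidy.dr_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  est <- x$coefficients
  se <- sqrt(pmax(diag(x$vcov), 0))
  stat <- est / se
  df <- x$df_inference
  out <- tibble::tibble(
    term = names(est), estimate = unname(est), std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * stats::pt(-abs(stat), df = df))
  )
  if (conf.int) {
    qv <- stats::qt(1 - (1 - conf.level) / 2, df = df)
    out$conf.low <- out$estimate - qv * out$std.error
    out$conf.high <- out$estimate + qv * out$std.error
  }
  out
}

#' One-row model summary of a dose-response fit
#'
#' @param x a `dr_fit`.
#' @param ... unused.
#' @return tibble: sigma, logLik, AIC, BIC, df.residual, nobs, converged.
#' @export
glance.dr_fit <- function(x, ...) {
  ll <- logLik(x)
  tibble::tibble(
    sigma = x$sigma, logLik = as.numeric(ll),
    AIC = stats::AIC(ll), BIC = stats::BIC(ll),
    df.residual = x$df_residual, nobs = x$n,
    method = x$method, converged = x$converged
  )
}

#' Augment the observation table with fitted values and residuals
#'
#' @param x a `dr_fit`.
#' @param ... unused.
#' @return the fit's data with `.fitted` and `.resid` columns appended.
#' @export
augment.dr_fit <- function(x, ...) {
  out <- x$data
  out$.fitted <- x$fitted
  out$.resid <- x$residuals
  out
}

#' Plot a fitted dose-response curve
#'
#' Per-dose mean responses (points) with the fitted curve and its confidence
#' band on a logarithmic dose axis; dose 0 is drawn at a broken-axis
#' position left of the smallest positive dose.
#'
#' @param object a `dr_fit`.
#' @param level confidence level of the band.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.dr_fit <- function(object, level = 0.95, ...) {
  cd <- dr_curve_data(object, level = level)
  obs <- object$data
  obs$display_dose <- ifelse(obs$dose == 0,
                             min(obs$dose[obs$dose > 0]) / 8, obs$dose)
  ggplot2::ggplot(cd, ggplot2::aes(x = .data$display_dose)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                                      fill = .data$curve), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$prediction,
                                    colour = .data$curve)) +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(y = .data$response,
                                     colour = .data$curve)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose", y = "response") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = if (length(unique(cd$curve)) > 1)
      "right" else "none")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
plot.dr_fit <- function(x, ...) print(autoplot.dr_fit(x, ...))

#' @importFrom rlang .data
NULL
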