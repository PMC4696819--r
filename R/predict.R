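# Fitted values, predictions with confidence/prediction intervals,
# back-fitting doses from observed per-dose means, and plot-ready curve data
# with optional control-normalization.

predict_one_curve <- function(fit, doses, curve, interval, level) {
  model <- fit$model
  theta <- curve_theta_free(fit, curve)
  beta_full <- merge_beta(model, theta)
  mu <- dr_mean(model, doses, beta_full)
  out <- tibble::tibble(curve = curve, dose = doses, prediction = mu)
  if (interval == "none") return(out)

  qv <- stats::qt(1 - (1 - level) / 2, df = fit$df_inference)
  G_free <- dr_mean_gradient(model, doses, beta_full)
  G <- t(apply(G_free, 1, function(g) {
    expand_gradient(fit, curve, stats::setNames(g, model$free_names))
  }))
  if (length(fit$coefficients) == 1) G <- matrix(G, ncol = 1)
  V <- fit$vcov
  tr <- fit$transform
  if (!is.null(tr) && isTRUE(tr$enabled)) {
    # delta intervals on the transformed scale, back-transformed
    lam <- tr$lambda; C <- tr$shift
    gprime <- (mu + C)^(lam - 1)
    se_t <- vapply(seq_along(doses), function(i) {
      delta_se(G[i, ] * gprime[i], V)
    }, numeric(1))
    if (interval == "prediction") se_t <- sqrt(se_t^2 + fit$sigma^2)
    zt <- boxcox_g(mu + C, lam)
    out$lower <- boxcox_ginv(zt - qv * se_t, lam) - C
    out$upper <- boxcox_ginv(zt + qv * se_t, lam) - C
    out$se <- se_t * (mu + C)^(1 - lam)  # back on the response scale
  } else {
    se <- vapply(seq_along(doses), function(i) delta_se(G[i, ], V),
                 numeric(1))
    if (interval == "prediction") {
      if (!is_ls_like(fit)) {
        stop("prediction intervals are only available for continuous fits",
             call. = FALSE)
      }
      se <- sqrt(se^2 + fit$sigma^2)
    }
    out$se <- se
    out$lower <- mu - qv * se
    out$upper <- mu + qv * se
  }
  out
}

#' Predict mean responses from a dose-response fit
#'
#' Point predictions `f(x, beta-hat)` with optional confidence intervals
#' (delta method on the mean) or prediction intervals (adding the residual
#' variance; continuous fits only).  For transform-both-sides fits intervals
#' are computed on the transformed scale and back-transformed.
#'
#' @param fit a `dr_fit`.
#' @param doses doses at which to predict; defaults to the observed doses.
#' @param interval `"none"`, `"confidence"` or `"prediction"`.
#' @param level confidence level.
#' @param curves curve labels (joint fits); default all.
#' @return tibble with columns curve, dose, prediction and, with intervals,
#'   se, lower, upper.
#' @export
dr_predict <- function(fit, doses = NULL,
                       interval = c("none", "confidence", "prediction"),
                       level = 0.95, curves = NULL) {
  interval <- match.arg(interval)
  stopifnot(inherits(fit, "dr_fit"))
  curves <- curves %||% (if (is.null(fit$sharing)) fit$data$curve[1] else
    fit$curves)
  rows <- lapply(curves, function(cv) {
    dz <- doses %||% fit$data$dose[fit$data$curve == cv]
    if (any(dz < 0)) stop("doses must be non-negative", call. = FALSE)
    predict_one_curve(fit, dz, cv, interval, level)
  })
  dplyr::bind_rows(rows)
}

#' @export
predict.dr_fit <- function(object, doses = NULL, ...) {
  dr_predict(object, doses = doses, ...)
}

#' Back-fit doses from observed per-dose mean responses
#'
#' Inverts the fitted (monotone) curve at the observed mean response of each
#' dose group, yielding the dose the fitted model associates with that mean.
#' Means outside the fitted range yield missing entries with a reason.
#'
#' @param fit a `dr_fit` with a monotone fitted curve.
#' @return tibble: curve, dose, mean_response, backfit_dose, note.
#' @export
dr_backfit <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!fit$model$monotone) {
    stop("back-fitting is only supported for monotone models", call. = FALSE)
  }
  curves <- if (is.null(fit$sharing)) fit$data$curve[1] else fit$curves
  rows <- lapply(curves, function(cv) {
    sub <- fit$data[fit$data$curve == cv, , drop = FALSE]
    dm <- dose_means(sub)
    beta_full <- merge_beta(fit$model, curve_theta_free(fit, cv))
    lims <- dr_mean_limits(fit$model, beta_full)
    lo <- min(lims); hi <- max(lims)
    bf <- numeric(nrow(dm)); note <- character(nrow(dm))
    for (i in seq_len(nrow(dm))) {
      m <- dm$response[i]
      if (m >= hi) {
        bf[i] <- NA_real_
        note[i] <- "above upper limit"
      } else if (m <= lo) {
        bf[i] <- NA_real_; note[i] <- "below lower limit"
      } else {
        bf[i] <- tryCatch(
          as.numeric(ed_solve(fit$model, beta_full, m,
                              bracket_hint = sub$dose[sub$dose > 0])),
          error = function(e) NA_real_)
        note[i] <- if (is.na(bf[i])) "no root" else ""
      }
    }
    tibble::tibble(curve = cv, dose = dm$dose, mean_response = dm$response,
                   backfit_dose = bf, note = note)
  })
  dplyr::bind_rows(rows)
}

#' Plot-ready curve data
#'
#' Predictions with confidence bands on a dose grid (by default 100
#' geometric points from half the smallest positive dose to twice the
#' largest, plus dose 0).  When a logarithmic grid is used, the dose-0 row
#' carries a `display_dose` below the grid for broken-axis plotting.
#' Optional normalization divides the predictions by the model-based control
#' mean `f(0)` over `normref` — based on the fit, not the data.
#'
#' @param fit a `dr_fit`.
#' @param n number of grid points.
#' @param normalize divide predictions by `f(0) / normref`.
#' @param normref normalization reference (default 1).
#' @param level confidence level for the band.
#' @param curves curve labels (joint fits); default all.
#' @return tibble: curve, dose, display_dose, prediction, se, lower, upper.
#' @export
dr_curve_data <- function(fit, n = 100, normalize = FALSE, normref = 1,
                          level = 0.95, curves = NULL) {
  stopifnot(inherits(fit, "dr_fit"))
  if (normalize && normref == 0) stop("normref must be nonzero", call. = FALSE)
  pos <- fit$data$dose[fit$data$dose > 0]
  grid <- exp(seq(log(min(pos) / 2), log(max(pos) * 2), length.out = n))
  doses <- c(0, grid)
  out <- dr_predict(fit, doses = doses, interval = "confidence",
                    level = level, curves = curves)
  out$display_dose <- ifelse(out$dose == 0, min(pos) / 8, out$dose)
  if (normalize) {
    for (cv in unique(out$curve)) {
      beta_full <- merge_beta(fit$model, curve_theta_free(fit, cv))
      f0 <- dr_mean(fit$model, 0, beta_full)
      sel <- out$curve == cv
      fac <- f0 / normref
      out$prediction[sel] <- out$prediction[sel] / fac
      out$lower[sel] <- out$lower[sel] / fac
      out$upper[sel] <- out$upper[sel] / fac
      out$se[sel] <- out$se[sel] / abs(fac)
    }
  }
  out
}
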