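# Inverse regression: relative and absolute effective doses, benchmark
# doses, relative potencies.  Standard errors come from the delta method
# using numeric gradients of the inverse map (the root is re-solved at
# perturbed parameters); ratio intervals may alternatively use Fieller's
# approach, and log-scale fits support back-transformed ("fls") intervals.

#' Delta-method standard error
#'
#' @param gradient numeric gradient of the derived quantity with respect to
#'   the estimated parameters.
#' @param covariance covariance matrix of the estimates (conformable).
#' @return the standard error `sqrt(g' V g)`.
#' @export
delta_se <- function(gradient, covariance) {
  if (length(gradient) != nrow(covariance) ||
      nrow(covariance) != ncol(covariance)) {
    stop("gradient and covariance dimensions do not match", call. = FALSE)
  }
  sqrt(max(drop(t(gradient) %*% covariance %*% gradient), 0))
}

#' Fieller confidence interval for a ratio
#'
#' Exact-form interval for the ratio of two (approximately) normally
#' distributed estimates.  May be unbounded when the denominator is not
#' significantly different from zero; unbounded intervals are returned as
#' infinite endpoints with attribute `unbounded = TRUE`.
#'
#' @param num,den numerator and denominator estimates.
#' @param cov2x2 their 2x2 covariance matrix (numerator first).
#' @param df degrees of freedom for the t quantile (`Inf` for z).
#' @param level confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
fieller_interval <- function(num, den, cov2x2, df = Inf, level = 0.95) {
  stopifnot(is.matrix(cov2x2), all(dim(cov2x2) == 2))
  v11 <- cov2x2[1, 1]; v22 <- cov2x2[2, 2]; v12 <- cov2x2[1, 2]
  tq <- stats::qt(1 - (1 - level) / 2, df = df)
  R <- num / den
  if (v22 <= 0) {
    # exact denominator: the ratio is normal with sd sqrt(v11)/|den|
    half <- tq * sqrt(max(v11, 0)) / abs(den)
    out <- c(R - half, R + half)
    attr(out, "unbounded") <- FALSE
    return(out)
  }
  g <- tq^2 * v22 / den^2
  if (g >= 1) {
    out <- c(-Inf, Inf)
    attr(out, "unbounded") <- TRUE
    return(out)
  }
  center <- (R - g * v12 / v22) / (1 - g)
  disc <- v11 - 2 * R * v12 + R^2 * v22 - g * (v11 - v12^2 / v22)
  half <- (tq / (abs(den) * (1 - g))) * sqrt(max(disc, 0))
  out <- c(center - half, center + half)
  attr(out, "unbounded") <- FALSE
  out
}

# solve f(x, beta) = target for x; beta_full on the estimated scale.
# Returns the dose; for non-monotone curves the smallest positive root, with
# all roots in attr "roots".
ed_solve <- function(model, beta_full, target, bracket_hint = NULL) {
  beta_full <- as_full_beta(model, beta_full)
  beta_nat <- natural_beta(model, beta_full)
  if (model$closed_form_ed) {
    cc <- beta_nat[["c"]]; d <- beta_nat[["d"]]
    pi_ <- (target - cc) / (d - cc)
    if (!is.finite(pi_) || pi_ <= 0 || pi_ >= 1) {
      stop("target response lies outside the open interval between the ",
           "curve limits", call. = FALSE)
    }
    return(family_inverse(model, pi_, beta_full))
  }
  # numeric root finding on log-dose
  if ("e" %in% names(beta_nat) && is.finite(beta_nat[["e"]]) &&
      beta_nat[["e"]] > 0) {
    lo <- log(beta_nat[["e"]]) + log(1e-6)
    hi <- log(beta_nat[["e"]]) + log(1e6)
  } else if (!is.null(bracket_hint)) {
    lo <- log(min(bracket_hint) / 1e3)
    hi <- log(max(bracket_hint) * 1e3)
  } else {
    stop("no bracket available for numeric inverse regression", call. = FALSE)
  }
  h <- function(u) dr_mean(model, exp(u), beta_full) - target
  if (model$monotone) {
    hlo <- h(lo); hhi <- h(hi)
    if (!is.finite(hlo) || !is.finite(hhi) || hlo * hhi > 0) {
      stop("no root in the search bracket; the target may be unattainable",
           call. = FALSE)
    }
    root <- stats::uniroot(h, c(lo, hi), tol = 1e-12)$root
    return(exp(root))
  }
  # non-monotone: scan for sign changes, keep all roots, return the smallest
  grid <- seq(lo, hi, length.out = 600)
  hv <- vapply(grid, h, numeric(1))
  ok <- is.finite(hv)
  grid <- grid[ok]; hv <- hv[ok]
  sgn <- sign(hv)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(flips) == 0) {
    exact <- which(hv == 0)
    if (length(exact) > 0) return(exp(grid[exact[1]]))
    stop("no root in the search bracket; the target may be unattainable",
         call. = FALSE)
  }
  roots <- vapply(flips, function(i) {
    exp(stats::uniroot(h, grid[c(i, i + 1)], tol = 1e-12)$root)
  }, numeric(1))
  out <- min(roots)
  attr(out, "roots") <- sort(roots)
  out
}

# target mean response for a relative level alpha on the curve defined by
# beta (estimated scale): (1 - alpha) * limit at dose 0 + alpha * limit at
# infinite dose
relative_target <- function(model, beta_full, alpha) {
  lims <- dr_mean_limits(model, beta_full)
  (1 - alpha) * lims[["at_zero"]] + alpha * lims[["at_inf"]]
}

# ed as a function of the free parameters of one curve; used for the point
# estimate and, re-solved at perturbed parameters, for the delta gradient
make_ed_fun <- function(fit, curve, level, type, hormesis = FALSE) {
  model <- fit$model
  sub <- if (is.null(fit$sharing)) fit$data else
    fit$data[fit$data$curve == curve, , drop = FALSE]
  if (nrow(sub) == 0) sub <- fit$data
  hint <- sub$dose[sub$dose > 0]
  function(theta) {
    beta_full <- merge_beta(model, theta)
    target <- if (type == "relative") {
      relative_target(model, beta_full, level)
    } else {
      level
    }
    ed_solve(model, beta_full, target, bracket_hint = hint)
  }
}

curve_theta_free <- function(fit, curve) {
  if (is.null(fit$sharing)) return(fit$coefficients)
  layout <- joint_layout(fit$model, fit$sharing, fit$curves)
  stats::setNames(joint_curve_theta(fit$coefficients, layout, curve),
                  fit$model$free_names)
}

# point estimate + gradient w.r.t. the fit's (expanded) coefficient vector
ed_with_gradient <- function(fit, curve, level, type, hormesis = FALSE) {
  edf <- make_ed_fun(fit, curve, level, type, hormesis)
  theta <- curve_theta_free(fit, curve)
  est <- edf(theta)
  g_free <- num_gradient(function(t) {
    names(t) <- names(theta)
    tryCatch(as.numeric(edf(t)), error = function(e) NA_real_)
  }, theta)
  names(g_free) <- names(theta)
  g <- expand_gradient(fit, curve, g_free)
  list(estimate = as.numeric(est), gradient = g,
       roots = attr(est, "roots"))
}

#' Effective doses from a fitted dose-response model
#'
#' Relative effective doses ED100a solve
#' \eqn{f(ED) = (1-\alpha)\lim_{x\to 0} f + \alpha \lim_{x\to\infty} f}: the
#' dose producing a 100a% change between the control-side and infinite-dose
#' limits of the curve.  Absolute effective doses solve `f(ED) = y0` for a
#' specified mean response.  Closed-form inversion is used for the
#' log-logistic, log-normal and Weibull families, numeric root finding
#' otherwise (smallest positive root for hormesis curves).  Standard errors
#' are delta-method; since the relative target involves the estimated limits,
#' their uncertainty is propagated through the full gradient.
#'
#' @param fit a `dr_fit`.
#' @param levels for `type = "relative"`: levels in (0, 1) (values >= 1 are
#'   interpreted as percentages); for `type = "absolute"`: target mean
#'   responses strictly between the curve limits.  Negative relative levels
#'   (the hormesis region) require `hormesis = TRUE` and a non-monotone
#'   model.
#' @param type `"relative"` or `"absolute"`.
#' @param interval `"delta"` (t/z Wald) or `"fls"` (delta on the log-dose
#'   scale, back-transformed; requires a `log_e` fit).
#' @param level confidence level.
#' @param curves curve labels (joint fits); default all.
#' @param hormesis allow negative relative levels for hormesis models.
#' @return tibble with one row per curve and level: estimate, se, lower,
#'   upper.
#' @export
dr_ed <- function(fit, levels = 0.5, type = c("relative", "absolute"),
                  interval = c("delta", "fls"), level = 0.95,
                  curves = NULL, hormesis = FALSE) {
  type <- match.arg(type)
  interval <- match.arg(interval)
  stopifnot(inherits(fit, "dr_fit"))
  if (interval == "fls" && !fit$model$log_e) {
    stop("'fls' intervals require a fit with the log-scale location ",
         "parameterization (log_e = TRUE)", call. = FALSE)
  }
  if (type == "relative") {
    levels <- ifelse(abs(levels) >= 1, levels / 100, levels)
    if (any(levels <= 0) && !hormesis) {
      stop("relative levels must lie in (0, 1); negative levels require ",
           "hormesis = TRUE", call. = FALSE)
    }
    if (any(levels <= 0) && fit$model$monotone) {
      stop("negative (hormesis) levels are only meaningful for non-monotone ",
           "models", call. = FALSE)
    }
    if (any(levels >= 1)) stop("relative levels must be below 1", call. = FALSE)
  }
  curves <- curves %||% (if (is.null(fit$sharing)) fit$data$curve[1] else
    fit$curves)
  qv <- stats::qt(1 - (1 - level) / 2, df = fit$df_inference)

  rows <- list()
  for (cv in curves) {
    for (lv in levels) {
      eg <- ed_with_gradient(fit, cv, lv, type, hormesis)
      se <- if (all(is.finite(fit$vcov)) && all(is.finite(eg$gradient))) {
        delta_se(eg$gradient, fit$vcov)
      } else NA_real_
      if (interval == "delta") {
        ci <- eg$estimate + c(-1, 1) * qv * se
      } else {
        se_log <- se / eg$estimate
        ci <- exp(log(eg$estimate) + c(-1, 1) * qv * se_log)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        curve = cv, level = lv, type = type,
        estimate = eg$estimate, se = se,
        lower = ci[1], upper = ci[2], interval = interval
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Benchmark dose estimation
#'
#' Treats benchmark-dose estimation as absolute effective-dose estimation:
#' with background risk `f(0)`, the added-risk BMD solves
#' `f(BMD) = f(0) + BMR` and the excess-risk BMD solves
#' `f(BMD) = f(0) + BMR (1 - f(0))`.  Requires an increasing risk curve.
#' The BMDL is the one-sided lower confidence bound at `level`.
#'
#' @param fit a `dr_fit` (binomial or continuous) with increasing mean.
#' @param bmr benchmark response in (0, 1).
#' @param definition `"added"` or `"excess"`.
#' @param level one-sided confidence level for the BMDL (default 0.95).
#' @param curve curve label for joint fits.
#' @return one-row tibble: bmr, definition, bmd, se, bmdl.
#' @export
dr_bmd <- function(fit, bmr, definition = c("added", "excess"),
                   level = 0.95, curve = NULL) {
  definition <- match.arg(definition)
  stopifnot(inherits(fit, "dr_fit"), bmr > 0, bmr < 1)
  curve <- curve %||% (if (is.null(fit$sharing)) fit$data$curve[1] else
    fit$curves[1])
  model <- fit$model
  theta <- curve_theta_free(fit, curve)
  beta_full <- merge_beta(model, theta)
  lims <- dr_mean_limits(model, beta_full)
  if (!(lims[["at_inf"]] > lims[["at_zero"]])) {
    stop("benchmark dose estimation requires an increasing risk curve",
         call. = FALSE)
  }
  target_of <- function(beta) {
    bg <- dr_mean(model, 0, beta)
    if (definition == "added") bg + bmr else bg + bmr * (1 - bg)
  }
  if (target_of(beta_full) >= lims[["at_inf"]]) {
    stop("benchmark response exceeds the curve's upper limit", call. = FALSE)
  }
  hint <- fit$data$dose[fit$data$dose > 0]
  bmd_of <- function(th) {
    bf <- merge_beta(model, th)
    ed_solve(model, bf, target_of(bf), bracket_hint = hint)
  }
  est <- as.numeric(bmd_of(theta))
  g_free <- num_gradient(function(t) {
    names(t) <- names(theta)
    tryCatch(as.numeric(bmd_of(t)), error = function(e) NA_real_)
  }, theta)
  names(g_free) <- names(theta)
  g <- expand_gradient(fit, curve, g_free)
  se <- if (all(is.finite(fit$vcov)) && all(is.finite(g))) {
    delta_se(g, fit$vcov)
  } else NA_real_
  qv <- stats::qt(level, df = fit$df_inference)
  tibble::tibble(bmr = bmr, definition = definition, bmd = est, se = se,
                 bmdl = max(est - qv * se, 0))
}

#' Compare effective doses of two curves
#'
#' Estimates the relative potency \eqn{\rho(\alpha_1, \alpha_2) =
#' ED_A(100\alpha_1) / ED_B(100\alpha_2)} (or the difference of EDs) from a
#' joint fit, with delta-method, Fieller or back-transformed confidence
#' intervals.
#'
#' @param fit a joint `dr_fit` containing both curves.
#' @param curves character vector of two curve labels `(A, B)`.
#' @param levels numeric pair of relative levels (recycled if length 1).
#' @param operator `"ratio"` or `"difference"`.
#' @param interval `"delta"`, `"fieller"` (ratio only) or `"fls"` (ratio
#'   only, log-scale back-transform).
#' @param level confidence level.
#' @return one-row tibble with estimate, se, lower, upper; Fieller intervals
#'   that are unbounded carry infinite endpoints and `unbounded = TRUE`.
#' @export
dr_ed_compare <- function(fit, curves, levels = c(0.5, 0.5),
                          operator = c("ratio", "difference"),
                          interval = c("delta", "fieller", "fls"),
                          level = 0.95) {
  operator <- match.arg(operator)
  interval <- match.arg(interval)
  stopifnot(inherits(fit, "dr_fit"), length(curves) == 2)
  if (length(levels) == 1) levels <- rep(levels, 2)
  levels <- ifelse(abs(levels) >= 1, levels / 100, levels)
  if (is.null(fit$sharing)) {
    stop("effective-dose comparison requires a joint fit", call. = FALSE)
  }
  if (interval != "delta" && operator == "difference") {
    stop("'", interval, "' intervals apply to ratios only", call. = FALSE)
  }
  if (interval == "fls" && !fit$model$log_e) {
    stop("'fls' intervals require a log_e fit", call. = FALSE)
  }
  eA <- ed_with_gradient(fit, curves[1], levels[1], "relative")
  eB <- ed_with_gradient(fit, curves[2], levels[2], "relative")
  V <- fit$vcov
  qv <- stats::qt(1 - (1 - level) / 2, df = fit$df_inference)
  unbounded <- FALSE
  if (operator == "ratio") {
    est <- eA$estimate / eB$estimate
    g <- eA$gradient / eB$estimate -
      eA$estimate * eB$gradient / eB$estimate^2
    se <- delta_se(g, V)
    if (interval == "delta") {
      ci <- est + c(-1, 1) * qv * se
    } else if (interval == "fieller") {
      vAA <- drop(t(eA$gradient) %*% V %*% eA$gradient)
      vBB <- drop(t(eB$gradient) %*% V %*% eB$gradient)
      vAB <- drop(t(eA$gradient) %*% V %*% eB$gradient)
      ci <- fieller_interval(eA$estimate, eB$estimate,
                             matrix(c(vAA, vAB, vAB, vBB), 2),
                             df = fit$df_inference, level = level)
      unbounded <- isTRUE(attr(ci, "unbounded"))
    } else {
      g_log <- eA$gradient / eA$estimate - eB$gradient / eB$estimate
      se_log <- delta_se(g_log, V)
      ci <- exp(log(est) + c(-1, 1) * qv * se_log)
    }
  } else {
    est <- eA$estimate - eB$estimate
    g <- eA$gradient - eB$gradient
    se <- delta_se(g, V)
    ci <- est + c(-1, 1) * qv * se
  }
  tibble::tibble(
    curve_A = curves[1], curve_B = curves[2],
    level_A = levels[1], level_B = levels[2],
    operator = operator, estimate = est, se = se,
    lower = ci[1], upper = ci[2], interval = interval,
    unbounded = unbounded
  )
}

#' Relative potency across a grid of levels
#'
#' Evaluates the relative potency of two curves at a grid of common levels.
#' Under "parallelism" (shared steepness, proportional location) the ratio is
#' constant across the grid.
#'
#' @inheritParams dr_ed_compare
#' @param alpha_grid relative levels at which to evaluate the potency.
#' @return tibble with one row per grid value: alpha, rho, se, lower, upper.
#' @export
dr_relpot <- function(fit, curves, alpha_grid = seq(0.1, 0.9, by = 0.1),
                      interval = c("delta", "fieller", "fls"),
                      level = 0.95) {
  interval <- match.arg(interval)
  rows <- lapply(alpha_grid, function(a) {
    cmp <- dr_ed_compare(fit, curves, levels = c(a, a), operator = "ratio",
                         interval = interval, level = level)
    tibble::tibble(alpha = a, rho = cmp$estimate, se = cmp$se,
                   lower = cmp$lower, upper = cmp$upper)
  })
  dplyr::bind_rows(rows)
}

#' Model-averaged effective dose
#'
#' Combines effective-dose estimates from several candidate fits of the same
#' data using Akaike weights \eqn{w_k \propto \exp(-\Delta_k/2)}.  The
#' standard error combines within- and between-model variability
#' (\eqn{\sum_k w_k \sqrt{se_k^2 + (ED_k - \bar{ED})^2}}).  Non-converged
#' fits are excluded with a warning.
#'
#' @param fits list of `dr_fit` objects on identical data.
#' @param level relative level (default ED50).
#' @param conf confidence level for the normal-theory interval.
#' @return one-row tibble with the averaged estimate, se and interval; the
#'   per-model table (weights, estimates) is attached as attribute
#'   `"per_model"`.
#' @export
dr_ma_ed <- function(fits, level = 0.5, conf = 0.95) {
  stopifnot(is.list(fits), length(fits) >= 2)
  conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (any(!conv)) {
    warning(sum(!conv), " non-converged fit(s) excluded from model averaging")
    fits <- fits[conv]
  }
  if (length(fits) < 1) stop("no converged fits to average", call. = FALSE)
  for (i in seq_along(fits)[-1]) check_same_data(fits[[1]], fits[[i]])
  labels <- names(fits) %||% vapply(fits, function(f) f$model$name,
                                    character(1))
  aic <- vapply(fits, function(f) -2 * f$loglik + 2 * fit_ic_df(f),
                numeric(1))
  w <- exp(-(aic - min(aic)) / 2)
  w <- w / sum(w)
  eds <- lapply(fits, dr_ed, levels = level)
  est_k <- vapply(eds, function(e) e$estimate[1], numeric(1))
  se_k <- vapply(eds, function(e) e$se[1], numeric(1))
  est <- sum(w * est_k)
  se <- sum(w * sqrt(se_k^2 + (est_k - est)^2))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  out <- tibble::tibble(level = level, estimate = est, se = se,
                        lower = est - z * se, upper = est + z * se)
  attr(out, "per_model") <- tibble::tibble(model = labels, weight = w,
                                           estimate = est_k, se = se_k,
                                           AIC = aic)
  out
}
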