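# Estimation engine: parameter pre-scaling, derivative-free simplex followed
# by a quasi-Newton polish (bounded quasi-Newton when box constraints are
# given), numeric observed information, and the transform-both-sides
# machinery.

BIG <- 1e300

# Minimize obj(theta) starting from `start`, optionally under box constraints.
# Parameters are pre-scaled by max(|start|, 1e-4) so the optimizer works near
# unit scale.  Returns theta, value, convergence flag, active-bound names.
run_optim <- function(obj, start, lower = NULL, upper = NULL,
                      reltol = 1e-10) {
  p <- length(start)
  sc <- pmax(abs(start), 1e-4)
  # exploration outside the admissible region returns a large finite value;
  # NaN warnings from e.g. log of a negative candidate are expected there
  safe <- function(u) {
    v <- suppressWarnings(obj(u * sc))
    if (!is.finite(v)) BIG else v
  }
  u0 <- start / sc
  bounded <- !is.null(lower) || !is.null(upper)
  if (bounded) {
    lo <- if (is.null(lower)) rep(-Inf, p) else lower / sc
    hi <- if (is.null(upper)) rep(Inf, p) else upper / sc
    u0 <- clip(u0, lo, hi)
    res <- stats::optim(u0, safe, method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = 500, factr = 1e4))
    res2 <- stats::optim(res$par, safe, method = "L-BFGS-B",
                         lower = lo, upper = hi,
                         control = list(maxit = 500, factr = 1e4))
    best <- if (res2$value <= res$value) res2 else res
    theta <- best$par * sc
    tol_b <- 1e-8 * pmax(abs(theta), 1)
    active <- (is.finite(lo * sc) & abs(theta - lo * sc) < tol_b) |
      (is.finite(hi * sc) & abs(theta - hi * sc) < tol_b)
    list(theta = theta, value = best$value,
         converged = best$convergence == 0, active_bounds = active)
  } else {
    nm <- stats::optim(u0, safe, method = "Nelder-Mead",
                       control = list(maxit = 500 * p, reltol = 1e-8))
    best <- nm
    # quasi-Newton polish, restarted while it still improves (restarting
    # resets the Hessian approximation, which helps near zero-residual optima)
    gr <- function(u) num_gradient(safe, u)
    for (r in 1:3) {
      bf <- tryCatch(
        stats::optim(best$par, safe, gr = gr, method = "BFGS",
                     control = list(maxit = 500, reltol = reltol)),
        error = function(e) NULL
      )
      if (is.null(bf) || bf$value > best$value) break
      improved <- best$value - bf$value > 1e-15 * (1 + abs(best$value))
      best <- bf
      if (!improved) break
    }
    # Newton polish on the numeric gradient/Hessian; accepted only while it
    # improves the objective
    for (it in 1:2) {
      g <- num_gradient(safe, best$par)
      H <- num_hessian(safe, best$par)
      step <- tryCatch(solve(H, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      cand <- best$par - step
      v <- safe(cand)
      if (!is.finite(v) || v > best$value) break
      best$par <- cand
      best$value <- v
    }
    v0 <- safe(u0)
    list(theta = best$par * sc, value = best$value,
         converged = best$convergence == 0 && best$value <= v0,
         active_bounds = rep(FALSE, p))
  }
}

# ---- transform-both-sides --------------------------------------------------

#' Box-Cox transform specification for transform-both-sides fitting
#'
#' @param lambda transformation exponent; 1 means no transformation, 0 the
#'   logarithm.
#' @param shift constant added to the response and the model function before
#'   transforming; all shifted responses must be positive.
#' @return a `dr_transform` object.
#' @export
dr_transform <- function(lambda, shift = 0) {
  stopifnot(is.numeric(lambda), length(lambda) == 1, is.finite(lambda),
            is.numeric(shift), shift >= 0)
  structure(list(lambda = lambda, shift = shift, enabled = TRUE),
            class = "dr_transform")
}

boxcox_g <- function(y, lambda) {
  if (abs(lambda) < 1e-10) log(y) else (y^lambda - 1) / lambda
}

boxcox_ginv <- function(z, lambda) {
  if (abs(lambda) < 1e-10) exp(z) else (lambda * z + 1)^(1 / lambda)
}

# ---- weighted (possibly transformed) least squares -------------------------

make_ls_objective <- function(model, data, transform) {
  x <- data$dose
  y <- data$response
  w <- data$weight
  if (!is.null(transform) && isTRUE(transform$enabled) &&
      transform$lambda != 1) {
    lam <- transform$lambda
    C <- transform$shift
    if (any(y + C <= 0)) {
      stop("all responses plus the shift constant must be positive for the ",
           "transform-both-sides approach", call. = FALSE)
    }
    gy <- boxcox_g(y + C, lam)
    function(theta) {
      mu <- dr_mean(model, x, merge_beta(model, theta))
      if (any(!is.finite(mu)) || any(mu + C <= 0)) return(NA_real_)
      sum((w * (gy - boxcox_g(mu + C, lam)))^2)
    }
  } else {
    function(theta) {
      mu <- dr_mean(model, x, merge_beta(model, theta))
      if (any(!is.finite(mu))) return(NA_real_)
      sum((w * (y - mu))^2)
    }
  }
}

# covariance from the numeric Hessian of the SS objective: the observed
# information of the normal log-likelihood is Hess(RSS)/(2 sigma^2), hence
# cov = 2 sigma^2 Hess(RSS)^{-1}; singular Hessians yield NA standard errors.
ls_vcov <- function(obj, theta, sigma2) {
  H <- num_hessian(function(t) {
    v <- obj(t); if (!is.finite(v)) BIG else v
  }, theta)
  Vi <- if (all(is.finite(H))) chol_inverse(H / 2) else NULL
  if (is.null(Vi)) {
    matrix(NA_real_, length(theta), length(theta),
           dimnames = list(names(theta), names(theta)))
  } else {
    V <- sigma2 * Vi
    dimnames(V) <- list(names(theta), names(theta))
    V
  }
}

new_dr_fit <- function(model, data, response_type, method, theta, vcov,
                       sigma, loglik, objective_value, converged, starts,
                       transform = NULL, bounds = NULL, active_bounds = NULL,
                       sharing = NULL, curves = NULL, robust = NULL,
                       df_inference = NULL) {
  n <- nrow(data)
  p <- length(theta)
  beta_full <- if (is.null(sharing)) merge_beta(model, theta) else NULL
  fitted <- if (is.null(sharing)) {
    dr_mean(model, data$dose, beta_full)
  } else {
    joint_fitted(model, data, theta, sharing, curves)
  }
  structure(
    list(
      model = model, data = data, response_type = response_type,
      method = method, coefficients = theta, vcov = vcov,
      sigma = sigma, loglik = loglik, n = n, p = p,
      df_residual = n - p,
      df_inference = df_inference %||%
        (if (method %in% c("ls", "robust")) n - p else Inf),
      objective_value = objective_value,
      converged = converged, starts = starts,
      transform = transform, bounds = bounds,
      active_bounds = active_bounds,
      sharing = sharing, curves = curves, robust = robust,
      fitted = fitted, residuals = data$response - fitted
    ),
    class = "dr_fit"
  )
}

#' Fit a dose-response model by (weighted) nonlinear least squares
#'
#' Minimizes the weighted residual sum of squares
#' \eqn{\sum_i w_i^2 (y_i - f(x_i, \beta))^2}, or its transform-both-sides
#' version when a Box-Cox `transform` is supplied.  Starting values come from
#' the data-driven self-starter unless given.  Optimization uses a
#' derivative-free simplex followed by a quasi-Newton polish on pre-scaled
#' parameters; with box constraints a bounded quasi-Newton method is used.
#' The parameter covariance is the scaled inverse of the numeric Hessian of
#' the objective; if that Hessian is singular, standard errors are reported
#' as `NA` rather than failing.
#'
#' @param data data frame with columns `dose`, `response`, optional `weight`
#'   (on the response scale, i.e. reciprocal standard deviations if used for
#'   variance weighting) and optional `curve` (ignored here; see
#'   [dr_fit_joint()]).
#' @param model a [dr_model()] or registry name.
#' @param weights optional numeric vector overriding the `weight` column.
#' @param transform optional [dr_transform()] (or [dr_boxcox()] result).
#' @param lower,upper optional named box constraints on free parameters.
#' @param start optional starting values (named vector over free parameters).
#' @return a `dr_fit` object.
#' @seealso [dr_fit_ml()], [dr_fit_robust()], [dr_fit_joint()]
#' @export
#' @examples
#' d <- dr_simulate("LL.4", c(b = 2, c = 0.1, d = 0.9, e = 3),
#'                  doses = 0.125 * 2^(0:7), reps = 4, sd = 0.05, seed = 11)
#' fit <- dr_fit_ls(d, "LL.4")
#' coef(fit)
dr_fit_ls <- function(data, model, weights = NULL, transform = NULL,
                      lower = NULL, upper = NULL, start = NULL) {
  if (is.character(model)) model <- dr_model(model)
  data <- validate_dr_data(data, "continuous")
  if (!is.null(weights)) data$weight <- weights
  data <- validate_dr_data(data, "continuous")

  starts <- if (is.null(start)) dr_start(model, data) else
    as_dr_starts(model, start)
  theta0 <- starts$beta0

  lo <- expand_bounds(model, lower, -Inf)
  hi <- expand_bounds(model, upper, Inf)
  bounded <- !is.null(lower) || !is.null(upper)
  if (bounded) theta0 <- clip(theta0, lo, hi)

  obj <- make_ls_objective(model, data, transform)
  opt <- run_optim(obj, theta0,
                   lower = if (bounded) lo else NULL,
                   upper = if (bounded) hi else NULL)
  theta <- stats::setNames(opt$theta, model$free_names)

  n <- nrow(data)
  p <- length(theta)
  if (n - p < 1) stop("no residual degrees of freedom", call. = FALSE)
  rss <- opt$value
  sigma2 <- rss / (n - p)
  V <- ls_vcov(obj, theta, sigma2)

  loglik <- ls_loglik(data, rss, transform)
  new_dr_fit(model, data, "continuous", "ls", theta, V,
             sigma = sqrt(sigma2), loglik = loglik,
             objective_value = rss, converged = opt$converged,
             starts = starts, transform = transform,
             bounds = if (bounded) list(lower = lo, upper = hi) else NULL,
             active_bounds = if (bounded)
               stats::setNames(opt$active_bounds, model$free_names) else NULL)
}

# normal log-likelihood at the ML variance, plus the Box-Cox Jacobian term
ls_loglik <- function(data, rss, transform) {
  n <- nrow(data)
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1) + sum(log(data$weight))
  if (!is.null(transform) && isTRUE(transform$enabled)) {
    ll <- ll + (transform$lambda - 1) * sum(log(data$response + transform$shift))
  }
  ll
}

expand_bounds <- function(model, b, default) {
  out <- stats::setNames(rep(default, n_free(model)), model$free_names)
  if (!is.null(b)) {
    if (is.null(names(b))) {
      if (length(b) != n_free(model)) {
        stop("unnamed bounds must cover all free parameters", call. = FALSE)
      }
      out[] <- b
    } else {
      bad <- setdiff(names(b), model$free_names)
      if (length(bad) > 0) stop("bounds for unknown parameter(s): ",
                                paste(bad, collapse = ", "), call. = FALSE)
      out[names(b)] <- b
    }
  }
  out
}

# ---- Box-Cox selection -----------------------------------------------------

#' Select a Box-Cox transform-both-sides exponent
#'
#' Chooses the exponent `lambda` over a grid by maximizing the
#' transform-both-sides profile log-likelihood, including the Jacobian term
#' \eqn{(\lambda - 1) \sum_i \log(y_i + C)}.  The `"profile"` method refits
#' the dose-response model at every grid value; the `"anova"` method replaces
#' the parametric curve with the saturated one-mean-per-dose model (a more
#' robust choice that requires replicate observations).
#'
#' @inheritParams dr_fit_ls
#' @param method `"anova"` or `"profile"`.
#' @param lambda_grid grid of candidate exponents.
#' @param shift shift constant `C`; responses plus `C` must be positive.
#' @return a `dr_transform` with the selected `lambda` and a `profile`
#'   tibble (`lambda`, `loglik`) attached.
#' @export
dr_boxcox <- function(data, model = NULL,
                      method = c("anova", "profile"),
                      lambda_grid = seq(-2, 2, by = 0.1), shift = 0) {
  method <- match.arg(method)
  data <- validate_dr_data(data, "continuous")
  y <- data$response
  if (any(y + shift <= 0)) {
    stop("responses plus the shift constant must be positive", call. = FALSE)
  }
  n <- nrow(data)
  jac <- sum(log(y + shift))

  if (method == "anova") {
    grp <- interaction(data$dose, data$curve, drop = TRUE)
    if (sum(table(grp) >= 2) < 2) {
      stop("the anova method requires replicates at two or more doses",
           call. = FALSE)
    }
    ll <- vapply(lambda_grid, function(lam) {
      z <- boxcox_g(y + shift, lam)
      rss <- sum((z - stats::ave(z, grp))^2)
      -n / 2 * log(rss / n) + (lam - 1) * jac
    }, numeric(1))
  } else {
    if (is.null(model)) stop("the profile method requires 'model'",
                             call. = FALSE)
    if (is.character(model)) model <- dr_model(model)
    warm <- dr_start(model, data)$beta0
    ll <- numeric(length(lambda_grid))
    for (i in seq_along(lambda_grid)) {
      lam <- lambda_grid[i]
      fit <- tryCatch(
        dr_fit_ls(data, model, transform = dr_transform(lam, shift),
                  start = warm),
        error = function(e) NULL
      )
      if (is.null(fit)) { ll[i] <- -Inf; next }
      warm <- stats::coef(fit)
      ll[i] <- -n / 2 * log(fit$objective_value / n) + (lam - 1) * jac
    }
  }
  best <- which.max(ll)
  out <- dr_transform(lambda_grid[best], shift)
  out$method <- method
  out$profile <- tibble::tibble(lambda = lambda_grid, loglik = ll)
  out
}
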