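# Joint fitting of several dose-response curves with parameter sharing:
# each model parameter is either "common" (one value across all curves) or
# "per-curve" (one value per curve label).  The objective is the sum of the
# per-curve objectives over the expanded parameter vector.

joint_layout <- function(model, sharing, levels) {
  free <- model$free_names
  if (is.null(sharing)) {
    sharing <- stats::setNames(rep("per-curve", length(free)), free)
  }
  if (is.null(names(sharing))) {
    stop("'sharing' must be a named vector over the free parameters",
         call. = FALSE)
  }
  full_sharing <- stats::setNames(rep("per-curve", length(free)), free)
  bad <- setdiff(names(sharing), free)
  if (length(bad) > 0) {
    stop("sharing given for unknown/fixed parameter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!all(sharing %in% c("common", "per-curve"))) {
    stop("sharing modes must be 'common' or 'per-curve'", call. = FALSE)
  }
  full_sharing[names(sharing)] <- sharing

  expanded <- character(0)
  for (p in free) {
    expanded <- c(expanded, if (full_sharing[[p]] == "common") p else
      paste(p, levels, sep = ":"))
  }
  map <- lapply(levels, function(l) {
    stats::setNames(
      ifelse(full_sharing[free] == "common", free, paste(free, l, sep = ":")),
      free
    )
  })
  names(map) <- levels
  list(sharing = full_sharing, expanded = expanded, map = map,
       levels = levels)
}

joint_curve_theta <- function(theta_exp, layout, curve) {
  stats::setNames(theta_exp[layout$map[[curve]]],
                  names(layout$map[[curve]]))
}

joint_fitted <- function(model, data, theta_exp, sharing, curves) {
  layout <- joint_layout(model, sharing, curves)
  out <- numeric(nrow(data))
  for (l in curves) {
    idx <- data$curve == l
    th <- joint_curve_theta(theta_exp, layout, l)
    out[idx] <- dr_mean(model, data$dose[idx], merge_beta(model, th))
  }
  out
}

#' Fit one model jointly to several dose-response curves
#'
#' Fits a single model family to data carrying curve labels, with each free
#' parameter either shared across curves (`"common"`) or estimated separately
#' per curve (`"per-curve"`, the default).  The expanded coefficients are
#' named `"parameter:curve"`, and the covariance spans all of them, enabling
#' comparisons between curves ([dr_compparm()], [dr_ed_compare()]).
#'
#' @inheritParams dr_fit_ls
#' @param sharing named character vector over free parameters with values
#'   `"common"` or `"per-curve"`; unnamed parameters default to per-curve.
#' @param family `"gaussian"` (least squares), `"binomial"` or `"poisson"`.
#' @param start optional named vector over the expanded parameters.
#' @return a `dr_fit` object with `sharing` and `curves` fields.
#' @export
#' @examples
#' d <- dr_simulate("LL.4", c(b = 2, c = 0.1, d = 0.9, e = 2),
#'                  doses = 0.125 * 2^(0:7), reps = 3, sd = 0.05,
#'                  curves = list(A = c(b = 2, c = 0.1, d = 0.9, e = 2),
#'                                B = c(b = 2, c = 0.1, d = 0.9, e = 6)),
#'                  seed = 5)
#' fit <- dr_fit_joint(d, "LL.4",
#'                     sharing = c(b = "common", c = "common", d = "common"))
#' coef(fit)
dr_fit_joint <- function(data, model, sharing = NULL,
                         family = c("gaussian", "binomial", "poisson"),
                         weights = NULL, transform = NULL, start = NULL) {
  family <- match.arg(family)
  if (is.character(model)) model <- dr_model(model)
  rtype <- switch(family, gaussian = "continuous", binomial = "binomial",
                  poisson = "poisson")
  data <- validate_dr_data(data, rtype)
  if (!is.null(weights)) data$weight <- weights
  curves <- sort(unique(data$curve))
  layout <- joint_layout(model, sharing, curves)

  # per-curve observation count must support the per-curve parameters
  n_percurve <- sum(layout$sharing == "per-curve")
  for (l in curves) {
    if (sum(data$curve == l) < n_percurve) {
      stop("curve '", l, "' has fewer observations than per-curve parameters",
           call. = FALSE)
    }
  }

  sub_objs <- lapply(curves, function(l) {
    sub <- data[data$curve == l, , drop = FALSE]
    if (family == "gaussian") make_ls_objective(model, sub, transform)
    else make_ml_objective(model, sub,
                           if (family == "binomial") "binomial" else "poisson")
  })
  names(sub_objs) <- curves

  obj <- function(theta_exp) {
    names(theta_exp) <- layout$expanded
    tot <- 0
    for (l in curves) {
      v <- sub_objs[[l]](joint_curve_theta(theta_exp, layout, l))
      if (!is.finite(v)) return(NA_real_)
      tot <- tot + v
    }
    tot
  }

  if (is.null(start)) {
    per_curve_starts <- lapply(curves, function(l) {
      sub <- data[data$curve == l, , drop = FALSE]
      tryCatch(dr_start(model, sub)$beta0,
               error = function(e) dr_start(model, data)$beta0)
    })
    names(per_curve_starts) <- curves
    theta0 <- stats::setNames(numeric(length(layout$expanded)),
                              layout$expanded)
    for (p in model$free_names) {
      if (layout$sharing[[p]] == "common") {
        theta0[p] <- mean(vapply(per_curve_starts, `[[`, numeric(1), p))
      } else {
        for (l in curves) {
          theta0[paste(p, l, sep = ":")] <- per_curve_starts[[l]][[p]]
        }
      }
    }
    starts <- structure(list(beta0 = theta0, method = "linearization",
                             diagnostics = list()), class = "dr_starts")
  } else {
    if (is.null(names(start)) && length(start) == length(layout$expanded)) {
      names(start) <- layout$expanded
    }
    missing <- setdiff(layout$expanded, names(start))
    if (length(missing) > 0) {
      stop("user starting values missing for: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    starts <- structure(list(beta0 = start[layout$expanded], method = "user",
                             diagnostics = list()), class = "dr_starts")
  }

  opt <- run_optim(obj, starts$beta0)
  theta <- stats::setNames(opt$theta, layout$expanded)
  n <- nrow(data); p <- length(theta)

  if (family == "gaussian") {
    rss <- opt$value
    sigma2 <- rss / (n - p)
    V <- ls_vcov(obj, theta, sigma2)
    loglik <- ls_loglik(data, rss, transform)
    method <- "ls"; sigma <- sqrt(sigma2)
  } else {
    H <- num_hessian(function(t) {
      v <- obj(t); if (!is.finite(v)) BIG else v
    }, theta)
    Vi <- if (all(is.finite(H))) chol_inverse(H) else NULL
    V <- if (is.null(Vi)) {
      matrix(NA_real_, p, p, dimnames = list(names(theta), names(theta)))
    } else {
      dimnames(Vi) <- list(names(theta), names(theta)); Vi
    }
    loglik <- -opt$value
    method <- paste0("ml_", family); sigma <- NA_real_
  }

  new_dr_fit(model, data, rtype, method, theta, V, sigma, loglik,
             objective_value = opt$value, converged = opt$converged,
             starts = starts, transform = transform,
             sharing = layout$sharing, curves = curves)
}

# full (estimated-scale) parameter vector for one curve of any fit
curve_beta <- function(fit, curve = NULL) {
  if (is.null(fit$sharing)) {
    merge_beta(fit$model, fit$coefficients)
  } else {
    curve <- curve %||% fit$curves[1]
    layout <- joint_layout(fit$model, fit$sharing, fit$curves)
    merge_beta(fit$model, joint_curve_theta(fit$coefficients, layout, curve))
  }
}

# gradient-expansion map: free-parameter gradient -> expanded-theta gradient
expand_gradient <- function(fit, curve, g_free) {
  if (is.null(fit$sharing)) return(g_free)
  layout <- joint_layout(fit$model, fit$sharing, fit$curves)
  out <- stats::setNames(numeric(length(fit$coefficients)),
                         names(fit$coefficients))
  map <- layout$map[[curve]]
  out[map] <- out[map] + g_free[names(map)]
  out
}
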