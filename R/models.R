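# Built-in dose-response mean functions under the unified (b, c, d, e, f)
# parameterization: b steepness, c/d lower and upper limits, e an ED50-like
# location, f an asymmetry or hormesis parameter.  The multistage model uses
# (b1, b2, b3, c, d) and the fractional-polynomial model uses (b, c, d, e)
# with b, e acting as polynomial coefficients.

# ---- family mean functions (vectorized over x, dose 0 handled analytically) --

ll_mean <- function(x, beta, constants) {
  b <- beta[["b"]]; cc <- beta[["c"]]; d <- beta[["d"]]
  e <- beta[["e"]]; f <- beta[["f"]]
  v <- numeric(length(x)); pos <- x > 0
  t <- exp(b * (log(x[pos]) - log(e)))
  v[pos] <- cc + (d - cc) / (1 + t)^f
  if (any(!pos)) {
    v[!pos] <- if (b > 0) d else if (b < 0) cc else cc + (d - cc) / 2^f
  }
  v
}

bc_mean <- function(x, beta, constants) {
  b <- beta[["b"]]; cc <- beta[["c"]]; d <- beta[["d"]]
  e <- beta[["e"]]; f <- beta[["f"]]
  v <- numeric(length(x)); pos <- x > 0
  v[pos] <- cc + (d - cc + f * x[pos]) /
    (1 + exp(b * (log(x[pos]) - log(e))))
  if (any(!pos)) v[!pos] <- if (b > 0) d else cc
  v
}

crs_mean <- function(x, beta, constants) {
  b <- beta[["b"]]; cc <- beta[["c"]]; d <- beta[["d"]]
  e <- beta[["e"]]; f <- beta[["f"]]
  alpha <- constants[["alpha"]]
  v <- numeric(length(x)); pos <- x > 0
  xx <- x[pos]
  v[pos] <- cc + (d - cc + f * exp(-1 / xx^alpha)) /
    (1 + exp(b * (log(xx) - log(e))))
  if (any(!pos)) v[!pos] <- if (b > 0) d else cc
  v
}

fpl_mean <- function(x, beta, constants) {
  b <- beta[["b"]]; cc <- beta[["c"]]; d <- beta[["d"]]; e <- beta[["e"]]
  p1 <- constants[["p1"]]; p2 <- constants[["p2"]]
  z <- log(x + 1)
  v <- numeric(length(x)); pos <- z > 0
  eta <- b * z[pos]^p1 + e * z[pos]^p2
  v[pos] <- cc + (d - cc) / (1 + exp(eta))
  if (any(!pos)) {
    # limit of eta as z -> 0+: the most negative exponent dominates
    ord <- order(c(p1, p2))
    coefs <- c(b, e)[ord]; ps <- sort(c(p1, p2))
    lim <- 0
    for (i in 1:2) {
      if (ps[i] < 0 && coefs[i] != 0) { lim <- sign(coefs[i]) * Inf; break }
    }
    v[!pos] <- cc + (d - cc) / (1 + exp(lim))
  }
  v
}

ln_mean <- function(x, beta, constants) {
  b <- beta[["b"]]; cc <- beta[["c"]]; d <- beta[["d"]]; e <- beta[["e"]]
  v <- numeric(length(x)); pos <- x > 0
  v[pos] <- cc + (d - cc) * stats::pnorm(b * (log(x[pos]) - log(e)))
  if (any(!pos)) v[!pos] <- if (b > 0) cc else if (b < 0) d else cc + (d - cc) / 2
  v
}

w1_mean <- function(x, beta, constants) {
  b <- beta[["b"]]; cc <- beta[["c"]]; d <- beta[["d"]]; e <- beta[["e"]]
  v <- numeric(length(x)); pos <- x > 0
  v[pos] <- cc + (d - cc) * exp(-exp(b * (log(x[pos]) - log(e))))
  if (any(!pos)) v[!pos] <- if (b > 0) d else if (b < 0) cc else cc + (d - cc) * exp(-1)
  v
}

w2_mean <- function(x, beta, constants) {
  b <- beta[["b"]]; cc <- beta[["c"]]; d <- beta[["d"]]; e <- beta[["e"]]
  v <- numeric(length(x)); pos <- x > 0
  v[pos] <- cc + (d - cc) * (1 - exp(-exp(b * (log(x[pos]) - log(e)))))
  if (any(!pos)) v[!pos] <- if (b > 0) cc else if (b < 0) d else cc + (d - cc) * (1 - exp(-1))
  v
}

gam_mean <- function(x, beta, constants) {
  b <- beta[["b"]]; cc <- beta[["c"]]; d <- beta[["d"]]; e <- beta[["e"]]
  # gamma cdf with shape e, scale 1, evaluated at b * x; requires b > 0, e > 0
  cc + (d - cc) * stats::pgamma(pmax(b * x, 0), shape = e, scale = 1)
}

multi_mean <- function(x, beta, constants) {
  b1 <- beta[["b1"]]; b2 <- beta[["b2"]]; b3 <- beta[["b3"]]
  cc <- beta[["c"]]; d <- beta[["d"]]
  cc + (d - cc) * exp(-b1 - b2 * x - b3 * x^2)
}

nec_mean <- function(x, beta, constants) {
  b <- beta[["b"]]; cc <- beta[["c"]]; d <- beta[["d"]]; e <- beta[["e"]]
  ifelse(x > e, cc + (d - cc) * exp(b * (x - e)), d)
}

# ---- family metadata -------------------------------------------------------

FP_EXPONENT_GRID <- c(-2, -1, -0.5, 0.5, 1, 2, 3)

.families <- list(
  llogistic = list(
    params = c("b", "c", "d", "e", "f"), mean = ll_mean,
    scale_invariant = TRUE, monotone = TRUE, closed_form_ed = TRUE,
    log_e_ok = TRUE, constants = character()
  ),
  braincousens = list(
    params = c("b", "c", "d", "e", "f"), mean = bc_mean,
    scale_invariant = FALSE, monotone = FALSE, closed_form_ed = FALSE,
    log_e_ok = TRUE, constants = character()
  ),
  cedergreen = list(
    params = c("b", "c", "d", "e", "f"), mean = crs_mean,
    scale_invariant = FALSE, monotone = FALSE, closed_form_ed = FALSE,
    log_e_ok = TRUE, constants = "alpha"
  ),
  fplogistic = list(
    params = c("b", "c", "d", "e"), mean = fpl_mean,
    scale_invariant = FALSE, monotone = TRUE, closed_form_ed = FALSE,
    log_e_ok = FALSE, constants = c("p1", "p2")
  ),
  lnormal = list(
    params = c("b", "c", "d", "e"), mean = ln_mean,
    scale_invariant = TRUE, monotone = TRUE, closed_form_ed = TRUE,
    log_e_ok = TRUE, constants = character()
  ),
  weibull1 = list(
    params = c("b", "c", "d", "e"), mean = w1_mean,
    scale_invariant = TRUE, monotone = TRUE, closed_form_ed = TRUE,
    log_e_ok = TRUE, constants = character()
  ),
  weibull2 = list(
    params = c("b", "c", "d", "e"), mean = w2_mean,
    scale_invariant = TRUE, monotone = TRUE, closed_form_ed = TRUE,
    log_e_ok = TRUE, constants = character()
  ),
  gammadr = list(
    params = c("b", "c", "d", "e"), mean = gam_mean,
    scale_invariant = FALSE, monotone = TRUE, closed_form_ed = FALSE,
    log_e_ok = FALSE, constants = character()
  ),
  multistage = list(
    params = c("b1", "b2", "b3", "c", "d"), mean = multi_mean,
    scale_invariant = FALSE, monotone = TRUE, closed_form_ed = FALSE,
    log_e_ok = FALSE, constants = character()
  ),
  nec = list(
    params = c("b", "c", "d", "e"), mean = nec_mean,
    scale_invariant = FALSE, monotone = TRUE, closed_form_ed = FALSE,
    log_e_ok = TRUE, constants = character()
  )
)

# registry: model name -> family + default fixed mask
.registry <- list(
  LL.2  = list(family = "llogistic", fixed = c(c = 0, d = 1, f = 1)),
  LL.3  = list(family = "llogistic", fixed = c(c = 0, f = 1)),
  LL.4  = list(family = "llogistic", fixed = c(f = 1)),
  LL.5  = list(family = "llogistic", fixed = c()),
  LN.2  = list(family = "lnormal",   fixed = c(c = 0, d = 1)),
  LN.3  = list(family = "lnormal",   fixed = c(c = 0)),
  LN.4  = list(family = "lnormal",   fixed = c()),
  W1.2  = list(family = "weibull1",  fixed = c(c = 0, d = 1)),
  W1.3  = list(family = "weibull1",  fixed = c(c = 0)),
  W1.4  = list(family = "weibull1",  fixed = c()),
  W2.2  = list(family = "weibull2",  fixed = c(c = 0, d = 1)),
  W2.3  = list(family = "weibull2",  fixed = c(c = 0)),
  W2.4  = list(family = "weibull2",  fixed = c()),
  BC.4  = list(family = "braincousens", fixed = c(c = 0)),
  BC.5  = list(family = "braincousens", fixed = c()),
  CRS.4 = list(family = "cedergreen",   fixed = c(c = 0)),
  CRS.5 = list(family = "cedergreen",   fixed = c()),
  FPL.4 = list(family = "fplogistic",   fixed = c()),
  GAM.4 = list(family = "gammadr",      fixed = c()),
  MULTI.3 = list(family = "multistage", fixed = c()),
  NEC.4 = list(family = "nec",          fixed = c())
)

#' List the built-in dose-response models
#'
#' @return A tibble with one row per registry name: the model name, the family
#'   it belongs to, its parameter names, the parameters fixed by the
#'   abbreviation, and any required constants.
#' @export
#' @examples
#' dr_models()
dr_models <- function() {
  tibble::tibble(
    name = names(.registry),
    family = vapply(.registry, function(r) r$family, character(1)),
    parameters = vapply(.registry, function(r) {
      paste(.families[[r$family]]$params, collapse = ", ")
    }, character(1)),
    fixed = vapply(.registry, function(r) {
      if (length(r$fixed) == 0) "" else
        paste(names(r$fixed), r$fixed, sep = "=", collapse = ", ")
    }, character(1)),
    constants = vapply(.registry, function(r) {
      paste(.families[[r$family]]$constants, collapse = ", ")
    }, character(1))
  )
}

#' Construct a dose-response model specification
#'
#' Builds a `dr_model` object for one of the built-in families, addressed by
#' its registry name (see [dr_models()]).  Parameters may be fixed a priori at
#' given values via `fixed`; fixed parameters are not estimated.  The
#' hierarchy of log-logistic abbreviations corresponds to successive fixings:
#' `LL.4` is `LL.5` with `f = 1`, `LL.3` additionally fixes `c = 0`, and
#' `LL.2` also fixes `d = 1`.
#'
#' Sign conventions: for the log-logistic and Weibull families `b > 0` gives a
#' curve decreasing from `d` at dose 0 towards `c`; the log-normal curve as
#' parameterized here is increasing for `b > 0`; the gamma model requires
#' `b > 0` (shape `e`, scale 1) and is increasing from `c` to `d`.
#'
#' @param name registry name, e.g. `"LL.4"`, `"W1.4"`, `"CRS.5"`.
#' @param fixed named numeric vector of parameters to fix (e.g.
#'   `c(c = 0, d = 1)`), merged on top of the fixings implied by `name`.
#' @param constants named list of model constants: `alpha` in (0, 1) for the
#'   Cedergreen-Ritz-Streibig hormesis model, exponents `p1`, `p2` (from the
#'   grid -2, -1, -0.5, 0.5, 1, 2, 3) for the fractional-polynomial model.
#' @param log_e if `TRUE` the location parameter is estimated on the log scale
#'   (the estimated `e` slot holds log ED50); useful for small datasets and a
#'   prerequisite for back-transformed ("fls") confidence intervals.
#' @return An object of class `dr_model`.
#' @export
#' @examples
#' dr_model("LL.4")
#' dr_model("LL.5", fixed = c(f = 1))  # identical mean function to LL.4
#' dr_model("CRS.5", constants = list(alpha = 0.25))
dr_model <- function(name, fixed = NULL, constants = list(), log_e = FALSE) {
  if (!name %in% names(.registry)) {
    stop("unknown model '", name, "'; available models: ",
         paste(names(.registry), collapse = ", "), call. = FALSE)
  }
  reg <- .registry[[name]]
  fam <- .families[[reg$family]]
  params <- fam$params

  fixed_mask <- stats::setNames(rep(NA_real_, length(params)), params)
  if (length(reg$fixed) > 0) fixed_mask[names(reg$fixed)] <- reg$fixed
  if (!is.null(fixed) && length(fixed) > 0) {
    if (is.null(names(fixed)) || any(!nzchar(names(fixed)))) {
      stop("'fixed' must be a named vector over the model parameters",
           call. = FALSE)
    }
    bad <- setdiff(names(fixed), params)
    if (length(bad) > 0) {
      stop("unknown parameter(s) in 'fixed': ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    fixed_mask[names(fixed)] <- fixed
  }
  free <- params[is.na(fixed_mask)]
  if (length(free) == 0) stop("all parameters fixed; nothing to estimate",
                              call. = FALSE)

  missing_const <- setdiff(fam$constants, names(constants))
  if (length(missing_const) > 0) {
    stop("model '", name, "' requires constant(s): ",
         paste(missing_const, collapse = ", "), call. = FALSE)
  }
  if ("alpha" %in% fam$constants) {
    a <- constants[["alpha"]]
    if (!is.numeric(a) || length(a) != 1 || a <= 0 || a >= 1) {
      stop("constant 'alpha' must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  if (all(c("p1", "p2") %in% fam$constants)) {
    for (pn in c("p1", "p2")) {
      if (!constants[[pn]] %in% FP_EXPONENT_GRID) {
        stop("exponent '", pn, "' must be one of ",
             paste(FP_EXPONENT_GRID, collapse = ", "), call. = FALSE)
      }
    }
  }
  if (log_e && !fam$log_e_ok) {
    stop("log-scale location parameterization is not available for model '",
         name, "'", call. = FALSE)
  }
  # admissibility of dose-scale fixings
  if ("e" %in% names(fixed_mask) && !is.na(fixed_mask[["e"]]) && !log_e &&
      reg$family != "fplogistic" && fixed_mask[["e"]] <= 0) {
    stop("fixed value for 'e' must be positive", call. = FALSE)
  }

  structure(
    list(
      name = name,
      family = reg$family,
      param_names = params,
      fixed = fixed_mask,
      free_names = free,
      constants = constants,
      log_e = log_e,
      scale_invariant = fam$scale_invariant,
      monotone = fam$monotone,
      closed_form_ed = fam$closed_form_ed
    ),
    class = "dr_model"
  )
}

#' @export
print.dr_model <- function(x, ...) {
  cat("<dr_model> ", x$name, " (", x$family, ")\n", sep = "")
  cat("  parameters: ", paste(x$param_names, collapse = ", "), "\n", sep = "")
  fx <- x$fixed[!is.na(x$fixed)]
  if (length(fx) > 0) {
    cat("  fixed: ", paste(names(fx), fx, sep = " = ", collapse = ", "),
        "\n", sep = "")
  }
  if (length(x$constants) > 0) {
    cat("  constants: ",
        paste(names(x$constants), unlist(x$constants), sep = " = ",
              collapse = ", "), "\n", sep = "")
  }
  if (x$log_e) cat("  location parameter estimated on the log scale\n")
  invisible(x)
}

n_free <- function(model) length(model$free_names)

# merge a reduced (free-only) vector with the fixed mask -> full named vector
merge_beta <- function(model, theta) {
  full <- model$fixed
  if (is.null(names(theta))) names(theta) <- model$free_names
  full[model$free_names] <- theta[model$free_names]
  full
}

reduce_beta <- function(model, beta) {
  if (is.null(names(beta))) names(beta) <- model$param_names
  beta[model$free_names]
}

# accept a full-length, reduced (free-only), or named partial beta; return a
# full named vector with fixed values merged in
as_full_beta <- function(model, beta) {
  p_all <- length(model$param_names)
  if (is.null(names(beta))) {
    if (length(beta) == p_all) {
      return(stats::setNames(beta, model$param_names))
    }
    if (length(beta) == n_free(model)) return(merge_beta(model, beta))
    stop("unnamed parameter vector has length ", length(beta), "; expected ",
         p_all, " (full) or ", n_free(model), " (free only)", call. = FALSE)
  }
  bad <- setdiff(names(beta), model$param_names)
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  full <- model$fixed
  full[names(beta)] <- beta
  if (any(is.na(full))) {
    stop("parameter(s) missing a value: ",
         paste(names(full)[is.na(full)], collapse = ", "), call. = FALSE)
  }
  full
}

# full beta in *natural* scale (exp-transforms the location if log_e)
natural_beta <- function(model, beta_full) {
  if (model$log_e && "e" %in% names(beta_full)) {
    beta_full[["e"]] <- exp(beta_full[["e"]])
  }
  beta_full
}

#' Evaluate a dose-response mean function
#'
#' Computes `f(x, beta)` for a built-in model.  Dose 0 is handled through the
#' analytic limit of the mean function, never by perturbing the dose.
#'
#' @param model a [dr_model()] specification.
#' @param x numeric vector of doses, all `>= 0`.
#' @param beta parameter vector: either the full vector in parameter order or
#'   only the free parameters (fixed values are merged in).
#' @return numeric vector of mean responses, same length as `x`.
#' @export
#' @examples
#' m <- dr_model("LL.4")
#' dr_mean(m, c(0, 10), c(b = 1, c = 0, d = 1, e = 10))
dr_mean <- function(model, x, beta) {
  stopifnot(inherits(model, "dr_model"))
  if (any(x < 0)) stop("doses must be non-negative", call. = FALSE)
  beta <- natural_beta(model, as_full_beta(model, beta))
  .families[[model$family]]$mean(x, beta, model$constants)
}

#' Asymptotic limits of a dose-response curve
#'
#' Returns the analytic limits of the mean function at dose 0 and as the dose
#' tends to infinity.  For most families these are the parameters `c` and `d`
#' ordered by the sign of `b`; for the hormesis families (Brain-Cousens,
#' Cedergreen-Ritz-Streibig) the low-dose bump vanishes at both extremes.
#'
#' @inheritParams dr_mean
#' @return named numeric vector `c(at_zero = , at_inf = )`.
#' @export
dr_mean_limits <- function(model, beta) {
  beta <- natural_beta(model, as_full_beta(model, beta))
  fam <- model$family
  b <- if ("b" %in% names(beta)) beta[["b"]] else NA_real_
  cc <- beta[["c"]]; d <- beta[["d"]]
  lims <- switch(fam,
    llogistic = ,
    weibull1 = if (b > 0) c(d, cc) else c(cc, d),
    lnormal = ,
    weibull2 = if (b > 0) c(cc, d) else c(d, cc),
    gammadr = c(cc, d),
    braincousens = ,
    cedergreen = c(if (b > 0) d else cc, cc),
    nec = c(d, if (b < 0) cc else Inf),
    multistage = {
      at0 <- cc + (d - cc) * exp(-beta[["b1"]])
      atInf <- if (beta[["b2"]] > 0 || beta[["b3"]] > 0) cc else at0
      c(at0, atInf)
    },
    fplogistic = {
      at0 <- .families$fplogistic$mean(0, beta, model$constants)
      # sign of the leading polynomial term decides the infinite-dose limit
      pmax_ <- max(model$constants$p1, model$constants$p2)
      lead <- if (model$constants$p1 > model$constants$p2) beta[["b"]] else beta[["e"]]
      atInf <- if (lead > 0) cc else if (lead < 0) d else at0
      c(at0, atInf)
    }
  )
  stats::setNames(lims, c("at_zero", "at_inf"))
}

#' Gradient of the mean function with respect to the free parameters
#'
#' Central finite differences with relative step on the estimated (possibly
#' log-scale) parameters; entries for fixed parameters are omitted.
#'
#' @inheritParams dr_mean
#' @return matrix with `length(x)` rows and one named column per free
#'   parameter.
#' @export
dr_mean_gradient <- function(model, x, beta) {
  beta_full <- as_full_beta(model, beta)
  theta <- reduce_beta(model, beta_full)
  h <- fd_step(theta)
  G <- matrix(NA_real_, length(x), length(theta),
              dimnames = list(NULL, names(theta)))
  for (j in seq_along(theta)) {
    tp <- theta; tm <- theta
    tp[j] <- theta[j] + h[j]
    tm[j] <- theta[j] - h[j]
    G[, j] <- (dr_mean(model, x, merge_beta(model, tp)) -
                 dr_mean(model, x, merge_beta(model, tm))) / (2 * h[j])
  }
  if (any(!is.finite(G))) {
    warning("non-finite mean gradient; parameter vector may be inadmissible")
  }
  G
}

# closed-form inverse of the "fraction of span" map for families that have
# one: given pi = (f(x) - c)/(d - c), return x.  pi must lie in (0, 1).
family_inverse <- function(model, pi_, beta_full) {
  beta <- natural_beta(model, beta_full)
  b <- beta[["b"]]; e <- beta[["e"]]
  switch(model$family,
    llogistic = {
      f <- beta[["f"]]
      u <- pi_^(-1 / f) - 1
      e * u^(1 / b)
    },
    lnormal = e * exp(stats::qnorm(pi_) / b),
    weibull1 = e * (-log(pi_))^(1 / b),
    weibull2 = e * (-log(1 - pi_))^(1 / b),
    stop("no closed-form inverse for family ", model$family, call. = FALSE)
  )
}
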