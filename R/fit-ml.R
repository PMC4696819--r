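# Maximum likelihood fitting for binomial (quantal) and count responses.
# The mean of the response is the dose-response function itself; the
# covariance of the estimates is the inverse observed information, and
# Wald inference is z-based.

make_ml_objective <- function(model, data, family) {
  x <- data$dose
  if (family == "binomial") {
    y <- data$successes
    m <- data$total
    function(theta) {
      p <- dr_mean(model, x, merge_beta(model, theta))
      if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) return(NA_real_)
      -sum(stats::dbinom(y, m, p, log = TRUE))
    }
  } else {
    y <- data$response
    function(theta) {
      mu <- dr_mean(model, x, merge_beta(model, theta))
      if (any(!is.finite(mu)) || any(mu <= 0)) return(NA_real_)
      -sum(stats::dpois(y, mu, log = TRUE))
    }
  }
}

#' Fit a dose-response model by maximum likelihood
#'
#' For binomial (quantal) data the log-likelihood
#' \eqn{\sum_i l(y_i, f(x_i, \beta))} uses the binomial likelihood with
#' success probability `f(x, beta)`, which is kept inside (0, 1) during the
#' search; for count data the Poisson likelihood with mean `f(x, beta) > 0`
#' is used.  The covariance of the estimates is the inverse of the numeric
#' observed information matrix and Wald inference is z-based.
#'
#' @param data for `family = "binomial"`: columns `dose`, `successes`,
#'   `total`; for `family = "poisson"`: columns `dose` and `count` (or
#'   `response`).
#' @param model a [dr_model()] or registry name.
#' @param family `"binomial"` or `"poisson"`.
#' @param start optional named starting values for the free parameters.
#' @return a `dr_fit` object.
#' @export
#' @examples
#' d <- dr_simulate("LL.2", c(b = -1.5, c = 0, d = 1, e = 10),
#'                  doses = 1.25 * 2^(0:5), error = "binomial",
#'                  totals = 50, seed = 7)
#' fit <- dr_fit_ml(d, "LL.2", family = "binomial")
#' coef(fit)
dr_fit_ml <- function(data, model, family = c("binomial", "poisson"),
                      start = NULL) {
  family <- match.arg(family)
  if (is.character(model)) model <- dr_model(model)
  data <- validate_dr_data(data, if (family == "binomial") "binomial" else
    "poisson")

  starts <- if (is.null(start)) dr_start(model, data) else
    as_dr_starts(model, start)

  obj <- make_ml_objective(model, data, family)
  if (!is.finite(obj(starts$beta0))) {
    stop("starting values give an inadmissible mean (outside the likelihood ",
         "support); supply starting values manually", call. = FALSE)
  }
  opt <- run_optim(obj, starts$beta0)
  theta <- stats::setNames(opt$theta, model$free_names)

  # mean admissible at the optimum?
  converged <- opt$converged && is.finite(obj(theta))

  H <- num_hessian(function(t) {
    v <- obj(t); if (!is.finite(v)) BIG else v
  }, theta)
  Vi <- if (all(is.finite(H))) chol_inverse(H) else NULL
  V <- if (is.null(Vi)) {
    matrix(NA_real_, length(theta), length(theta),
           dimnames = list(names(theta), names(theta)))
  } else {
    dimnames(Vi) <- list(names(theta), names(theta))
    Vi
  }

  new_dr_fit(model, data, if (family == "binomial") "binomial" else "poisson",
             method = paste0("ml_", family), theta = theta, vcov = V,
             sigma = NA_real_, loglik = -opt$value,
             objective_value = opt$value, converged = converged,
             starts = starts)
}
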