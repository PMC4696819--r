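# Robust M-estimation for continuous responses.  The loss rho controls the
# influence of observations; rho(u) = u^2 reproduces ordinary least squares.
# The scale is a median-absolute-deviation estimate, alternated with the
# parameter optimization until the estimates stabilise.

# losses are scaled so that rho(u) ~ u^2 near zero, making the
# "information"-type covariance sigma~^2 (0.5 Hessian)^{-1} reduce exactly
# to the least-squares covariance when rho(u) = u^2.
rho_huber <- function(u, k) ifelse(abs(u) <= k, u^2, 2 * k * abs(u) - k^2)

rho_bisquare <- function(u, k) {
  ifelse(abs(u) <= k, (k^2 / 3) * (1 - (1 - (u / k)^2)^3), k^2 / 3)
}

#' Fit a dose-response model by robust M-estimation
#'
#' Minimizes \eqn{\tilde\sigma^2 \sum_i \rho(w_i (y_i - f(x_i, \beta)) /
#' \tilde\sigma)} with a Huber or Tukey-bisquare loss, weighing down extreme
#' observations.  The robust scale \eqn{\tilde\sigma} is the (rescaled)
#' median absolute deviation of the residuals, re-estimated between
#' optimization passes.  Hampel's loss is not supported.  Accurate starting
#' values help; by default the data-driven self-starter is used.
#'
#' @inheritParams dr_fit_ls
#' @param loss `"huber"` or `"bisquare"`.
#' @param tuning tuning constant; defaults 1.345 (Huber) and 4.685
#'   (bisquare).  A very large Huber constant reproduces least squares.
#' @return a `dr_fit` object with `method = "robust"`.
#' @export
dr_fit_robust <- function(data, model, loss = c("huber", "bisquare"),
                          tuning = NULL, start = NULL) {
  loss_in <- as.character(loss)[1]
  if (identical(tolower(loss_in), "hampel")) {
    stop("the Hampel loss is not implemented; use 'huber' or 'bisquare'",
         call. = FALSE)
  }
  loss <- match.arg(loss)
  if (is.character(model)) model <- dr_model(model)
  data <- validate_dr_data(data, "continuous")
  k <- tuning %||% switch(loss, huber = 1.345, bisquare = 4.685)
  rho <- switch(loss, huber = rho_huber, bisquare = rho_bisquare)

  starts <- if (is.null(start)) dr_start(model, data) else
    as_dr_starts(model, start)
  theta <- starts$beta0

  x <- data$dose; y <- data$response; w <- data$weight
  resid_at <- function(th) w * (y - dr_mean(model, x, merge_beta(model, th)))

  sigma_t <- stats::mad(resid_at(theta), center = 0)
  if (!is.finite(sigma_t) || sigma_t <= 0) sigma_t <- stats::sd(y)

  make_obj <- function(s) {
    function(th) {
      r <- resid_at(th)
      if (any(!is.finite(r))) return(NA_real_)
      s^2 * sum(rho(r / s, k))
    }
  }

  converged <- FALSE
  opt <- NULL
  for (iter in 1:10) {
    obj <- make_obj(sigma_t)
    opt <- run_optim(obj, theta)
    new_theta <- opt$theta
    delta <- max(abs(new_theta - theta) / pmax(abs(theta), 1e-8))
    theta <- new_theta
    s_new <- stats::mad(resid_at(theta), center = 0)
    if (is.finite(s_new) && s_new > 0) sigma_t <- s_new
    if (delta < 1e-8) { converged <- opt$converged; break }
  }
  theta <- stats::setNames(theta, model$free_names)

  obj <- make_obj(sigma_t)
  H <- num_hessian(function(t) {
    v <- obj(t); if (!is.finite(v)) BIG else v
  }, theta)
  Vi <- if (all(is.finite(H))) chol_inverse(H / 2) else NULL
  V <- if (is.null(Vi)) {
    matrix(NA_real_, length(theta), length(theta),
           dimnames = list(names(theta), names(theta)))
  } else {
    V0 <- sigma_t^2 * Vi
    dimnames(V0) <- list(names(theta), names(theta))
    V0
  }

  rss <- sum(resid_at(theta)^2)
  new_dr_fit(model, data, "continuous", "robust", theta, V,
             sigma = sigma_t, loglik = ls_loglik(data, rss, NULL),
             objective_value = obj(theta), converged = converged,
             starts = starts, robust = list(loss = loss, tuning = k))
}
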