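# Tests and model selection: parameter comparisons across curves, nested
# model tests, the no-effect test against a constant mean, lack-of-fit
# against the saturated one-mean-per-dose model, and information-criterion
# based selection.

new_dr_test <- function(statistic, df1, df2 = NA_real_, p_value, kind) {
  tibble::tibble(statistic = statistic, df1 = df1, df2 = df2,
                 p_value = p_value, kind = kind)
}

is_ls_like <- function(fit) fit$method %in% c("ls", "robust")

#' Compare one parameter across the curves of a joint fit
#'
#' Computes all pairwise ratios (null value 1) or differences (null value 0)
#' of a per-curve parameter, with delta-method standard errors from the joint
#' covariance.  P-values are unadjusted; family-wise adjustment is left to
#' dedicated multiple-comparison machinery.
#'
#' @param fit a joint `dr_fit` (see [dr_fit_joint()]).
#' @param param name of a per-curve free parameter, e.g. `"e"`.
#' @param operator `"ratio"` or `"difference"`.
#' @return tibble with one row per curve pair: estimate, standard error,
#'   t/z statistic, degrees of freedom and p-value.
#' @export
dr_compparm <- function(fit, param, operator = c("ratio", "difference")) {
  operator <- match.arg(operator)
  stopifnot(inherits(fit, "dr_fit"))
  if (is.null(fit$sharing)) {
    stop("parameter comparison requires a joint fit with curve labels",
         call. = FALSE)
  }
  if (!param %in% names(fit$sharing) || fit$sharing[[param]] != "per-curve") {
    stop("parameter '", param, "' is not estimated per-curve in this fit",
         call. = FALSE)
  }
  lv <- fit$curves
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  V <- fit$vcov
  df <- fit$df_inference
  rows <- lapply(pairs, function(pr) {
    nA <- paste(param, pr[1], sep = ":")
    nB <- paste(param, pr[2], sep = ":")
    A <- fit$coefficients[[nA]]; B <- fit$coefficients[[nB]]
    vA <- V[nA, nA]; vB <- V[nB, nB]; vAB <- V[nA, nB]
    if (operator == "ratio") {
      est <- A / B
      se <- sqrt(max(vA / B^2 - 2 * A * vAB / B^3 + A^2 * vB / B^4, 0))
      null <- 1
    } else {
      est <- A - B
      se <- sqrt(max(vA + vB - 2 * vAB, 0))
      null <- 0
    }
    stat <- (est - null) / se
    tibble::tibble(
      comparison = paste(pr[1], pr[2], sep = "/"),
      parameter = param, operator = operator,
      estimate = est, se = se, statistic = stat, df = df,
      p_value = 2 * stats::pt(-abs(stat), df = df)
    )
  })
  dplyr::bind_rows(rows)
}

check_same_data <- function(fit1, fit2) {
  if (fit1$n != fit2$n ||
      !isTRUE(all.equal(sort(fit1$data$dose), sort(fit2$data$dose))) ||
      !isTRUE(all.equal(sort(fit1$data$response), sort(fit2$data$response)))) {
    stop("fits are not based on the same data", call. = FALSE)
  }
  if (fit1$response_type != fit2$response_type) {
    stop("fits have different response types", call. = FALSE)
  }
  invisible(TRUE)
}

#' Test a reduced dose-response model against a full one
#'
#' For continuous least-squares fits an F test on residual sums of squares;
#' for maximum-likelihood fits a chi-square likelihood-ratio test.  The
#' reduced model must be nested in the full one (fewer free parameters on the
#' same data).
#'
#' @param reduced,full `dr_fit` objects on identical data.
#' @return a one-row tibble: statistic, degrees of freedom, p-value, kind.
#' @export
dr_anova <- function(reduced, full) {
  stopifnot(inherits(reduced, "dr_fit"), inherits(full, "dr_fit"))
  check_same_data(reduced, full)
  if (reduced$p > full$p) {
    stop("'reduced' has more free parameters than 'full'; swap the arguments",
         call. = FALSE)
  }
  df1 <- full$p - reduced$p
  if (is_ls_like(full)) {
    if (df1 == 0) {
      return(new_dr_test(0, 0, full$df_residual, 1, "F"))
    }
    rss_r <- reduced$objective_value
    rss_f <- full$objective_value
    stat <- max((rss_r - rss_f) / df1, 0) / (rss_f / full$df_residual)
    new_dr_test(stat, df1, full$df_residual,
                stats::pf(stat, df1, full$df_residual, lower.tail = FALSE),
                "F")
  } else {
    if (df1 == 0) return(new_dr_test(0, 0, NA_real_, 1, "LR"))
    stat <- max(2 * (full$loglik - reduced$loglik), 0)
    new_dr_test(stat, df1, NA_real_,
                stats::pchisq(stat, df1, lower.tail = FALSE), "LR")
  }
}

#' Test for any dose-response relationship
#'
#' Compares the fitted dose-response model against the model in which the
#' response is on average constant (one grand mean): an F test for
#' least-squares fits, a likelihood-ratio test for maximum-likelihood fits.
#'
#' @param fit a `dr_fit`.
#' @return a one-row tibble: statistic, degrees of freedom, p-value, kind.
#' @export
dr_no_effect <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  data <- fit$data
  df1 <- fit$p - 1
  if (is_ls_like(fit)) {
    w2 <- data$weight^2
    y <- data$response
    tr <- fit$transform
    if (!is.null(tr) && isTRUE(tr$enabled)) y <- boxcox_g(y + tr$shift, tr$lambda)
    ybar <- sum(w2 * y) / sum(w2)
    rss0 <- sum(w2 * (y - ybar)^2)
    rss1 <- fit$objective_value
    stat <- max((rss0 - rss1) / df1, 0) / (rss1 / fit$df_residual)
    new_dr_test(stat, df1, fit$df_residual,
                stats::pf(stat, df1, fit$df_residual, lower.tail = FALSE),
                "F")
  } else {
    ll0 <- if (fit$response_type == "binomial") {
      p0 <- sum(data$successes) / sum(data$total)
      sum(stats::dbinom(data$successes, data$total, p0, log = TRUE))
    } else {
      mu0 <- mean(data$response)
      sum(stats::dpois(data$response, mu0, log = TRUE))
    }
    stat <- max(2 * (fit$loglik - ll0), 0)
    new_dr_test(stat, df1, NA_real_,
                stats::pchisq(stat, df1, lower.tail = FALSE), "LR")
  }
}

#' Lack-of-fit test against the saturated one-mean-per-dose model
#'
#' F test of the parametric dose-response model against the ANOVA model with
#' one mean per dose (per curve, for joint fits).  Requires replicate
#' observations and a continuous response.
#'
#' @param fit a continuous `dr_fit`.
#' @return a one-row tibble: statistic, degrees of freedom, p-value, kind.
#' @export
dr_model_fit <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  if (!is_ls_like(fit)) {
    stop("lack-of-fit test requires a continuous (least-squares) fit",
         call. = FALSE)
  }
  data <- fit$data
  y <- data$response
  tr <- fit$transform
  if (!is.null(tr) && isTRUE(tr$enabled)) y <- boxcox_g(y + tr$shift, tr$lambda)
  w <- data$weight
  grp <- interaction(data$dose, data$curve, drop = TRUE)
  k <- nlevels(grp)
  n <- fit$n
  if (n <= k) stop("lack-of-fit test requires replicate observations",
                   call. = FALSE)
  # weighted per-group means minimise the weighted SS
  mu_sat <- tapply(w^2 * y, grp, sum) / tapply(w^2, grp, sum)
  rss_sat <- sum((w * (y - mu_sat[grp]))^2)
  df1 <- k - fit$p
  if (df1 <= 0) return(new_dr_test(0, max(df1, 0), n - k, 1, "F"))
  stat <- max((fit$objective_value - rss_sat) / df1, 0) / (rss_sat / (n - k))
  new_dr_test(stat, df1, n - k,
              stats::pf(stat, df1, n - k, lower.tail = FALSE), "F")
}

fit_ic_df <- function(fit) {
  fit$p + if (is_ls_like(fit)) 1 else 0
}

#' Compare candidate models by information criteria
#'
#' Tabulates log-likelihood, AIC, BIC, residual variance and (when replicate
#' observations exist) the lack-of-fit p-value for a set of fits of the same
#' data, ordered by ascending AIC (ties broken by fewer parameters).
#'
#' @param fits list of `dr_fit` objects on identical data; names are used as
#'   labels.
#' @return a tibble, one row per fit.
#' @export
dr_mselect <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2)
  for (i in seq_along(fits)[-1]) check_same_data(fits[[1]], fits[[i]])
  labels <- names(fits) %||% vapply(fits, function(f) f$model$name,
                                    character(1))
  if (is.null(names(fits))) names(fits) <- labels
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    kdf <- fit_ic_df(f)
    lof <- tryCatch(dr_model_fit(f)$p_value, error = function(e) NA_real_)
    tibble::tibble(
      model = labels[i],
      logLik = f$loglik,
      df = kdf,
      AIC = -2 * f$loglik + 2 * kdf,
      BIC = -2 * f$loglik + log(f$n) * kdf,
      res_var = if (is_ls_like(f)) f$objective_value / f$df_residual
                else NA_real_,
      lack_of_fit_p = lof,
      n_params = f$p
    )
  })
  out <- dplyr::bind_rows(rows)
  out[order(out$AIC, out$n_params), ]
}

#' @export
anova.dr_fit <- function(object, full, ...) dr_anova(object, full)
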