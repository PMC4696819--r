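# Data-driven starting values by linearization of transformed responses.
# For the sigmoid families the per-dose mean responses are rescaled to
# fractions of the asymptote span and the family's linearizing transform
# (logit, probit, log-log) is regressed on log-dose.

#' Data-driven starting values for a dose-response model
#'
#' Computes optimizer starting values by linearization: asymptote guesses are
#' taken from the per-dose mean responses at the extreme doses (expanded by a
#' configurable margin), responses are rescaled to fractions of the span,
#' clipped away from 0 and 1, transformed by the family's linearizing link,
#' and regressed on log-dose over the positive doses.  Zero doses inform the
#' asymptote guesses but are excluded from the regression.
#'
#' @param model a [dr_model()] or registry name.
#' @param data a data frame with columns `dose` and `response` (binomial data
#'   may pass `successes`/`total`; the observed fraction is used).
#' @param margin asymptote expansion as a fraction of the response range
#'   (default 0.05).
#' @param clip_bounds clipping bounds for the rescaled responses before the
#'   linearizing transform (default `c(0.001, 0.999)`).
#' @return an object of class `dr_starts`: a list with `beta0` (named vector
#'   of free-parameter starts), `method` (`"linearization"`), and
#'   `diagnostics` (the intermediate asymptote guesses).
#' @export
dr_start <- function(model, data, margin = 0.05,
                     clip_bounds = c(0.001, 0.999)) {
  if (is.character(model)) model <- dr_model(model)
  if (!"response" %in% names(data) &&
      all(c("successes", "total") %in% names(data))) {
    data$response <- data$successes / data$total
  }
  data <- validate_dr_data(data, "continuous")
  dm <- dose_means(data)
  if (sum(dm$dose > 0) < 2) {
    stop("self-start requires at least 2 distinct positive doses",
         call. = FALSE)
  }
  rng <- diff(range(dm$response))
  if (rng == 0) {
    stop("zero response range; supply starting values manually",
         call. = FALSE)
  }
  if (nrow(data) < n_free(model)) {
    stop("fewer observations than free parameters", call. = FALSE)
  }

  fx <- model$fixed
  m_lo <- dm$response[1]
  m_hi <- dm$response[nrow(dm)]
  lo_guess <- min(dm$response) - margin * rng
  hi_guess <- max(dm$response) + margin * rng

  fam <- model$family
  # c is the lower and d the upper asymptote for the span-fraction families
  c0 <- if (!is.na(fx[["c"]])) fx[["c"]] else lo_guess
  d0 <- if (!is.na(fx[["d"]])) fx[["d"]] else hi_guess
  if (fam %in% c("gammadr", "nec", "multistage")) {
    # c/d play directional roles: d is the dose-0 limit for nec/multistage,
    # c the dose-0 limit for the gamma model
    if (fam == "gammadr") {
      c0 <- if (!is.na(fx[["c"]])) fx[["c"]] else m_lo + sign(m_lo - m_hi) * margin * rng
      d0 <- if (!is.na(fx[["d"]])) fx[["d"]] else m_hi + sign(m_hi - m_lo) * margin * rng
    } else {
      d0 <- if (!is.na(fx[["d"]])) fx[["d"]] else m_lo + sign(m_lo - m_hi) * margin * rng
      c0 <- if (!is.na(fx[["c"]])) fx[["c"]] else m_hi + sign(m_hi - m_lo) * margin * rng
    }
  }

  pos <- dm$dose > 0
  span <- d0 - c0
  pfrac <- clip((dm$response - c0) / ifelse(span == 0, 1, span),
                clip_bounds[1], clip_bounds[2])

  beta0_full <- stats::setNames(rep(NA_real_, length(model$param_names)),
                                model$param_names)
  beta0_full["c"] <- if ("c" %in% model$param_names) c0 else NA
  beta0_full["d"] <- if ("d" %in% model$param_names) d0 else NA

  lin <- function(z) {
    # regress transformed fraction on log-dose: z = a + k * log(x)
    fit <- stats::lm(z[pos] ~ log(dm$dose[pos]))
    stats::coef(fit)
  }

  if (fam %in% c("llogistic", "braincousens", "cedergreen")) {
    ck <- lin(stats::qlogis(pfrac))
    a <- ck[1]; k <- ck[2]
    if (!is.finite(k) || abs(k) < 1e-12) {
      stop("degenerate linearization (flat transformed response); ",
           "supply starting values manually", call. = FALSE)
    }
    b0 <- -k
    e0 <- exp(a / b0)
    beta0_full["b"] <- b0
    beta0_full["e"] <- e0
    if (fam == "llogistic") {
      beta0_full["f"] <- 1
    } else if (fam == "braincousens") {
      beta0_full["f"] <- 0
    } else {
      beta0_full["f"] <- 0.1 * abs(span)
    }
  } else if (fam %in% c("lnormal", "weibull1", "weibull2")) {
    z <- switch(fam,
      lnormal = stats::qnorm(pfrac),
      weibull1 = log(-log(pfrac)),
      weibull2 = log(-log(1 - pfrac))
    )
    ck <- lin(z)
    a <- ck[1]; k <- ck[2]
    if (!is.finite(k) || abs(k) < 1e-12) {
      stop("degenerate linearization (flat transformed response); ",
           "supply starting values manually", call. = FALSE)
    }
    b0 <- k
    e0 <- exp(-a / b0)
    beta0_full["b"] <- b0
    beta0_full["e"] <- e0
  } else if (fam == "fplogistic") {
    z <- log(dm$dose[pos] + 1)
    zz <- -stats::qlogis(pfrac[pos])
    X <- cbind(z^model$constants$p1, z^model$constants$p2)
    cf <- stats::coef(stats::lm(zz ~ X - 1))
    beta0_full["b"] <- cf[1]
    beta0_full["e"] <- cf[2]
  } else if (fam == "gammadr") {
    half <- (c0 + d0) / 2
    x50 <- dm$dose[pos][which.min(abs(dm$response[pos] - half))]
    beta0_full["b"] <- log(2) / max(x50, .Machine$double.eps)
    beta0_full["e"] <- 1
  } else if (fam == "multistage") {
    nl <- -log(pfrac)
    x1 <- min(dm$dose[pos])
    beta0_full["b1"] <- max(nl[dm$dose == x1][1], 0)
    cf <- stats::coef(stats::lm(nl[pos] ~ dm$dose[pos]))
    beta0_full["b2"] <- cf[2]
    beta0_full["b3"] <- 0
  } else if (fam == "nec") {
    drop_below <- d0 - margin * rng * sign(d0 - c0)
    below <- if (d0 > c0) dm$response < drop_below else dm$response > drop_below
    e0 <- if (any(below & pos)) min(dm$dose[below & pos]) else
      stats::median(dm$dose[pos])
    beta0_full["e"] <- e0
    beyond <- dm$dose > e0
    if (sum(beyond) >= 2) {
      cf <- stats::coef(stats::lm(log(pfrac[beyond]) ~ I(dm$dose[beyond] - e0)))
      beta0_full["b"] <- min(cf[2], -1e-6)
    } else {
      beta0_full["b"] <- -1 / max(dm$dose)
    }
  }

  if (model$log_e && "e" %in% model$free_names) {
    beta0_full["e"] <- log(max(beta0_full[["e"]], .Machine$double.xmin))
  }

  beta0 <- beta0_full[model$free_names]
  if (any(!is.finite(beta0))) {
    stop("self-start produced non-finite values; ",
         "supply starting values manually", call. = FALSE)
  }
  structure(
    list(beta0 = beta0, method = "linearization",
         diagnostics = list(c0 = c0, d0 = d0, dose_means = dm)),
    class = "dr_starts"
  )
}

as_dr_starts <- function(model, start) {
  if (inherits(start, "dr_starts")) return(start)
  if (is.null(names(start))) names(start) <- model$free_names
  missing <- setdiff(model$free_names, names(start))
  if (length(missing) > 0) {
    stop("user starting values missing for: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(beta0 = start[model$free_names], method = "user",
                 diagnostics = list()),
            class = "dr_starts")
}

#' Starting values actually used by a fit
#'
#' @param fit a fitted `dr_fit` object.
#' @return the `dr_starts` object recorded at fit time (data-driven or
#'   user-supplied).
#' @export
get_initial <- function(fit) {
  stopifnot(inherits(fit, "dr_fit"))
  fit$starts
}

#' @export
print.dr_starts <- function(x, ...) {
  cat("<dr_starts> method:", x$method, "\n")
  print(x$beta0)
  invisible(x)
}
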