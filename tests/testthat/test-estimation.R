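# Estimation: weighted nonlinear least squares, maximum likelihood for
# quantal and count responses, robust M-estimation, box constraints, and
# the transform-both-sides machinery.

test_that("noiseless generate-fit roundtrip recovers the parameters", {
  expect_lt(max(abs(coef(fit_noiseless) - ll4_true)), 1e-6)
  expect_lt(fit_noiseless$sigma, 1e-8)
  expect_true(fit_noiseless$converged)
})

test_that("fixing the extra parameter reproduces the nested fit's objective", {
  st <- dr_start("LL.4", fx$ll4_clean)$beta0
  f4 <- dr_fit_ls(fx$ll4_clean, "LL.4", start = st)
  f5 <- dr_fit_ls(fx$ll4_clean, dr_model("LL.5", fixed = c(f = 1)),
                  start = st)
  expect_lt(abs(f4$objective_value - f5$objective_value), 1e-10)
})

test_that("rescaling all weights leaves estimates and covariance unchanged", {
  f1 <- dr_fit_ls(fx$ll4_clean, "LL.4")
  d2 <- fx$ll4_clean
  d2$weight <- 2
  f2 <- dr_fit_ls(d2, "LL.4")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
  expect_equal(f2$sigma, 2 * f1$sigma, tolerance = 1e-7)
  expect_equal(vcov(f1), vcov(f2), tolerance = 1e-4)
})

test_that("box constraints bind when the optimum lies outside", {
  fit <- dr_fit_ls(fx$ll4_clean, "LL.4", lower = c(e = 10), upper = c(e = 20))
  expect_equal(coef(fit)[["e"]], 10, tolerance = 1e-6)
  expect_true(fit$active_bounds[["e"]])
})

test_that("binomial ML matches the logistic-regression oracle", {
  # LL.2 on log-dose is exactly a logistic regression via
  # logit(p) = -b (log x - log e)
  fit <- fit_ll2_binom
  g <- stats::glm(cbind(successes, total - successes) ~ log(dose),
                  family = binomial, data = fx$ll2_binom)
  b_glm <- -stats::coef(g)[[2]]
  loge_glm <- stats::coef(g)[[1]] / b_glm
  expect_equal(coef(fit)[["b"]], b_glm, tolerance = 1e-5)
  expect_equal(log(coef(fit)[["e"]]), loge_glm, tolerance = 1e-5)
  # z-based Wald inference and reported log-likelihood
  expect_identical(fit$df_inference, Inf)
  p <- fitted(fit)
  expect_equal(fit$loglik,
               sum(stats::dbinom(fx$ll2_binom$successes,
                                 fx$ll2_binom$total, p, log = TRUE)),
               tolerance = 1e-8)
})

test_that("Bernoulli rows give the aggregated likelihood up to constants", {
  db <- fx$ll2_binom
  bern <- db[rep(seq_len(nrow(db)), db$total), c("dose", "successes")]
  bern$successes <- unlist(lapply(seq_len(nrow(db)), function(i) {
    c(rep(1, db$successes[i]), rep(0, db$total[i] - db$successes[i]))
  }))
  bern$total <- 1
  fb <- dr_fit_ml(bern, "LL.2", family = "binomial",
                  start = coef(fit_ll2_binom))
  expect_equal(coef(fb), coef(fit_ll2_binom), tolerance = 1e-5)
  const <- sum(lchoose(db$total, db$successes))
  expect_equal(fb$loglik + const, fit_ll2_binom$loglik, tolerance = 1e-6)
})

test_that("poisson ML recovers the generating curve across replications", {
  set.seed(88)
  beta <- c(b = 1.5, c = 2, d = 30, e = 3)
  hits <- vapply(seq_len(200), function(i) {
    d <- dr_simulate("LL.4", beta, doses = ll4_doses, reps = 3,
                     error = "poisson", seed = NULL)
    f <- tryCatch(suppressWarnings(dr_fit_ml(d, "LL.4", family = "poisson")),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged || any(!is.finite(diag(vcov(f)))))
      return(NA)
    all(abs(coef(f) - beta) <= 3 * sqrt(diag(vcov(f))))
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.90)
  expect_lte(mean(is.na(hits)), 0.05)
})

test_that("a quadratic loss reproduces least squares; Hampel is refused", {
  fls <- dr_fit_ls(fx$ll4_clean, "LL.4")
  frob <- dr_fit_robust(fx$ll4_clean, "LL.4", loss = "huber", tuning = 1e6)
  expect_lt(max(abs(coef(fls) - coef(frob))), 1e-6)
  expect_error(dr_fit_robust(fx$ll4_clean, "LL.4", loss = "hampel"),
               "not implemented")
})

test_that("bisquare estimation shrugs off a gross outlier", {
  e_clean <- coef(fit_ll4_clean)[["e"]]
  e_ls <- coef(dr_fit_ls(fx$outlier_ll4, "LL.4",
                         start = coef(fit_ll4_clean)))[["e"]]
  e_rob <- coef(dr_fit_robust(fx$outlier_ll4, "LL.4", loss = "bisquare",
                              start = coef(fit_ll4_clean)))[["e"]]
  expect_lt(abs(e_rob - e_clean), 0.2 * abs(e_ls - e_clean))
})

test_that("an identity Box-Cox transform reproduces the plain fit exactly", {
  f0 <- dr_fit_ls(fx$ll4_clean, "LL.4")
  f1 <- dr_fit_ls(fx$ll4_clean, "LL.4", transform = dr_transform(1, 0))
  expect_identical(coef(f0), coef(f1))
})

test_that("the log transform squares log-scale residuals", {
  d <- fx$ll4_clean
  fit <- dr_fit_ls(d, "LL.4", transform = dr_transform(0, 0))
  mu <- dr_mean(dr_model("LL.4"), d$dose, coef(fit))
  expect_equal(fit$objective_value, sum((log(d$response) - log(mu))^2),
               tolerance = 1e-10)
})

test_that("Box-Cox selection validates its inputs", {
  d <- fx$ll4_clean
  d_neg <- d; d_neg$response[1] <- -2
  expect_error(dr_boxcox(d_neg), "positive")
  d_norep <- dr_simulate("LL.4", ll4_true, doses = ll4_doses, reps = 1,
                         sd = 0.05, seed = 2)
  expect_error(dr_boxcox(d_norep, method = "anova"), "replicates")
})

test_that("reported log-likelihood is the normal likelihood at the ML scale", {
  f <- fit_ll4_clean
  n <- f$n
  s2_ml <- f$objective_value / n
  ll <- sum(stats::dnorm(f$data$response, fitted(f), sqrt(s2_ml), log = TRUE))
  expect_equal(f$loglik, ll, tolerance = 1e-8)
})

test_that("reported optimum is never worse than at the starting values", {
  for (seed in 1:5) {
    d <- dr_simulate("LL.4", ll4_true, doses = ll4_doses, reps = 4,
                     sd = 0.1, seed = 100 + seed)
    f <- suppressWarnings(dr_fit_ls(d, "LL.4"))
    obj <- dosefit:::make_ls_objective(f$model, f$data, NULL)
    expect_lte(f$objective_value, obj(get_initial(f)$beta0) + 1e-12)
  }
})

test_that("delta-method covariance agrees with a case-resampling bootstrap", {
  set.seed(404)
  d <- fx$ll4_clean
  se_e <- sqrt(vcov(fit_ll4_clean)[["e", "e"]])
  boot_e <- vapply(seq_len(500), function(i) {
    idx <- sample(nrow(d), replace = TRUE)
    f <- tryCatch(
      suppressWarnings(dr_fit_ls(d[idx, ], "LL.4",
                                 start = coef(fit_ll4_clean))),
      error = function(e) NULL)
    if (is.null(f)) NA_real_ else coef(f)[["e"]]
  }, numeric(1))
  # a few resamples lose design support at the extreme doses and blow the
  # tail up; summarise the bootstrap spread by its robust (MAD) scale
  se_boot <- stats::mad(boot_e, na.rm = TRUE)
  expect_lt(abs(se_e - se_boot) / se_boot, 0.2)
})
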