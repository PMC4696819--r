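# Inverse regression: effective doses, benchmark doses, relative potency,
# delta and Fieller intervals, model averaging.

test_that("the relative ED50 of a log-logistic fit is the location parameter", {
  ed <- dr_ed(fit_ll4_clean, 0.5)
  expect_equal(ed$estimate, coef(fit_ll4_clean)[["e"]], tolerance = 1e-8)
  expect_equal(ed$se, sqrt(vcov(fit_ll4_clean)[["e", "e"]]),
               tolerance = 1e-6)
})

test_that("numeric root finding matches the closed-form inverse", {
  # closed form for Weibull I at the midpoint: e * (log 2)^(1/b)
  m <- dr_model("W1.4")
  bt <- c(b = 2, c = 0, d = 1, e = 5)
  target <- dosefit:::relative_target(m, bt, 0.5)
  closed <- dosefit:::ed_solve(m, bt, target)
  expect_equal(closed, 5 * sqrt(log(2)), tolerance = 1e-10)
  m_num <- m; m_num$closed_form_ed <- FALSE
  expect_equal(dosefit:::ed_solve(m_num, bt, target), closed,
               tolerance = 1e-8)
})

test_that("an absolute dose at the midpoint equals the relative ED50", {
  bt <- coef(fit_ll4_clean)
  mid <- (bt[["c"]] + bt[["d"]]) / 2
  ed_rel <- dr_ed(fit_ll4_clean, 0.5)
  ed_abs <- dr_ed(fit_ll4_clean, mid, type = "absolute")
  expect_equal(ed_abs$estimate, ed_rel$estimate, tolerance = 1e-8)
})

test_that("effective doses increase with the level and invert the curve", {
  eds <- dr_ed(fit_ll4_clean, c(0.1, 0.5, 0.9))
  expect_true(all(diff(eds$estimate) > 0))
  # percent levels mean the same thing
  eds_pct <- dr_ed(fit_ll4_clean, c(10, 50, 90))
  expect_equal(eds_pct$estimate, eds$estimate)
  # defining identity: f(ED100a) = (1-a) L0 + a Linf
  m <- fit_ll4_clean$model
  bt <- coef(fit_ll4_clean)
  lims <- dr_mean_limits(m, bt)
  for (i in seq_len(nrow(eds))) {
    target <- (1 - eds$level[i]) * lims[["at_zero"]] +
      eds$level[i] * lims[["at_inf"]]
    expect_equal(dr_mean(m, eds$estimate[i], bt), unname(target),
                 tolerance = 1e-8)
  }
})

test_that("hormesis levels need a non-monotone model and an explicit flag", {
  expect_error(dr_ed(fit_ll4_clean, -0.05), "hormesis")
  expect_error(dr_ed(fit_ll4_clean, -0.05, hormesis = TRUE), "non-monotone")
  crs <- dr_model("CRS.5", constants = list(alpha = 0.25))
  fit_crs <- suppressWarnings(dr_fit_ls(fx$hormesis_crs, crs))
  ed_h <- dr_ed(fit_crs, -0.05, hormesis = TRUE)
  expect_true(is.finite(ed_h$estimate) && ed_h$estimate > 0)
})

test_that("benchmark doses reduce to effective doses", {
  # zero background: added and excess risk coincide
  bmd_a <- dr_bmd(fit_ll2_binom, 0.1, "added")
  bmd_e <- dr_bmd(fit_ll2_binom, 0.1, "excess")
  expect_equal(bmd_a$bmd, bmd_e$bmd, tolerance = 1e-8)
  expect_lte(bmd_a$bmdl, bmd_a$bmd)
  # with background c and BMR = (d - c)/2, the added-risk BMD is the ED50
  d_inc <- dr_simulate("LL.4", c(b = -2, c = 0.1, d = 0.9, e = 3),
                       doses = ll4_doses, reps = 4, sd = 0.03, seed = 12)
  f_inc <- dr_fit_ls(d_inc, "LL.4")
  bt <- coef(f_inc)
  bmr <- (bt[["d"]] - bt[["c"]]) / 2
  bmd <- dr_bmd(f_inc, bmr, "added")
  ed50 <- dr_ed(f_inc, 0.5)
  expect_equal(bmd$bmd, ed50$estimate, tolerance = 1e-8)
  # decreasing curves are rejected
  expect_error(dr_bmd(fit_ll4_clean, 0.1), "increasing")
})

test_that("benchmark-dose lower bounds cover the true dose", {
  set.seed(606)
  true_beta <- c(b = -1.5, c = 0, d = 1, e = 10)
  m <- dr_model("LL.2")
  true_bmd <- dosefit:::ed_solve(m, c(b = -1.5, e = 10),
                                 dosefit:::relative_target(m, true_beta, 0) +
                                   0.1)
  res <- vapply(seq_len(200), function(i) {
    d <- dr_simulate("LL.2", true_beta, doses = 1.25 * 2^(0:5),
                     error = "binomial", totals = 50, seed = NULL)
    f <- tryCatch(suppressWarnings(dr_fit_ml(d, "LL.2", "binomial")),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(c(NA, NA))
    b <- dr_bmd(f, 0.1, "added")
    c(b$bmdl <= b$bmd, b$bmdl <= true_bmd)
  }, numeric(2))
  expect_equal(mean(res[1, ], na.rm = TRUE), 1)
  expect_gte(mean(res[2, ], na.rm = TRUE), 0.90)
  expect_lte(mean(res[2, ], na.rm = TRUE), 0.995)
})

test_that("a curve compared with itself has unit potency", {
  d <- fx$ll4_clean
  dup <- rbind(transform(d, curve = "A"), transform(d, curve = "B"))
  fj <- dr_fit_joint(dup, "LL.4")
  cmp <- dr_ed_compare(fj, c("A", "B"))
  expect_equal(cmp$estimate, 1, tolerance = 1e-4)
  dif <- dr_ed_compare(fj, c("A", "B"), operator = "difference")
  expect_equal(dif$estimate, 0, tolerance = 1e-4)
})

test_that("halving all doses of one curve doubles the potency at any level", {
  doses <- 0.125 * 2^(0:7)
  bA <- c(b = 2, c = 0.1, d = 0.9, e = 3)
  bB <- c(b = 2, c = 0.1, d = 0.9, e = 1.5)
  d <- dr_simulate("LL.4", doses = doses, reps = 4, sd = 0,
                   curves = list(A = bA, B = bB), seed = 1)
  fj <- dr_fit_joint(d, "LL.4")
  for (a in c(0.1, 0.5, 0.9)) {
    cmp <- dr_ed_compare(fj, c("A", "B"), levels = c(a, a))
    expect_equal(cmp$estimate, 2, tolerance = 1e-6)
  }
})

test_that("Fieller intervals approach delta intervals for a sharp denominator", {
  num <- 2; den <- 1
  V <- matrix(c(0.04, 0, 0, 1e-12), 2)
  fi <- fieller_interval(num, den, V, df = Inf)
  se_delta <- delta_se(c(1 / den, -num / den^2), V)
  de <- num / den + c(-1, 1) * stats::qnorm(0.975) * se_delta
  expect_lt(abs(diff(fi) - diff(de)) / diff(de), 0.05)
})

test_that("relative potency is constant under parallelism and not otherwise", {
  fj <- dr_fit_joint(fx$two_curve, "LL.4",
                     sharing = c(b = "common", c = "common", d = "common"))
  rp <- dr_relpot(fj, c("A", "B"), alpha_grid = c(0.1, 0.25, 0.5, 0.75, 0.9))
  expect_lt(diff(range(rp$rho)) / mean(rp$rho), 1e-6)
  # per-curve steepness: the ratio drifts monotonically with the level
  d <- dr_simulate("LL.4", doses = ll4_doses, reps = 4, sd = 0,
                   curves = list(A = c(b = 1.5, c = 0.1, d = 0.9, e = 3),
                                 B = c(b = 3, c = 0.1, d = 0.9, e = 3)),
                   seed = 2)
  fj2 <- dr_fit_joint(d, "LL.4")
  rp2 <- dr_relpot(fj2, c("A", "B"), alpha_grid = c(0.2, 0.4, 0.6, 0.8))
  expect_true(all(diff(rp2$rho) > 0) || all(diff(rp2$rho) < 0))
  # a single grid value reduces to the pairwise comparison
  one <- dr_relpot(fj, c("A", "B"), alpha_grid = 0.5)
  cmp <- dr_ed_compare(fj, c("A", "B"))
  expect_equal(one$rho, cmp$estimate)
})

test_that("model averaging weights by AIC and stays within the envelope", {
  f_ll <- fit_ll4_clean
  f_w <- dr_fit_ls(fx$ll4_clean, "W1.4")
  # identical fits share the weight and reproduce the single-model dose
  ma_same <- dr_ma_ed(list(a = f_ll, b = f_ll))
  w <- attr(ma_same, "per_model")$weight
  expect_equal(unname(w), c(0.5, 0.5))
  expect_equal(ma_same$estimate, dr_ed(f_ll, 0.5)$estimate, tolerance = 1e-10)
  # a fit 20 AIC units better dominates
  f_bad <- f_ll
  f_bad$loglik <- f_ll$loglik - 10
  ma_dom <- dr_ma_ed(list(good = f_ll, bad = f_bad))
  expect_gt(attr(ma_dom, "per_model")$weight[1], 0.999)
  # averaging two families brackets the per-model estimates
  ma <- dr_ma_ed(list(LL.4 = f_ll, W1.4 = f_w))
  ed_range <- range(dr_ed(f_ll, 0.5)$estimate, dr_ed(f_w, 0.5)$estimate)
  expect_gte(ma$estimate, ed_range[1])
  expect_lte(ma$estimate, ed_range[2])
  # non-converged fits are dropped with a warning
  f_nc <- f_w
  f_nc$converged <- FALSE
  expect_warning(dr_ma_ed(list(f_ll, f_nc, f_ll)), "non-converged")
})

test_that("log-scale back-transformed intervals approach delta at large n", {
  # fls intervals need the log-location parameterization
  expect_error(dr_ed(fit_ll4_clean, 0.5, interval = "fls"), "log_e")
  d <- dr_simulate("LL.4", ll4_true, doses = ll4_doses, reps = 50,
                   sd = 0.05, seed = 900)
  mlog <- dr_model("LL.4", log_e = TRUE)
  f <- dr_fit_ls(d, mlog)
  expect_equal(exp(coef(f)[["e"]]), ll4_true[["e"]], tolerance = 0.05)
  ed_d <- dr_ed(f, 0.5, interval = "delta")
  ed_f <- dr_ed(f, 0.5, interval = "fls")
  expect_equal(ed_f$estimate, ed_d$estimate)
  expect_lt(abs(ed_f$lower - ed_d$lower) / ed_d$lower, 0.05)
  expect_lt(abs(ed_f$upper - ed_d$upper) / ed_d$upper, 0.05)
  # ratio comparison via the log-scale back-transform on a joint log_e fit
  tc <- dr_simulate("LL.4", doses = ll4_doses, reps = 25, sd = 0.05,
                    curves = list(A = c(b = 2, c = 0.1, d = 0.9, e = 2),
                                  B = c(b = 2, c = 0.1, d = 0.9, e = 6)),
                    seed = 901)
  fj <- dr_fit_joint(tc, mlog,
                     sharing = c(b = "common", c = "common", d = "common"))
  cmp_d <- dr_ed_compare(fj, c("A", "B"), interval = "delta")
  cmp_f <- dr_ed_compare(fj, c("A", "B"), interval = "fls")
  expect_equal(cmp_f$estimate, cmp_d$estimate)
  expect_lt(abs(cmp_f$lower - cmp_d$lower) / cmp_d$lower, 0.1)
  expect_lt(abs(cmp_f$upper - cmp_d$upper) / cmp_d$upper, 0.1)
})

test_that("delta and Fieller utilities handle edge cases", {
  expect_equal(delta_se(1, matrix(4)), 2)
  expect_equal(delta_se(c(0, 0), diag(2)), 0)
  expect_error(delta_se(c(1, 2), matrix(1)), "dimensions")
  # zero covariance: a degenerate point interval at the ratio
  fi0 <- fieller_interval(3, 2, matrix(0, 2, 2), df = Inf)
  expect_equal(as.numeric(fi0), c(1.5, 1.5))
  # weak denominator: unbounded, flagged not raised
  fiu <- fieller_interval(1, 0.1, diag(c(1, 1)), df = Inf)
  expect_true(attr(fiu, "unbounded"))
})
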