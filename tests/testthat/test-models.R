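# Model library: registry, hierarchical fixing, evaluation (including the
# analytic dose-0 limits), asymptotes, gradients and structural invariants.

test_that("mean functions evaluate Table-style reference points", {
  m <- dr_model("LL.4")
  beta <- c(b = 1, c = 0, d = 1, e = 10)
  expect_equal(dr_mean(m, 10, beta), 0.5)          # x = e is the midpoint
  expect_equal(dr_mean(m, 0, beta), 1)             # limit at dose 0 is d (b > 0)

  w1 <- dr_model("W1.4")
  expect_equal(dr_mean(w1, 5, c(b = 2, c = 0.2, d = 1.2, e = 5)),
               0.2 + 1 * exp(-1), tolerance = 1e-12)

  nec <- dr_model("NEC.4")
  expect_equal(dr_mean(nec, 1, c(b = -0.5, c = 0, d = 1, e = 2)), 1)
  expect_equal(dr_mean(nec, 4, c(b = -0.5, c = 0, d = 1, e = 2)),
               exp(-0.5 * 2), tolerance = 1e-12)
})

test_that("dose 0 yields finite analytic limits for every family", {
  betas <- list(
    LL.5 = c(b = 2, c = 0.1, d = 1, e = 3, f = 1.5),
    LN.4 = c(b = 2, c = 0.1, d = 1, e = 3),
    W1.4 = c(b = -2, c = 0.1, d = 1, e = 3),
    W2.4 = c(b = 2, c = 0.1, d = 1, e = 3),
    BC.5 = c(b = 2, c = 0, d = 1, e = 3, f = 0.3),
    GAM.4 = c(b = 1, c = 0, d = 1, e = 2),
    MULTI.3 = c(b1 = 0.1, b2 = 0.5, b3 = 0.05, c = 0, d = 1),
    NEC.4 = c(b = -0.5, c = 0, d = 1, e = 2)
  )
  for (nm in names(betas)) {
    m <- dr_model(nm)
    expect_true(is.finite(dr_mean(m, 0, betas[[nm]])), label = nm)
  }
  crs <- dr_model("CRS.5", constants = list(alpha = 0.25))
  expect_true(is.finite(dr_mean(crs, 0, c(b = 2, c = 0, d = 1, e = 3,
                                          f = 0.5))))
  # fractional polynomial with a negative exponent still has a limit
  fpl <- dr_model("FPL.4", constants = list(p1 = -1, p2 = 2))
  expect_true(is.finite(dr_mean(fpl, 0, c(b = 1, c = 0, d = 1, e = 0.5))))
})

test_that("registry rejects bad specifications", {
  expect_error(dr_model("NOPE"), "unknown model")
  expect_error(dr_model("CRS.5", constants = list(alpha = 1.5)),
               "strictly in \\(0, 1\\)")
  expect_error(dr_model("CRS.5"), "requires constant")
  expect_error(dr_model("LL.2", fixed = c(b = 1, e = 1)), "all parameters")
  expect_error(dr_model("FPL.4", constants = list(p1 = 0.3, p2 = 1)),
               "must be one of")
  expect_error(dr_model("LL.4", fixed = c(zz = 1)), "unknown parameter")
  expect_error(dr_model("LL.4", fixed = c(e = -1)), "positive")
})

test_that("hierarchical fixing reproduces the abbreviated models exactly", {
  grid <- c(0, 10^seq(-3, 3, length.out = 25))
  # LL.5 with f = 1 versus LL.4
  m5 <- dr_model("LL.5", fixed = c(f = 1))
  m4 <- dr_model("LL.4")
  expect_identical(length(m5$free_names), 4L)
  b <- c(b = 1.7, c = 0.2, d = 1.1, e = 2.5)
  expect_identical(dr_mean(m5, grid, b), dr_mean(m4, grid, b))
  # LL.4 with c = 0, d = 1 versus LL.2
  m42 <- dr_model("LL.4", fixed = c(c = 0, d = 1))
  m2 <- dr_model("LL.2")
  expect_identical(length(m42$free_names), 2L)
  b2 <- c(b = -1.5, e = 10)
  expect_identical(dr_mean(m42, grid, b2), dr_mean(m2, grid, b2))
})

test_that("merging and stripping a reduced parameter vector round-trips", {
  m <- dr_model("LL.3")
  theta <- c(b = 1.3, d = 0.8, e = 4.2)
  full <- dosefit:::merge_beta(m, theta)
  expect_identical(dosefit:::reduce_beta(m, full), theta[m$free_names])
  expect_identical(full[["c"]], 0)
})

test_that("scale-invariant families commute with dose rescaling", {
  x <- 10^seq(-2, 2, length.out = 17)
  for (bt in random_beta4(10, seed = 401)) {
    for (nm in c("LL.4", "LN.4", "W1.4", "W2.4")) {
      m <- dr_model(nm)
      expect_true(m$scale_invariant)
      for (k in c(0.01, 7, 250)) {
        bt_k <- bt; bt_k[["e"]] <- k * bt[["e"]]
        expect_equal(dr_mean(m, k * x, bt_k), dr_mean(m, x, bt),
                     tolerance = 1e-12)
      }
    }
  }
  expect_false(dr_model("BC.5")$scale_invariant)
  expect_false(dr_model("CRS.5",
                        constants = list(alpha = 0.5))$scale_invariant)
})

test_that("log-scale location parameterization matches the natural one", {
  x <- c(0, 10^seq(-2, 2, length.out = 11))
  m <- dr_model("LL.4")
  mlog <- dr_model("LL.4", log_e = TRUE)
  bt <- c(b = 2, c = 0.1, d = 0.9, e = 3)
  bt_log <- bt; bt_log[["e"]] <- log(3)
  expect_equal(dr_mean(mlog, x, bt_log), dr_mean(m, x, bt),
               tolerance = 1e-14)
})

test_that("monotone families are monotone over a wide geometric grid", {
  for (bt in random_beta4(8, seed = 77)) {
    x <- bt[["e"]] * 10^seq(-6, 6, length.out = 60)
    for (nm in c("LL.4", "LN.4", "W1.4", "W2.4")) {
      v <- dr_mean(dr_model(nm), x, bt)
      d <- diff(v)
      expect_true(all(d <= 1e-12) || all(d >= -1e-12),
                  label = paste(nm, "monotone"))
    }
  }
})

test_that("asymptotic limits follow the sign of the steepness", {
  bt <- c(b = 2, c = 0.1, d = 0.9, e = 3)
  expect_equal(unname(dr_mean_limits(dr_model("LL.4"), bt)), c(0.9, 0.1))
  bt_neg <- bt; bt_neg[["b"]] <- -2
  expect_equal(unname(dr_mean_limits(dr_model("LL.4"), bt_neg)), c(0.1, 0.9))
  # hormesis bump vanishes at both extremes
  crs <- dr_model("CRS.5", constants = list(alpha = 0.25))
  btc <- c(b = 2, c = 0.1, d = 0.9, e = 3, f = 0.6)
  lims <- dr_mean_limits(crs, btc)
  expect_equal(unname(lims), c(0.9, 0.1))
  expect_equal(dr_mean(crs, 1e-8, btc), lims[["at_zero"]], tolerance = 1e-4)
  expect_equal(dr_mean(crs, 1e8, btc), lims[["at_inf"]], tolerance = 1e-4)
})

test_that("numeric mean gradients match a Richardson-extrapolated oracle", {
  # independent oracle: central differences at two step sizes combined by
  # Richardson extrapolation
  rich_grad <- function(m, x, beta, free) {
    vapply(free, function(p) {
      h <- 1e-4 * max(abs(beta[[p]]), 1)
      f1 <- function(hh) {
        bp <- beta; bm <- beta
        bp[[p]] <- beta[[p]] + hh; bm[[p]] <- beta[[p]] - hh
        (dr_mean(m, x, bp) - dr_mean(m, x, bm)) / (2 * hh)
      }
      (4 * f1(h / 2) - f1(h)) / 3
    }, numeric(1))
  }
  cases <- list(
    list(m = dr_model("LL.4"), bt = c(b = 2, c = 0.1, d = 0.9, e = 3)),
    list(m = dr_model("W1.4"), bt = c(b = -1.3, c = 0.2, d = 1.1, e = 0.7)),
    list(m = dr_model("LN.4"), bt = c(b = 1.1, c = 0, d = 1, e = 5))
  )
  for (cs in cases) {
    for (x in c(0.3, 1, 4.7)) {
      g <- dr_mean_gradient(cs$m, x, cs$bt)
      o <- rich_grad(cs$m, x, cs$bt, cs$m$free_names)
      expect_equal(as.numeric(g), as.numeric(o), tolerance = 1e-6)
    }
  }
  # at the midpoint of LL.4: df/dd = 1/2; at dose 0: df/db = 0
  g <- dr_mean_gradient(dr_model("LL.4"), 10, c(b = 1, c = 0, d = 1, e = 10))
  expect_equal(g[1, "d"], c(d = 0.5), tolerance = 1e-8)
  g0 <- dr_mean_gradient(dr_model("LL.4"), 0, c(b = 1, c = 0, d = 1, e = 10))
  expect_equal(g0[1, "b"], c(b = 0), tolerance = 1e-10)
})

test_that("negative doses and malformed parameter vectors are rejected", {
  m <- dr_model("LL.4")
  expect_error(dr_mean(m, -1, c(b = 1, c = 0, d = 1, e = 1)), "non-negative")
  expect_error(dr_mean(m, 1, c(1, 2, 3)), "length")
  expect_error(dr_mean(m, 1, c(b = 1, q = 2)), "unknown parameter")
})
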