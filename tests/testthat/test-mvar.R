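# Simulation, lagged covariances and Yule-Walker / OLS estimation.

test_that("simulation reproduces closed-form stationary moments", {
  # white noise: lag-1 autocovariances vanish
  x <- mvar_simulate(matrix(0, 3, 3), diag(3), T_obs = 20000, seed = 1)
  q <- lagged_covariance(x, 1)
  expect_true(all(abs(diag(q$q[[2]])) < 4 / sqrt(20000)))

  # AR(1): var = sigma^2 / (1 - a^2) = 4/3
  x1 <- mvar_simulate(matrix(0.5, 1, 1), matrix(1, 1, 1), T_obs = 1e5,
                      seed = 2)
  expect_equal(var(drop(x1)), 1 / (1 - 0.25), tolerance = 0.03)

  # determinism and shape
  xa <- mvar_simulate(matrix(0.3, 2, 2) * diag(2), diag(2), 500, seed = 9)
  xb <- mvar_simulate(matrix(0.3, 2, 2) * diag(2), diag(2), 500, seed = 9)
  expect_identical(xa, xb)
  expect_equal(dim(xa), c(2L, 500L))
  xt <- mvar_simulate(diag(0.3, 2), diag(2), 100, seed = 3, trials = 4)
  expect_equal(dim(xt), c(2L, 100L, 4L))

  expect_error(mvar_simulate(diag(1.2, 2), diag(2), 100), "unstable")
})

test_that("lagged covariance matches the direct formula on a 4-point series", {
  x <- matrix(c(1, 2, 3, 4), nrow = 1)
  cs <- lagged_covariance(x, tau_max = 1)
  # window t = 1..3, divisor T - tau_max - 1 = 2, full-series mean 2.5
  xc <- c(1, 2, 3, 4) - 2.5
  q0 <- sum(xc[1:3] * xc[1:3]) / 2
  q1 <- sum(xc[2:4] * xc[1:3]) / 2
  expect_equal(drop(cs$q[[1]]), q0)   # = 1.375
  expect_equal(drop(cs$q[[2]]), q1)   # = 0.625
  expect_equal(cs$t_used, 3L)

  # constant series: zero covariances, flagged
  expect_warning(csc <- lagged_covariance(matrix(1, 1, 10), 1), "zero")
  expect_equal(drop(csc$q[[1]]), 0)

  # lag-0 symmetry is exact for any panel
  set.seed(4)
  cs2 <- lagged_covariance(matrix(rnorm(5 * 50), 5), 2)
  expect_identical(cs2$q[[1]], t(cs2$q[[1]]))
})

test_that("Yule-Walker on theoretical covariances recovers A exactly", {
  for (topo in c("random", "modular", "hierarchical", "ei")) {
    net <- generate_connectivity(topo, N = 8, density = 0.3, wmin = 0.05,
                                 wmax = 0.2, seed = 17, n_intermediate = 2,
                                 n_leaves = 2)
    inp <- generate_input_covariance(net$N, 0.3, seed = 18)
    th <- theoretical_covariance(net, inp)
    expect_equal(yule_walker(th, 1), net$weights, tolerance = 1e-9)
    # Q1 = A Q0 holds by construction
    expect_equal(th$q[[2]], net$weights %*% th$q[[1]], tolerance = 1e-10)
  }
  # A = 0: Q0 = Sigma, Q1 = 0
  inp <- generate_input_covariance(4, 0.5, seed = 19)
  th0 <- theoretical_covariance(matrix(0, 4, 4), inp)
  expect_equal(th0$q[[1]], inp$sigma)
  expect_true(all(th0$q[[2]] == 0))
})

test_that("theoretical covariances match a long simulation", {
  net <- generate_connectivity("random", N = 4, density = 0.4, wmin = 0.1,
                               wmax = 0.3, seed = 21)
  inp <- generate_input_covariance(4, 0.3, seed = 22)
  th <- theoretical_covariance(net, inp)
  x <- mvar_simulate(net, inp, T_obs = 2e5, seed = 23)
  emp <- lagged_covariance(x, 1)
  scale <- max(abs(diag(th$q[[1]])))
  expect_lt(max(abs(emp$q[[1]] - th$q[[1]])) / scale, 0.03)
  expect_lt(max(abs(emp$q[[2]] - th$q[[2]])) / scale, 0.03)
})

test_that("the coefficient estimate equals a direct least-squares regression", {
  inst <- bench_instance(31, N = 6, T_obs = 2000, wmin = 0.05, wmax = 0.2)
  fit <- mvar(inst$x)
  # independent oracle: per-target OLS of x_t on x_{t-1} with intercept
  x <- inst$x
  T_obs <- ncol(x)
  z <- t(rbind(1, x[, 1:(T_obs - 1)]))
  for (i in 1:6) {
    beta <- qr.solve(z, x[i, 2:T_obs])
    expect_equal(unname(coef(fit)[i, ]), unname(beta[-1]), tolerance = 0.01)
  }
})

test_that("estimates are consistent and improve with sample size", {
  inst <- bench_instance(41, N = 5, T_obs = 10000, wmin = 0.05, wmax = 0.2,
                         cross_corr = 0)
  fit <- mvar(inst$x)
  # tolerance set from the repeated-seed spread of this configuration
  expect_lt(max(abs(coef(fit) - inst$net$weights)), 0.08)

  # mean |error| on existing weights decreases monotonically in T
  errs <- sapply(c(1000, 3000, 10000), function(T_obs) {
    mean(sapply(1:20, function(s) {
      inst <- bench_instance(700 + s, N = 10, T_obs = T_obs,
                             wmin = 0.03, wmax = 0.1)
      a <- coef(mvar(inst$x, keep_data = FALSE))
      mean(abs(a - inst$net$weights)[inst$net$mask])
    }))
  })
  expect_true(errs[1] > errs[2] && errs[2] > errs[3])
})

test_that("order-2 estimation recovers both lag matrices", {
  net <- generate_connectivity("random", N = 6, density = 0.3, wmin = 0.05,
                               wmax = 0.2, seed = 51, order = 2)
  inp <- generate_input_covariance(6, 0.2, seed = 52)
  # exact recovery from theoretical covariances
  th <- theoretical_covariance(net, inp, tau_max = 2)
  ab <- yule_walker(th, 2)
  expect_equal(ab$a1, net$weights, tolerance = 1e-8)
  expect_equal(ab$a2, net$weights2, tolerance = 1e-8)

  # from simulated data, and against a stacked-regression oracle
  x <- mvar_simulate(net, inp, T_obs = 10000, seed = 53)
  fit2 <- mvar(x, order = 2)
  expect_lt(max(abs(coef(fit2)$a1 - net$weights)), 0.06)
  expect_lt(max(abs(coef(fit2)$a2 - net$weights2)), 0.06)
  T_obs <- ncol(x)
  z <- t(rbind(1, x[, 2:(T_obs - 1)], x[, 1:(T_obs - 2)]))
  for (i in 1:6) {
    beta <- qr.solve(z, x[i, 3:T_obs])
    expect_equal(unname(cbind(coef(fit2)$a1, coef(fit2)$a2)[i, ]),
                 unname(beta[-1]), tolerance = 0.02)
  }

  # fitting order 2 on order-1 data leaves the second matrix at noise level
  net1 <- generate_connectivity("random", N = 6, density = 0.3, wmin = 0.05,
                                wmax = 0.2, seed = 54)
  x1 <- mvar_simulate(net1, inp, T_obs = 10000, seed = 55)
  f21 <- mvar(x1, order = 2)
  expect_lt(max(abs(coef(f21)$a2)), 0.05)
  expect_lt(max(abs(coef(f21)$a1 - net1$weights)), 0.06)
})

test_that("multi-trial covariance averaging agrees with concatenation for
           zero-mean identically distributed trials", {
  net <- generate_connectivity("random", N = 4, density = 0.4, wmin = 0.05,
                               wmax = 0.2, seed = 61)
  inp <- generate_input_covariance(4, 0, seed = 62)
  xt <- mvar_simulate(net, inp, T_obs = 2000, seed = 63, trials = 6)
  avg <- lagged_covariance(xt, 1)
  conc <- lagged_covariance(matrix(xt, 4, 2000 * 6), 1)
  expect_lt(max(abs(avg$q[[1]] - conc$q[[1]])), 0.05)
  expect_lt(max(abs(avg$q[[2]] - conc$q[[2]])), 0.05)
})

test_that("ill-conditioned covariances are refused with a useful error", {
  x <- matrix(rnorm(3 * 100), 3)
  x[3, ] <- x[1, ]                       # duplicated node
  suppressWarnings(cs <- lagged_covariance(x, 1))
  expect_error(yule_walker(cs, 1), "condition")
})

test_that("fit methods: print, summary, residuals, predict, simulate", {
  inst <- bench_instance(71, N = 5, T_obs = 3000, wmin = 0.05, wmax = 0.2)
  fit <- mvar(inst$x)
  expect_output(print(fit), "MVAR\\(1\\) fit")
  expect_output(print(summary(fit)), "spectral radius")
  r <- residuals(fit)
  expect_equal(dim(r), c(5L, 2999L))
  # residual covariance should approximate the innovation covariance
  expect_lt(max(abs(tcrossprod(r) / ncol(r) - inst$input$sigma)), 0.15)
  p <- predict(fit)
  expect_equal(dim(p), c(5L, 2999L))
  expect_equal(inst$x[, -1] - p, r)
  y <- simulate(fit, nsim = 4000, seed = 5)
  refit <- mvar(y)
  expect_lt(max(abs(coef(refit) - coef(fit))), 0.1)
})
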