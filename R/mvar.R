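# MVAR simulation, lagged covariances and Yule-Walker / OLS estimation.

#' Simulate activity of an MVAR network
#'
#' Iterates the noise-diffusion dynamics `x_t = A x_{t-1} + z_t` (order 1) or
#' `x_t = A1 x_{t-1} + A2 x_{t-2} + z_t` (order 2) with Gaussian innovations
#' `z_t ~ N(0, Sigma)`, i.i.d. over time.  The initial state is drawn from
#' `N(0, Sigma)` and the first `burn_in` steps are discarded so that the
#' retained samples are close to stationarity.
#'
#' @param conn an [`mvar_network`][generate_connectivity] (or square matrix).
#' @param input an [`mvar_input`][generate_input_covariance] (or covariance
#'   matrix, factorized internally).
#' @param T_obs number of retained time samples.
#' @param seed integer seed.
#' @param burn_in discarded initial steps (default 100).
#' @param trials number of independent trials; for `trials > 1` an
#'   `N x T_obs x trials` array is returned, otherwise an `N x T_obs` matrix.
#' @return the simulated panel (node x time), matrix or 3-d array.
#' @examples
#' net <- generate_connectivity("random", N = 5, density = 0.3, seed = 1)
#' inp <- generate_input_covariance(5, 0, seed = 2)
#' x <- mvar_simulate(net, inp, T_obs = 500, seed = 3)
#' dim(x)
#' @export
mvar_simulate <- function(conn, input, T_obs, seed = NULL, burn_in = 100,
                          trials = 1) {
  if (is.matrix(conn))
    conn <- structure(list(weights = conn, mask = conn != 0, weights2 = NULL,
                           order = 1L, N = nrow(conn), rescale = 1,
                           topology = "custom"),
                      class = "mvar_network")
  a1 <- conn$weights; a2 <- conn$weights2
  N <- nrow(a1)
  if (T_obs < 1) stop("T_obs must be >= 1", call. = FALSE)
  rho <- companion_spectral_radius(conn)
  if (rho >= 1)
    stop(sprintf("unstable connectivity (spectral radius %.3f >= 1)", rho),
         call. = FALSE)
  mix <- input_mixing(input, N)

  with_seed(seed, {
    sim_one <- function() {
      total <- T_obs + burn_in
      z <- mix %*% matrix(rnorm(N * total), N, total)
      x <- matrix(0, N, total)
      xp <- drop(mix %*% rnorm(N))        # x_{t-1} at start
      if (is.null(a2)) {
        for (t in seq_len(total)) {
          xp <- drop(a1 %*% xp) + z[, t]
          x[, t] <- xp
        }
      } else {
        xpp <- drop(mix %*% rnorm(N))     # x_{t-2}
        for (t in seq_len(total)) {
          xt <- drop(a1 %*% xp) + drop(a2 %*% xpp) + z[, t]
          x[, t] <- xt
          xpp <- xp; xp <- xt
        }
      }
      x[, burn_in + seq_len(T_obs), drop = FALSE]
    }
    if (trials == 1) sim_one()
    else array(vapply(seq_len(trials), function(r) sim_one(),
                      matrix(0, N, T_obs)),
               dim = c(N, T_obs, trials))
  })
}

input_mixing <- function(input, N) {
  if (inherits(input, "mvar_input")) {
    if (input$N != N) stop("input covariance size does not match network",
                           call. = FALSE)
    return(input$mixing)
  }
  if (!is_square(input) || nrow(input) != N)
    stop("input must be an mvar_input or an N x N covariance", call. = FALSE)
  ev <- eigen(input, symmetric = TRUE)
  if (min(ev$values) < -1e-8 * max(abs(ev$values)))
    stop("input covariance is not positive semidefinite", call. = FALSE)
  ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), N)
}

#' Empirical lagged covariances of a panel
#'
#' Computes `Qhat_tau[i, j] = 1/(T - tau_max - 1) *
#' sum_{t=1}^{T - tau_max} (x_i(t + tau) - xbar_i)(x_j(t) - xbar_j)` for
#' `tau = 0, ..., tau_max`, i.e. a common summation window for all lags and
#' the full-series mean.  For multi-trial panels each trial is centered
#' individually and the per-trial covariances are averaged.
#'
#' @param x panel: `N x T` matrix, `N x T x trials` array, or list of trials.
#' @param tau_max largest time shift.
#' @param divisor `"paper"` uses `T - tau_max - 1`; `"window"` uses the plain
#'   window length `T - tau_max`.
#' @param common_window if `FALSE`, each lag uses its own maximal window
#'   `t = 1..T - tau` instead of the shared one.
#' @return an object of class `mvar_covset`: list with `q` (list of
#'   `tau_max + 1` matrices), `tau_max`, `t_used`, `means`, `N`, `T_obs`,
#'   `n_trials`.
#' @examples
#' x <- matrix(c(1, 2, 3, 4), nrow = 1)
#' lagged_covariance(x, tau_max = 1)$q
#' @export
lagged_covariance <- function(x, tau_max = 1,
                              divisor = c("paper", "window"),
                              common_window = TRUE) {
  divisor <- match.arg(divisor)
  trials <- as_trial_list(x)
  T_obs <- ncol(trials[[1]])
  if (any(vapply(trials, ncol, 1L) != T_obs))
    stop("all trials must have the same length", call. = FALSE)
  if (T_obs <= tau_max + 1)
    stop("need T > tau_max + 1 samples", call. = FALSE)
  N <- nrow(trials[[1]])

  q <- vector("list", tau_max + 1L)
  for (tau in 0:tau_max) q[[tau + 1L]] <- matrix(0, N, N)
  means <- matrix(0, N, length(trials))
  for (r in seq_along(trials)) {
    xc <- trials[[r]] - rowMeans(trials[[r]])
    means[, r] <- rowMeans(trials[[r]])
    for (tau in 0:tau_max) {
      w <- if (common_window) T_obs - tau_max else T_obs - tau
      den <- if (divisor == "paper") T_obs - tau_max - 1 else w
      cp <- if (tau == 0L) {
        tcrossprod(xc[, seq_len(w), drop = FALSE])    # symmetric rank-k
      } else {
        tcrossprod(xc[, tau + seq_len(w), drop = FALSE],
                   xc[, seq_len(w), drop = FALSE])
      }
      q[[tau + 1L]] <- q[[tau + 1L]] + cp / den
    }
  }
  q <- lapply(q, function(m) m / length(trials))
  zero_var <- which(diag(q[[1L]]) <= .Machine$double.eps * T_obs)
  if (length(zero_var))
    warning("node(s) with (near) zero variance: ",
            paste(zero_var, collapse = ", "),
            "; covariance inversion will fail downstream", call. = FALSE)
  structure(list(q = q, tau_max = as.integer(tau_max),
                 t_used = T_obs - tau_max, means = rowMeans(means),
                 N = N, T_obs = T_obs, n_trials = length(trials)),
            class = "mvar_covset")
}

#' Theoretical lagged covariances of a stable MVAR network
#'
#' Solves the stationary (Lyapunov) equation `Q0 = A Q0 A' + Sigma` for order
#' 1 — or its companion-form analogue for order 2 — and propagates
#' `Q_tau` through the Yule-Walker recursion (`Q1 = A Q0`, and for order 2
#' `Q1 = A1 Q0 + A2 Q1'`, `Q_tau = A1 Q_{tau-1} + A2 Q_{tau-2}`).  Serves as
#' the infinite-sample oracle for the empirical covariances.
#'
#' @inheritParams mvar_simulate
#' @param tau_max largest lag to return.
#' @return an `mvar_covset` (with `t_used = Inf`).
#' @export
theoretical_covariance <- function(conn, input, tau_max = NULL) {
  if (is.matrix(conn))
    conn <- list(weights = conn, weights2 = NULL, order = 1L)
  a1 <- conn$weights; a2 <- conn$weights2
  N <- nrow(a1)
  if (is.null(tau_max)) tau_max <- if (is.null(a2)) 1L else 2L
  rho <- companion_spectral_radius(if (is.null(a2)) a1 else list(a1, a2))
  if (rho >= 1) stop("unstable connectivity", call. = FALSE)
  sigma <- if (inherits(input, "mvar_input")) input$sigma else input

  if (is.null(a2)) {
    q0 <- lyapunov_fixed_point(a1, sigma)
    q <- vector("list", tau_max + 1L)
    q[[1L]] <- q0
    for (tau in seq_len(tau_max)) q[[tau + 1L]] <- a1 %*% q[[tau]]
  } else {
    comp <- companion_matrix(a1, a2)
    sig2 <- matrix(0, 2 * N, 2 * N)
    sig2[1:N, 1:N] <- sigma
    p <- lyapunov_fixed_point(comp, sig2)
    q0 <- (p[1:N, 1:N] + t(p[1:N, 1:N])) / 2
    q1 <- p[1:N, N + 1:N]                     # E[x_t x_{t-1}'] = Q^1
    q <- vector("list", tau_max + 1L)
    q[[1L]] <- q0; if (tau_max >= 1) q[[2L]] <- q1
    if (tau_max >= 2)
      for (tau in 2:tau_max)
        q[[tau + 1L]] <- a1 %*% q[[tau]] + a2 %*% q[[tau - 1L]]
  }
  structure(list(q = q, tau_max = as.integer(tau_max), t_used = Inf,
                 means = rep(0, N), N = N, T_obs = Inf, n_trials = 1L),
            class = "mvar_covset")
}

# Fixed-point iteration for Q = A Q A' + S; geometric convergence for
# spectral radius < 1, avoids forming the N^2 x N^2 Kronecker system.
lyapunov_fixed_point <- function(a, s, tol = 1e-13, max_iter = 10000L) {
  q <- s
  for (k in seq_len(max_iter)) {
    qn <- a %*% q %*% t(a) + s
    if (max(abs(qn - q)) <= tol * max(1, max(abs(qn)))) {
      return((qn + t(qn)) / 2)
    }
    q <- qn
  }
  warning("Lyapunov iteration did not fully converge", call. = FALSE)
  (q + t(q)) / 2
}

#' Yule-Walker / OLS coefficient estimate from lagged covariances
#'
#' Order 1: `a = Q1 solve(Q0)`.  Order 2: `cbind(a1, a2) = Qt1 solve(Qt0)`
#' with the block matrices `Qt0 = rbind(cbind(Q0, Q1), cbind(t(Q1), Q0))` and
#' `Qt1 = cbind(Q1, Q2)`.  Identical to the least-squares regression of
#' `x_t` on its lagged values (up to end-effects in the mean handling).
#'
#' @param covs an [`mvar_covset`][lagged_covariance].
#' @param order 1 or 2 (must not exceed `covs$tau_max`).
#' @param max_condition refuse inversion when the condition number (2-norm)
#'   of the lag-0 block exceeds this cap.
#' @return for order 1, an `N x N` coefficient matrix; for order 2 a list
#'   `list(a1, a2)`.
#' @export
yule_walker <- function(covs, order = 1, max_condition = 1e12) {
  stopifnot(inherits(covs, "mvar_covset"))
  if (order > covs$tau_max)
    stop("covariance set has too few lags for the requested order",
         call. = FALSE)
  q0 <- covs$q[[1L]]; q1 <- covs$q[[2L]]
  if (order == 1) {
    g <- q0
  } else {
    g <- rbind(cbind(q0, q1), cbind(t(q1), q0))
  }
  kap <- kappa(g, exact = FALSE)
  if (!is.finite(kap) || kap > max_condition) {
    bad <- order(diag(q0))[seq_len(min(3L, covs$N))]
    stop(sprintf(paste0("ill-conditioned lag-0 covariance (condition number ",
                        "%.2e); lowest-variance nodes: %s"),
                 kap, paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (order == 1) {
    t(solve(g, t(q1)))
  } else {
    q2 <- covs$q[[3L]]
    ab <- t(solve(g, t(cbind(q1, q2))))
    n <- covs$N
    list(a1 = ab[, 1:n, drop = FALSE], a2 = ab[, n + 1:n, drop = FALSE])
  }
}

#' Fit an MVAR model to an observed panel
#'
#' The central model-fitting function: computes the empirical lagged
#' covariances of the panel and estimates the connectivity coefficients via
#' the Yule-Walker relation (equivalently, ordinary least squares of each
#' node on the lagged activity of all nodes).
#'
#' @param x panel: `N x T` matrix (rows = nodes), `N x T x trials` array, or
#'   list of trial matrices.  Multi-trial panels are centered per trial and
#'   their covariances averaged before the single inversion.
#' @param order MVAR order, 1 or 2.
#' @param tau_max covariance lags to compute (default `order`).
#' @param keep_data retain the panel inside the fit (needed by
#'   [residuals.mvar()] and [predict.mvar()]).
#' @param ... passed to [lagged_covariance()].
#' @return an object of class `mvar`: list with `coefficients` (matrix, or
#'   `list(a1, a2)` for order 2), `order`, `covs`, `N`, `T_obs`, `n_trials`,
#'   `noise_cov` (innovation covariance estimate `Q0 - a Q1'`), `call`.
#' @examples
#' net <- generate_connectivity("random", N = 5, density = 0.3,
#'                              wmin = 0.05, wmax = 0.2, seed = 1)
#' inp <- generate_input_covariance(5, 0, seed = 2)
#' x <- mvar_simulate(net, inp, T_obs = 5000, seed = 3)
#' fit <- mvar(x)
#' max(abs(coef(fit) - net$weights))
#' @export
mvar <- function(x, order = 1, tau_max = order, keep_data = TRUE, ...) {
  covs <- lagged_covariance(x, tau_max = max(order, tau_max), ...)
  a <- yule_walker(covs, order = order)
  if (order == 1) {
    noise <- covs$q[[1L]] - a %*% t(covs$q[[2L]])
  } else {
    noise <- covs$q[[1L]] - a$a1 %*% t(covs$q[[2L]]) - a$a2 %*% t(covs$q[[3L]])
  }
  structure(list(coefficients = a, order = as.integer(order), covs = covs,
                 N = covs$N, T_obs = covs$T_obs, n_trials = covs$n_trials,
                 noise_cov = (noise + t(noise)) / 2,
                 data = if (keep_data) x else NULL,
                 call = match.call()),
            class = "mvar")
}

coef_matrices <- function(fit) {
  if (fit$order == 1) list(fit$coefficients) else
    list(fit$coefficients$a1, fit$coefficients$a2)
}

#' @export
coef.mvar <- function(object, ...) object$coefficients

#' @export
print.mvar <- function(x, ...) {
  cat(sprintf("MVAR(%d) fit: %d nodes, %s samples%s\n", x$order, x$N,
              format(x$T_obs),
              if (x$n_trials > 1) sprintf(" x %d trials", x$n_trials) else ""))
  a <- coef_matrices(x)[[1L]]
  cat(sprintf("  coefficient range [%.4f, %.4f], spectral radius %.3f\n",
              min(a), max(a),
              companion_spectral_radius(if (x$order == 1) x$coefficients
                                        else list(x$coefficients$a1,
                                                  x$coefficients$a2))))
  invisible(x)
}

#' @export
summary.mvar <- function(object, ...) {
  mats <- coef_matrices(object)
  off <- lapply(mats, function(m) m[row(m) != col(m)])
  s <- list(order = object$order, N = object$N, T_obs = object$T_obs,
            n_trials = object$n_trials,
            spectral_radius = companion_spectral_radius(
              if (object$order == 1) object$coefficients
              else list(object$coefficients$a1, object$coefficients$a2)),
            coef_quantiles = lapply(off, quantile,
                                    probs = c(0, .05, .25, .5, .75, .95, 1)),
            diag_mean = mean(diag(mats[[1L]])),
            noise_var_mean = mean(diag(object$noise_cov)))
  class(s) <- "summary.mvar"
  s
}

#' @export
print.summary.mvar <- function(x, ...) {
  cat(sprintf("MVAR(%d) fit summary: %d nodes, %s samples%s\n", x$order, x$N,
              format(x$T_obs),
              if (x$n_trials > 1) sprintf(" x %d trials", x$n_trials) else ""))
  cat(sprintf("  spectral radius %.3f, mean diagonal coefficient %.3f\n",
              x$spectral_radius, x$diag_mean))
  cat(sprintf("  mean innovation variance %.3f\n", x$noise_var_mean))
  for (k in seq_along(x$coef_quantiles)) {
    cat(sprintf("  off-diagonal coefficients (lag %d):\n", k))
    print(round(x$coef_quantiles[[k]], 4))
  }
  invisible(x)
}

#' Simulate new data from a fitted MVAR model
#'
#' @param object an [mvar] fit.
#' @param nsim number of time samples per simulated panel.
#' @param seed integer seed.
#' @param n number of panels (returned as a list if `> 1`).
#' @param ... unused.
#' @return an `N x nsim` matrix (or list of such matrices).
#' @export
simulate.mvar <- function(object, nsim = object$covs$T_obs, seed = NULL,
                          n = 1, ...) {
  a <- object$coefficients
  net <- structure(list(weights = if (object$order == 1) a else a$a1,
                        weights2 = if (object$order == 1) NULL else a$a2,
                        order = object$order, N = object$N, rescale = 1,
                        topology = "fitted"),
                   class = "mvar_network")
  # project the estimated innovation covariance onto the PSD cone
  ev <- eigen(object$noise_cov, symmetric = TRUE)
  mix <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), object$N)
  inp <- structure(list(sigma = tcrossprod(mix), mixing = mix, N = object$N),
                   class = "mvar_input")
  with_seed(seed, {
    out <- lapply(seq_len(n), function(i)
      mvar_simulate(net, inp, T_obs = nsim))
    if (n == 1) out[[1L]] else out
  })
}

#' One-step-ahead predictions from a fitted MVAR model
#'
#' @param object an [mvar] fit (with `keep_data = TRUE`, or supply `newdata`).
#' @param newdata optional `N x T` matrix to predict on.
#' @param ... unused.
#' @return an `N x (T - order)` matrix of predictions of `x_t` from its past;
#'   column `t` predicts sample `t + order` of the input.
#' @export
predict.mvar <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data else newdata
  if (is.null(x)) stop("fit carries no data; supply 'newdata'", call. = FALSE)
  trials <- as_trial_list(x)
  if (length(trials) > 1L)
    stop("prediction expects a single-trial panel", call. = FALSE)
  x <- trials[[1L]] - rowMeans(trials[[1L]])
  T_obs <- ncol(x)
  p <- object$order
  a <- coef_matrices(object)
  pred <- a[[1L]] %*% x[, p:(T_obs - 1), drop = FALSE]
  if (p == 2)
    pred <- pred + a[[2L]] %*% x[, 1:(T_obs - 2), drop = FALSE]
  pred + rowMeans(trials[[1L]])
}

#' @export
residuals.mvar <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data else newdata
  if (is.null(x)) stop("fit carries no data; supply 'newdata'", call. = FALSE)
  trials <- as_trial_list(x)
  if (length(trials) > 1L)
    stop("residuals expect a single-trial panel", call. = FALSE)
  x <- trials[[1L]]
  p <- object$order
  x[, (p + 1):ncol(x), drop = FALSE] - predict(object, newdata = x)
}

#' Image plot of fitted MVAR coefficients
#'
#' @param x an [mvar] fit.
#' @param lag which coefficient matrix to draw (order-2 fits).
#' @param ... passed to [graphics::image()].
#' @export
plot.mvar <- function(x, lag = 1, ...) {
  m <- coef_matrices(x)[[lag]]
  lim <- max(abs(m))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[nrow(m):1, , drop = FALSE]),
                  zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(65, "Blue-Red 3"),
                  xlab = "source node j", ylab = "target node i",
                  main = sprintf("MVAR(%d) coefficients, lag %d", x$order, lag),
                  ...)
  invisible(x)
}
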