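# Surrogate time series (RP / CS / PR / STD) and null coefficient ensembles.

#' Generate one surrogate panel
#'
#' Destroys the cross-covariance structure of the panel while preserving
#' per-node marginal features, applying the chosen scheme to each node's time
#' series independently:
#' \describe{
#'   \item{RP}{random permutation of the time indices;}
#'   \item{CS}{circular shift by a random offset `t0` drawn uniformly on
#'     `{1, ..., T}` (`t0 = 1` returns the original series);}
#'   \item{PR}{phase randomization: multiply each discrete-Fourier
#'     coefficient by `exp(2*pi*1i*phi)` with independent uniform phases,
#'     conjugate-symmetrized so the inverse transform is real;}
#'   \item{STD}{replace every node by i.i.d. `N(0, sbar^2)` noise, where
#'     `sbar` is the per-node standard deviation averaged over all nodes.}
#' }
#'
#' @param x panel (`N x T` matrix; multi-trial inputs are shuffled per trial
#'   independently and returned in the same shape).
#' @param method `"RP"`, `"CS"`, `"PR"` or `"STD"`.
#' @param seed integer seed.
#' @param pr_real `"symmetrize"` (default: conjugate-symmetric phases) or
#'   `"real-part"` (keep unconstrained phases, take the real part of the
#'   inverse transform).
#' @return a panel of the same shape.
#' @export
make_surrogate <- function(x, method = c("RP", "CS", "PR", "STD"),
                           seed = NULL,
                           pr_real = c("symmetrize", "real-part")) {
  method <- match.arg(method)
  pr_real <- match.arg(pr_real)
  multi <- is.array(x) && length(dim(x)) == 3L
  trials <- as_trial_list(x)
  if (ncol(trials[[1L]]) < 2L) stop("need T >= 2", call. = FALSE)
  out <- with_seed(seed,
    lapply(trials, surrogate_one, method = method, pr_real = pr_real))
  if (multi) {
    array(unlist(out), dim = dim(x), dimnames = dimnames(x))
  } else if (is.matrix(x)) out[[1L]] else out
}

surrogate_one <- function(m, method, pr_real) {
  N <- nrow(m); T_obs <- ncol(m)
  switch(method,
    RP = {
      for (i in seq_len(N)) m[i, ] <- m[i, sample.int(T_obs)]
      m
    },
    CS = {
      for (i in seq_len(N)) {
        t0 <- sample.int(T_obs, 1L)
        if (t0 > 1L) m[i, ] <- m[i, c(t0:T_obs, 1:(t0 - 1L))]
      }
      m
    },
    PR = phase_randomize_panel(m, pr_real),
    STD = {
      sbar <- mean(apply(m, 1L, sd))
      matrix(rnorm(N * T_obs, sd = sbar), N, T_obs)
    })
}

phase_randomize <- function(v, pr_real = "symmetrize") {
  drop(phase_randomize_panel(matrix(v, nrow = 1L), pr_real))
}

# Batched over nodes: one forward and one inverse multi-column FFT.
# Independent uniform phases per node; under "symmetrize" they are made
# conjugate-symmetric (phi(T-k) = -phi(k), zero phase at the DC and Nyquist
# bins) so the inverse transform is exactly real.
phase_randomize_panel <- function(m, pr_real = "symmetrize") {
  N <- nrow(m); T_obs <- ncol(m)
  f <- stats::mvfft(t(m))                       # T x N
  if (pr_real == "symmetrize") {
    # draw phases for the lower half-spectrum only and mirror conjugates
    k <- 2:ceiling((T_obs + 1L) / 2L)
    rot <- matrix(1 + 0i, T_obs, N)
    rk <- exp(1i * matrix(runif(length(k) * N, 0, 2 * pi), length(k), N))
    if (T_obs %% 2L == 0L) rk[length(k), ] <- 1   # Nyquist bin stays real
    rot[k, ] <- rk
    rot[T_obs + 2L - k, ] <- Conj(rk)
  } else {
    rot <- exp(1i * matrix(runif(T_obs * N, 0, 2 * pi), T_obs, N))
  }
  t(Re(stats::mvfft(f * rot, inverse = TRUE))) / T_obs
}

#' Build a null ensemble of surrogate coefficient matrices
#'
#' Generates `S` surrogate panels, estimates the requested statistic on each
#' (Yule-Walker coefficients of order 1 or 2, or the conditional Granger
#' log-ratio matrix) and stacks the results.  Per-surrogate seeds are derived
#' from the master seed with a counter-based scheme, so the ensemble is
#' reproducible and independent of evaluation order.  A surrogate whose
#' covariance turns out singular is re-drawn (up to 5 retries).
#'
#' @param x panel (matrix, array or trial list; multi-trial panels are
#'   shuffled per trial and their covariances averaged, as in estimation).
#' @param S number of surrogates.
#' @param method surrogate scheme, see [make_surrogate()].
#' @param estimator `"order1"`, `"order2"` or `"grc"`.
#' @param seed master integer seed.
#' @return an object of class `mvar_null`: list with `values` (`S x N x N`
#'   array; `values2` as well for `"order2"`), `method`, `S`, `estimator_tag`,
#'   `seed`.
#' @examples
#' x <- matrix(rnorm(4 * 300), 4)
#' null <- build_null(x, S = 20, method = "RP", seed = 1)
#' dim(null$values)
#' @export
build_null <- function(x, S, method = c("RP", "CS", "PR", "STD"),
                       estimator = c("order1", "order2", "grc"),
                       seed = NULL) {
  method <- match.arg(method)
  estimator <- match.arg(estimator)
  if (S < 1) stop("S must be >= 1", call. = FALSE)
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  N <- nrow(as_trial_list(x)[[1L]])
  values <- array(NA_real_, dim = c(S, N, N))
  values2 <- if (estimator == "order2") array(NA_real_, dim = c(S, N, N))
  for (s in seq_len(S)) {
    est <- NULL
    for (retry in 0:5) {
      sx <- make_surrogate(x, method = method,
                           seed = derive_seed(seed, s, stream = retry))
      est <- tryCatch(surrogate_estimate(sx, estimator),
                      error = function(e) NULL)
      if (!is.null(est)) break
    }
    if (is.null(est))
      stop(sprintf("surrogate %d: estimation failed after retries", s),
           call. = FALSE)
    values[s, , ] <- est[[1L]]
    if (estimator == "order2") values2[s, , ] <- est[[2L]]
  }
  structure(list(values = values, values2 = values2, method = method,
                 S = as.integer(S), estimator_tag = estimator,
                 seed = seed, N = N),
            class = "mvar_null")
}

surrogate_estimate <- function(sx, estimator) {
  if (estimator == "grc") {
    list(grc_from_panel(as_trial_list(sx)[[1L]])$scores)
  } else {
    ord <- if (estimator == "order1") 1L else 2L
    a <- yule_walker(lagged_covariance(sx, tau_max = ord), order = ord)
    if (ord == 1L) list(a) else list(a$a1, a$a2)
  }
}

#' @export
print.mvar_null <- function(x, ...) {
  cat(sprintf("Surrogate null ensemble: S = %d, method %s, estimator %s, %d nodes\n",
              x$S, x$method, x$estimator_tag, x$N))
  cat(sprintf("  pooled spread: sd %.4g, range [%.4g, %.4g]\n",
              sd(x$values), min(x$values), max(x$values)))
  invisible(x)
}
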