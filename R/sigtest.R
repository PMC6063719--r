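# Nonparametric significance decisions from surrogate null ensembles.

new_detect <- function(decisions, pvals, thresholds, alpha, tails, test_tag,
                       statistic = NULL, lower = NULL, method = NULL,
                       S = NULL) {
  structure(list(decisions = decisions, pvals = pvals,
                 thresholds = thresholds, lower_thresholds = lower,
                 alpha = alpha, tails = as.integer(tails),
                 test_tag = test_tag, statistic = statistic,
                 surrogate_method = method, S = S),
            class = "mvar_detect")
}

#' @export
print.mvar_detect <- function(x, ...) {
  n_total <- sum(!is.na(x$decisions))
  cat(sprintf("MVAR detection report (%s test%s, alpha = %g, %d-tailed)\n",
              x$test_tag,
              if (!is.null(x$surrogate_method))
                sprintf(", %s surrogates, S = %d", x$surrogate_method, x$S)
              else "",
              x$alpha, x$tails))
  cat(sprintf("  %d / %d connections declared significant (%.2f%%)\n",
              sum(x$decisions, na.rm = TRUE), n_total,
              100 * sum(x$decisions, na.rm = TRUE) / max(n_total, 1)))
  invisible(x)
}

#' @export
summary.mvar_detect <- function(object, truth = NULL, ...) {
  print(object)
  if (!is.null(truth)) print(detection_rates(object, truth))
  invisible(object)
}

detect_input_matrix <- function(estimate, lag = 1) {
  if (inherits(estimate, "mvar")) {
    coef_matrices(estimate)[[lag]]
  } else if (is.list(estimate) && !is.data.frame(estimate)) {
    estimate[[lag]]
  } else estimate
}

null_values <- function(null, lag = 1) {
  if (lag == 1) null$values else {
    if (is.null(null$values2))
      stop("null ensemble has no second-lag values", call. = FALSE)
    null$values2
  }
}

# Type-1 (inverted ECDF) empirical quantile of each edge's S null values:
# thresholds are always realized surrogate values, well-defined at small S.
# Partial sort per edge keeps this O(S N^2) without full sorting.
edge_quantile <- function(vals, p) {
  d <- dim(vals)
  m <- matrix(vals, d[1L])
  out <- vapply(seq_len(ncol(m)), function(j) {
    v <- m[, j]
    if (anyNA(v)) v <- v[!is.na(v)]
    n <- length(v)
    if (!n) return(NA_real_)
    k <- min(max(ceiling(n * p), 1L), n)
    sort.int(v, partial = k)[k]
  }, 0)
  matrix(out, d[2L], d[3L])
}

#' Local (per-connection) nonparametric significance test
#'
#' For each connection `(i, j)` the null distribution is the set of `S`
#' values of the same matrix element across the surrogate ensemble.
#' One-tailed: significant when the observed estimate exceeds the empirical
#' `1 - alpha` quantile of its null.  Two-tailed: the tail mass is split,
#' `alpha/2` per side, and either exceedance is significant (this is how
#' negative, e.g. inhibitory, couplings are detected).  Empirical p-values
#' use the permutation `+1` correction: one-tailed
#' `p = (1 + #\{null >= obs\}) / (S + 1)`, two-tailed with `|.|`.
#'
#' @param estimate observed coefficient matrix (or an [mvar] fit, or the
#'   list of two matrices for order-2 fits together with `lag`).
#' @param null an [`mvar_null`][build_null] ensemble.
#' @param alpha nominal false-alarm rate.
#' @param tails 1 or 2.
#' @param lag which coefficient matrix to test for order-2 ensembles.
#' @return an object of class `mvar_detect`: list with `decisions`, `pvals`,
#'   `thresholds` (+ `lower_thresholds` when two-tailed), `alpha`, `tails`,
#'   `test_tag`, `statistic`.
#' @examples
#' x <- matrix(rnorm(3 * 400), 3)
#' fit <- mvar(x)
#' null <- build_null(x, S = 99, method = "RP", seed = 1)
#' local_test(fit, null, alpha = 0.05)
#' @export
local_test <- function(estimate, null, alpha = 0.02, tails = 1, lag = 1) {
  check_alpha(alpha)
  obs <- detect_input_matrix(estimate, lag)
  vals <- null_values(null, lag)
  if (!all(dim(obs) == dim(vals)[2:3]))
    stop("estimate and null ensemble dimensions disagree", call. = FALSE)
  if (null$S < ceiling(1 / alpha))
    warning(sprintf("S = %d surrogates is small for alpha = %g (recommend S >= %d)",
                    null$S, alpha, ceiling(1 / alpha)), call. = FALSE)
  S <- null$S
  obs_rep <- aperm(array(obs, dim = c(dim(obs), S)), c(3L, 1L, 2L))
  if (tails == 1) {
    thr <- edge_quantile(vals, 1 - alpha)
    decisions <- obs > thr
    exceed <- colSums(vals >= obs_rep, na.rm = TRUE, dims = 1L)
    lower <- NULL
  } else if (tails == 2) {
    thr <- edge_quantile(vals, 1 - alpha / 2)
    lower <- edge_quantile(vals, alpha / 2)
    decisions <- obs > thr | obs < lower
    exceed <- colSums(abs(vals) >= abs(obs_rep), na.rm = TRUE, dims = 1L)
  } else stop("tails must be 1 or 2", call. = FALSE)
  decisions[is.na(thr)] <- NA
  pvals <- (1 + exceed) / (S + 1)
  new_detect(decisions, pvals, thr, alpha, tails, "local",
             statistic = obs, lower = lower, method = null$method, S = S)
}

#' Global (pooled) nonparametric significance test
#'
#' A single threshold is taken from the pooled distribution of all `S * N^2`
#' surrogate matrix elements; every connection is compared with the same cut.
#' The pool includes the diagonal elements by default (set
#' `include_diag = FALSE` to drop them, e.g. with circular-shift surrogates
#' whose preserved autocovariances contaminate the pool).
#'
#' @inheritParams local_test
#' @param include_diag keep diagonal elements in the pooled null.
#' @return an `mvar_detect` report (scalar `thresholds`).
#' @export
global_test <- function(estimate, null, alpha = 0.02, tails = 1, lag = 1,
                        include_diag = TRUE) {
  check_alpha(alpha)
  obs <- detect_input_matrix(estimate, lag)
  vals <- null_values(null, lag)
  if (!all(dim(obs) == dim(vals)[2:3]))
    stop("estimate and null ensemble dimensions disagree", call. = FALSE)
  if (!include_diag) {
    N <- dim(vals)[2L]
    for (i in seq_len(N)) vals[, i, i] <- NA_real_
  }
  pool <- vals[!is.na(vals)]
  S_pool <- length(pool)
  if (tails == 1) {
    thr <- quantile(pool, 1 - alpha, type = 1, names = FALSE)
    decisions <- obs > thr
    pvals <- (1 + vapply(obs, function(o) sum(pool >= o), 0)) / (S_pool + 1)
    lower <- NULL
  } else if (tails == 2) {
    thr <- quantile(pool, 1 - alpha / 2, type = 1, names = FALSE)
    lower <- quantile(pool, alpha / 2, type = 1, names = FALSE)
    decisions <- obs > thr | obs < lower
    apool <- abs(pool)
    pvals <- (1 + vapply(abs(obs), function(o) sum(apool >= o), 0)) /
      (S_pool + 1)
  } else stop("tails must be 1 or 2", call. = FALSE)
  pvals <- matrix(pvals, nrow(obs), ncol(obs))
  new_detect(decisions, pvals, thr, alpha, tails, "global",
             statistic = obs, lower = lower, method = null$method,
             S = null$S)
}

#' Fit-and-test convenience wrapper
#'
#' Fits the MVAR model, builds the surrogate null ensemble and runs the
#' local or global test in one call.
#'
#' @param x panel (matrix, array or trial list).
#' @param method `"local"` or `"global"`.
#' @param surrogate surrogate scheme, see [make_surrogate()].
#' @param S number of surrogates.
#' @param alpha nominal false-alarm rate.
#' @param tails 1 or 2.
#' @param order MVAR order (1 or 2).
#' @param seed master seed for the surrogate ensemble.
#' @param ... passed to [global_test()] (e.g. `include_diag`).
#' @return an `mvar_detect` report with the fit attached as attribute
#'   `"fit"`; for order 2 a list of two reports (one per lag matrix).
#' @export
mvar_test <- function(x, method = c("local", "global"),
                      surrogate = c("RP", "CS", "PR", "STD"),
                      S = 400, alpha = 0.02, tails = 1, order = 1,
                      seed = NULL, ...) {
  method <- match.arg(method)
  surrogate <- match.arg(surrogate)
  fit <- mvar(x, order = order, keep_data = FALSE)
  null <- build_null(x, S = S, method = surrogate,
                     estimator = if (order == 1) "order1" else "order2",
                     seed = seed)
  test_fun <- if (method == "local") local_test else global_test
  if (order == 1) {
    rep1 <- test_fun(fit, null, alpha = alpha, tails = tails, ...)
    attr(rep1, "fit") <- fit
    rep1
  } else {
    out <- lapply(1:2, function(l)
      test_fun(fit, null, alpha = alpha, tails = tails, lag = l, ...))
    names(out) <- c("a1", "a2")
    attr(out, "fit") <- fit
    out
  }
}

#' Nonparametric permutation test for conditional Granger causality
#'
#' Builds null distributions for the GRc log-ratios by random permutation:
#' in `"target"` mode only the target node's series is shuffled (its lagged
#' copy in the predictors included) and the scores of its incoming
#' connections recomputed; in `"full"` mode all nodes are shuffled
#' simultaneously and the whole GRc matrix recomputed, as in the
#' coefficient-based tests.  Local-style per-connection thresholds.
#'
#' @param x `N x T` panel matrix.
#' @param mode `"target"` or `"full"`.
#' @param S number of permutations.
#' @param alpha nominal false-alarm rate.
#' @param tails 1 (GRc scores are nonnegative) — kept for interface
#'   symmetry.
#' @param seed master seed.
#' @return an `mvar_detect` report (`test_tag` `"grc-target"`/`"grc-full"`).
#' @export
nonparam_grc_test <- function(x, mode = c("target", "full"), S = 100,
                              alpha = 0.02, tails = 1, seed = NULL) {
  mode <- match.arg(mode)
  check_alpha(alpha)
  x <- as_trial_list(x)[[1L]]
  N <- nrow(x); T_obs <- ncol(x)
  if (is.null(seed)) seed <- floor(runif(1, 1, 2^31 - 1))
  obs <- grc_from_panel(x)$scores
  vals <- array(NA_real_, dim = c(S, N, N))
  if (mode == "full") {
    for (s in seq_len(S)) {
      sx <- make_surrogate(x, "RP", seed = derive_seed(seed, s))
      vals[s, , ] <- grc_from_panel(sx)$scores
    }
  } else {
    for (s in seq_len(S)) {
      perm_rows <- with_seed(derive_seed(seed, s),
                             replicate(N, sample.int(T_obs)))
      for (i in seq_len(N)) {
        xi <- x
        xi[i, ] <- x[i, perm_rows[, i]]
        vals[s, i, ] <- grc_target_row(xi, i)
      }
    }
  }
  null <- structure(list(values = vals, values2 = NULL, method = "RP",
                         S = as.integer(S),
                         estimator_tag = paste0("grc-", mode),
                         seed = seed, N = N),
                    class = "mvar_null")
  rep <- local_test(obs, null, alpha = alpha, tails = tails)
  rep$test_tag <- paste0("grc-", mode)
  rep
}

# GRc scores of all incoming connections of one target, full regression.
grc_target_row <- function(x, i) {
  N <- nrow(x); T_obs <- ncol(x)
  y <- x[i, 2:T_obs]; y <- y - mean(y)
  z <- x[, 1:(T_obs - 1), drop = FALSE]
  z <- z - rowMeans(z)
  g <- tcrossprod(z)
  ginv <- solve(g)
  cv <- drop(z %*% y)
  beta <- drop(ginv %*% cv)
  rss_full <- max(sum(y^2) - sum(beta * cv), 0)
  out <- log1p(pmax(beta^2 / diag(ginv), 0) / (rss_full + 1e-12))
  out[i] <- NA_real_
  out
}
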