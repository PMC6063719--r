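# Granger-causality baselines: nested lag-1 regressions, unconditional (GRu)
# and conditional (GRc) log-ratios, and their parametric F-tests.

# Centered design: target samples t = 2..T regressed on source samples
# t = 1..T-1.  Returns the residual sum of squares and the coefficients.
granger_regression <- function(x, target, sources) {
  T_obs <- ncol(x)
  y <- x[target, 2:T_obs] - mean(x[target, 2:T_obs])
  z <- x[sources, 1:(T_obs - 1), drop = FALSE]
  z <- z - rowMeans(z)
  g <- tcrossprod(z)
  c_vec <- drop(z %*% y)
  beta <- tryCatch(solve(g, c_vec), error = function(e)
    stop(sprintf("rank-deficient regressor matrix for target %d (sources %s)",
                 target, paste(sources, collapse = ",")), call. = FALSE))
  rss <- sum(y^2) - sum(beta * c_vec)
  list(rss = max(rss, 0), beta = beta)
}

#' Residual norm of a lagged least-squares regression
#'
#' Fits `x_i(t) = sum_{j in S} a_ij x_j(t-1) + e(t)` for `t = 2..T` by least
#' squares (intercept handled by mean-centering) and returns the residual
#' norm `sqrt(sum_t e(t)^2)`.
#'
#' @param x `N x T` panel matrix.
#' @param target target node index `i`.
#' @param sources nonempty set of source node indices `S`.
#' @return non-negative scalar residual norm.
#' @export
residual_std <- function(x, target, sources) {
  x <- as_trial_list(x)[[1L]]
  if (length(sources) < 1L) stop("sources must be nonempty", call. = FALSE)
  if (ncol(x) < length(sources) + 2L)
    stop("too few samples for the requested regression", call. = FALSE)
  sqrt(granger_regression(x, target, sources)$rss)
}

#' Granger-causality log-ratio for one connection
#'
#' Compares the residual sums of squares of two nested lag-1 regressions of
#' the target node: `GRu` conditions only on the target itself (reduced)
#' versus target + source (full); `GRc` conditions on all nodes except the
#' source (reduced) versus all nodes (full).  The score is the log of the
#' ratio of residual *sums of squares*, `ln(RSS_reduced / RSS_full) >= 0`,
#' the classic Granger measure whose F-test is [granger_f_test()].
#'
#' @param x `N x T` panel matrix.
#' @param i target node.
#' @param j candidate source node (`i != j`).
#' @param kind `"GRu"` (unconditional) or `"GRc"` (conditional).
#' @return an object of class `granger_score`: list with `value`, `kind`,
#'   `target`, `source`, `residual_full`, `residual_reduced` (residual norms
#'   as in [residual_std()]).
#' @export
granger_logratio <- function(x, i, j, kind = c("GRu", "GRc")) {
  kind <- match.arg(kind)
  x <- as_trial_list(x)[[1L]]
  if (i == j) stop("target and source must differ", call. = FALSE)
  N <- nrow(x)
  if (kind == "GRu") {
    reduced <- granger_regression(x, i, i)
    full <- granger_regression(x, i, sort(c(i, j)))
  } else {
    reduced <- granger_regression(x, i, setdiff(seq_len(N), j))
    full <- granger_regression(x, i, seq_len(N))
  }
  eps <- 1e-12
  value <- log((reduced$rss + eps) / (full$rss + eps))
  structure(list(value = max(value, 0), kind = kind, target = i, source = j,
                 residual_full = sqrt(full$rss),
                 residual_reduced = sqrt(reduced$rss)),
            class = "granger_score")
}

#' @export
print.granger_score <- function(x, ...) {
  cat(sprintf("%s(%d -> %d) = %.5g  (residuals: reduced %.4g, full %.4g)\n",
              x$kind, x$source, x$target, x$value,
              x$residual_reduced, x$residual_full))
  invisible(x)
}

#' Parametric F-test for a Granger log-ratio
#'
#' The statistic `exp(GR) - 1` (the relative excess residual sum of squares
#' of the reduced model) is compared with `phi(alpha, 1, d) / d`, where `phi`
#' is the inverse survival function of the F distribution and the degrees of
#' freedom are `d = T - 3` for GRu and `d = T - N - 1` for GRc.
#'
#' @param score a [`granger_score`][granger_logratio], or a bare numeric
#'   log-ratio (in which case `kind` must be given).
#' @param T_obs number of time samples used in the regressions.
#' @param N network size (needed for GRc degrees of freedom).
#' @param alpha nominal false-alarm rate in (0, 1).
#' @param kind override/supply the score kind.
#' @return list with `significant` (logical), `statistic` (`exp(GR) - 1`),
#'   `threshold` (`phi(alpha, 1, d)/d`), `df` and `p_value`.
#' @export
granger_f_test <- function(score, T_obs, N = NULL, alpha = 0.02,
                           kind = NULL) {
  check_alpha(alpha)
  if (inherits(score, "granger_score")) {
    if (is.null(kind)) kind <- score$kind
    value <- score$value
  } else {
    if (is.null(kind)) stop("supply 'kind' for a bare numeric score",
                            call. = FALSE)
    value <- score
  }
  d <- granger_df(kind, T_obs, N)
  stat <- exp(value) - 1
  thr <- qf(alpha, 1, d, lower.tail = FALSE) / d
  list(significant = stat > thr, statistic = stat, threshold = thr, df = d,
       p_value = pf(stat * d, 1, d, lower.tail = FALSE))
}

granger_df <- function(kind, T_obs, N) {
  d <- if (kind == "GRu") T_obs - 3 else {
    if (is.null(N)) stop("N is required for GRc degrees of freedom",
                         call. = FALSE)
    T_obs - N - 1
  }
  if (d <= 0) stop("nonpositive degrees of freedom", call. = FALSE)
  d
}

#' All-pairs Granger log-ratio matrix
#'
#' Computes `GR(j -> i)` for every ordered pair.  For `"GRc"` this costs a
#' single full regression per panel: the reduced-model residual for dropping
#' source `j` follows from the standard rank-one identity
#' `RSS_{-j} = RSS_full + beta_j^2 / (G^{-1})_{jj}` with `G` the Gram matrix
#' of the lagged predictors.
#'
#' @param x `N x T` panel matrix.
#' @param kind `"GRc"` or `"GRu"`.
#' @return `N x N` matrix of scores (`[i, j]` is `j -> i`); diagonal `NA`.
#' @export
granger_matrix <- function(x, kind = c("GRc", "GRu")) {
  kind <- match.arg(kind)
  x <- as_trial_list(x)[[1L]]
  N <- nrow(x)
  if (kind == "GRu") return(gru_from_panel(x))
  grc_from_panel(x)$scores
}

# All-pairs GRu from shared crossproducts: for each (target i, source j) the
# full model has the two lagged regressors (x_i, x_j), so its normal
# equations are 2 x 2 and solvable in closed form.
gru_from_panel <- function(x) {
  T_obs <- ncol(x)
  y <- x[, 2:T_obs, drop = FALSE]; y <- y - rowMeans(y)
  z <- x[, 1:(T_obs - 1), drop = FALSE]; z <- z - rowMeans(z)
  g <- tcrossprod(z)                  # G[i, j] = z_i . z_j
  cyz <- tcrossprod(y, z)             # C[i, j] = y_i . z_j
  yy <- rowSums(y^2)
  gd <- diag(g)
  rss_red <- yy - cyz[cbind(seq_len(nrow(x)), seq_len(nrow(x)))]^2 / gd
  # 2x2 solve: det = G_ii G_jj - G_ij^2; beta = det^-1 [G_jj c_i - G_ij c_j;
  #                                                     G_ii c_j - G_ij c_i]
  det2 <- outer(gd, gd) - g^2
  ci_mat <- matrix(diag(cyz), nrow(x), nrow(x))     # C[i, i] per row
  cj_mat <- cyz                                     # C[i, j]
  b1 <- (matrix(gd, nrow(x), nrow(x), byrow = TRUE) * ci_mat -
           g * cj_mat) / det2
  b2 <- (matrix(gd, nrow(x), nrow(x)) * cj_mat - g * ci_mat) / det2
  rss_full <- yy - (b1 * ci_mat + b2 * cj_mat)
  eps <- 1e-12
  out <- log(pmax(rss_red + eps, eps) /
               pmax(pmin(rss_full, rss_red) + eps, eps))
  diag(out) <- NA_real_
  out
}

# Full-panel GRc machinery shared with the nonparametric permutation tests.
# Returns the score matrix plus the pieces needed to rebuild single rows.
grc_from_panel <- function(x) {
  T_obs <- ncol(x)
  y <- x[, 2:T_obs, drop = FALSE]
  z <- x[, 1:(T_obs - 1), drop = FALSE]
  y <- y - rowMeans(y)
  z <- z - rowMeans(z)
  g <- tcrossprod(z)
  ginv <- tryCatch(solve(g), error = function(e)
    stop("rank-deficient regressor matrix in GRc computation", call. = FALSE))
  cyz <- tcrossprod(y, z)            # N x N, row i = Z x y_i
  b <- cyz %*% ginv                  # coefficient matrix, row i = target i
  rss_full <- rowSums(y^2) - rowSums(b * cyz)
  rss_full <- pmax(rss_full, 0)
  dg <- diag(ginv)
  eps <- 1e-12
  scores <- log1p(pmax(sweep(b^2, 2, dg, "/"), 0) /
                    (rss_full + eps))
  diag(scores) <- NA_real_
  list(scores = scores, ginv = ginv, z = z, rss_full = rss_full)
}

#' Parametric Granger detection report for a whole panel
#'
#' Runs [granger_matrix()] and thresholds every off-diagonal connection with
#' the F-test of [granger_f_test()].
#'
#' @inheritParams granger_matrix
#' @param alpha nominal false-alarm rate.
#' @return an [`mvar_detect`][local_test] report (`test_tag`
#'   `"grc-parametric"` or `"gru-parametric"`).
#' @export
granger_parametric_test <- function(x, kind = c("GRc", "GRu"), alpha = 0.02) {
  kind <- match.arg(kind)
  check_alpha(alpha)
  x <- as_trial_list(x)[[1L]]
  N <- nrow(x); T_obs <- ncol(x)
  scores <- granger_matrix(x, kind)
  d <- granger_df(kind, T_obs, N)
  thr <- qf(alpha, 1, d, lower.tail = FALSE) / d
  stat <- exp(scores) - 1
  decisions <- !is.na(stat) & stat > thr
  pvals <- pf(stat * d, 1, d, lower.tail = FALSE)
  new_detect(decisions = decisions, pvals = pvals, thresholds = thr,
             alpha = alpha, tails = 1L,
             test_tag = paste0(tolower(kind), "-parametric"),
             statistic = scores)
}
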