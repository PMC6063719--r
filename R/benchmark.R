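# Benchmark harness: ROC/AUC, Spearman rank match, false-alarm and miss
# rates stratified by connection class, and seeded simulation sweeps.

#' Area under the ROC curve for connection scores
#'
#' Slides a common threshold over the score matrix and accumulates
#' true-positive and false-alarm rates against the ground-truth mask.  The
#' AUC is computed with the rank (Mann-Whitney) identity, so ties are
#' handled by mid-ranks.
#'
#' @param scores real `N x N` matrix of connection estimates (`NA` entries
#'   are excluded).
#' @param truth_mask boolean `N x N` ground-truth mask (or an
#'   [`mvar_network`][generate_connectivity]).
#' @param include_self evaluate diagonal (self-connection) entries too.
#' @return list with `auc` and `curve` (data frame with columns `threshold`,
#'   `fpr`, `tpr`).
#' @export
roc_auc <- function(scores, truth_mask, include_self = FALSE) {
  if (inherits(truth_mask, "mvar_network")) truth_mask <- truth_mask$mask
  stopifnot(all(dim(scores) == dim(truth_mask)))
  keep <- !is.na(scores)
  if (!include_self) keep <- keep & (row(scores) != col(scores))
  s <- scores[keep]; y <- truth_mask[keep]
  n_pos <- sum(y); n_neg <- sum(!y)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC undefined: need at least one existing and one absent connection",
         call. = FALSE)
  r <- rank(s)
  auc <- (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(s), decreasing = TRUE)
  ord <- order(s, decreasing = TRUE)
  tp <- cumsum(y[ord]); fp <- cumsum(!y[ord])
  last <- !duplicated(s[ord], fromLast = TRUE)  # last index at each value
  curve <- data.frame(threshold = s[ord][last],
                      fpr = fp[last] / n_neg, tpr = tp[last] / n_pos)
  list(auc = auc, curve = rbind(data.frame(threshold = Inf, fpr = 0, tpr = 0),
                                curve))
}

#' Spearman rank correlation between estimates and true weights
#'
#' @param estimates real `N x N` matrix of estimated values.
#' @param truth_weights real `N x N` matrix of ground-truth weights (or an
#'   `mvar_network`).
#' @param include_self include diagonal entries.
#' @return Spearman correlation in `[-1, 1]`.
#' @export
rank_match <- function(estimates, truth_weights, include_self = FALSE) {
  if (inherits(truth_weights, "mvar_network"))
    truth_weights <- truth_weights$weights
  stopifnot(all(dim(estimates) == dim(truth_weights)))
  keep <- !is.na(estimates)
  if (!include_self) keep <- keep & (row(estimates) != col(estimates))
  e <- estimates[keep]; w <- truth_weights[keep]
  if (sum(keep) < 3L) stop("need at least 3 compared connections", call. = FALSE)
  if (sd(e) == 0 || sd(w) == 0)
    stop("rank correlation undefined for constant values", call. = FALSE)
  cor(e, w, method = "spearman")
}

#' Standard connection classes of a ground-truth network
#'
#' Returns named boolean masks partitioning (a subset of) the connection
#' matrix: `self`, `unidirectional` and `reciprocal` for any topology, plus
#' topology-specific classes (`intra_group` / `hub` for modular networks;
#' `center_intermediate` / `intermediate_leaf` for hierarchical ones) and,
#' when `terciles = TRUE`, masks of existing connections grouped in terciles
#' of the true weight.
#'
#' @param net an `mvar_network`.
#' @param terciles add weight-tercile classes of existing connections.
#' @return named list of boolean `N x N` masks.
#' @export
connection_classes <- function(net, terciles = FALSE) {
  m <- net$mask
  N <- net$N
  diag_mask <- diag(N) == 1
  both <- m & t(m)
  classes <- list(self = m & diag_mask,
                  unidirectional = m & !both & !diag_mask,
                  reciprocal = both & !diag_mask)
  if (net$topology == "modular" && !is.null(net$node_labels)) {
    hub <- net$node_labels == "hub"
    hub_edge <- outer(hub, hub, "|")
    classes$intra_group <- m & !diag_mask & !hub_edge
    classes$hub <- m & !diag_mask & hub_edge
  }
  if (net$topology == "hierarchical" && !is.null(net$node_labels)) {
    lab <- net$node_labels
    classes$center_intermediate <-
      m & outer(lab == "intermediate", lab == "center")
    classes$intermediate_leaf <-
      m & outer(lab == "leaf", lab == "intermediate")
  }
  if (terciles) {
    w <- abs(net$weights[m])
    br <- quantile(w, c(1, 2) / 3, names = FALSE)
    for (k in 1:3) {
      lo <- if (k == 1) -Inf else br[k - 1]
      hi <- if (k == 3) Inf else br[k]
      classes[[paste0("weight_tercile_", k)]] <-
        m & abs(net$weights) > lo & abs(net$weights) <= hi
    }
  }
  classes
}

#' False-alarm and miss rates of a detection report
#'
#' `false_alarm` is the fraction of truly-absent connections declared
#' significant; `miss` the fraction of truly-present connections not
#' detected.  Self-connections are excluded unless `include_self = TRUE`
#' (they are evaluated separately through `classes`).  Classes with no
#' member yield `NA` rates, never 0.
#'
#' @param report an [`mvar_detect`][local_test] report, or a boolean
#'   decision matrix.
#' @param truth ground-truth `mvar_network` (or boolean mask).
#' @param classes optional named list of boolean masks (see
#'   [connection_classes()]); per-class miss rates are reported for classes
#'   of existing connections.
#' @param include_self evaluate diagonal entries in the overall rates.
#' @param lag ground-truth matrix to score against for order-2 networks.
#' @return an object of class `mvar_rates`: list with `false_alarm`, `miss`,
#'   `n_true`, `n_absent`, and `by_class` (per-class miss rates).
#' @export
detection_rates <- function(report, truth, classes = NULL,
                            include_self = FALSE, lag = 1) {
  dec <- if (inherits(report, "mvar_detect")) report$decisions else report
  if (inherits(truth, "mvar_network")) {
    mask <- if (lag == 1) truth$mask else truth$mask2
  } else mask <- truth
  stopifnot(all(dim(dec) == dim(mask)))
  keep <- !is.na(dec)
  if (!include_self) keep <- keep & (row(dec) != col(dec))
  n_true <- sum(mask & keep)
  n_absent <- sum(!mask & keep)
  fa <- if (n_absent) sum(dec & !mask & keep) / n_absent else NA_real_
  miss <- if (n_true) sum(!dec & mask & keep) / n_true else NA_real_
  by_class <- NULL
  if (!is.null(classes)) {
    by_class <- vapply(classes, function(cl) {
      n <- sum(cl & !is.na(dec))
      if (!n) return(NA_real_)
      sum(!dec & cl, na.rm = TRUE) / n
    }, 0)
  }
  structure(list(false_alarm = fa, miss = miss, n_true = n_true,
                 n_absent = n_absent, by_class = by_class),
            class = "mvar_rates")
}

#' @export
print.mvar_rates <- function(x, ...) {
  cat(sprintf("false-alarm rate %.4f (%d absent), miss rate %.4f (%d existing)\n",
              x$false_alarm, x$n_absent, x$miss, x$n_true))
  if (!is.null(x$by_class)) {
    cat("  miss rate by class:\n")
    for (nm in names(x$by_class))
      cat(sprintf("    %-22s %.4f\n", nm, x$by_class[[nm]]))
  }
  invisible(x)
}

#' Configuration for a benchmark sweep
#'
#' Collects the ranges from which each network configuration of a sweep is
#' drawn.  Defaults mirror the benchmark conditions: sizes 50-90, densities
#' 0.1-0.3, per-network uniform weight ranges, correlated inputs, T = 3000.
#'
#' @param n_networks number of network configurations.
#' @param topology network topology.
#' @param N_range inclusive integer range for the network size.
#' @param density_range range of the uniform density draw.
#' @param wmin_range range of the per-network draw of `wmin`.
#' @param wspan_range range of the per-network draw of `wmax - wmin`.
#' @param cross_corr input cross-correlation strength.
#' @param T_obs observed samples per network.
#' @param S surrogates per null ensemble.
#' @param alpha nominal false-alarm rate.
#' @param order MVAR order.
#' @param methods surrogate schemes to run.
#' @param tests `"local"`, `"global"` or both.
#' @param granger also run the parametric GRc baseline.
#' @param tails 1 or 2.
#' @param ... extra arguments stored and passed to
#'   [generate_connectivity()] (e.g. `inhib_ratio`).
#' @return a list of class `mvar_sweep_config`.
#' @export
sweep_config <- function(n_networks = 30, topology = "random",
                         N_range = c(50, 90), density_range = c(0.1, 0.3),
                         wmin_range = c(0.005, 0.02),
                         wspan_range = c(0.01, 0.04),
                         cross_corr = 0.1, T_obs = 3000, S = 400,
                         alpha = 0.02, order = 1, methods = "RP",
                         tests = "local", granger = FALSE, tails = 1, ...) {
  structure(list(n_networks = n_networks, topology = topology,
                 N_range = N_range, density_range = density_range,
                 wmin_range = wmin_range, wspan_range = wspan_range,
                 cross_corr = cross_corr, T_obs = T_obs, S = S,
                 alpha = alpha, order = order, methods = methods,
                 tests = tests, granger = granger, tails = tails,
                 extra = list(...)),
            class = "mvar_sweep_config")
}

# Draw one network configuration + panel for a sweep entry.
sweep_instance <- function(config, seed) {
  with_seed(seed, {
    N <- if (config$topology == "hierarchical") NA_integer_ else
      sample(config$N_range[1]:config$N_range[2], 1L)
    density <- runif(1, config$density_range[1], config$density_range[2])
    wmin <- runif(1, config$wmin_range[1], config$wmin_range[2])
    wmax <- wmin + runif(1, config$wspan_range[1], config$wspan_range[2])
    args <- c(list(topology = config$topology, density = density,
                   wmin = wmin, wmax = wmax, order = config$order),
              config$extra)
    if (!is.na(N)) args$N <- N
    net <- do.call(generate_connectivity, args)
    inp <- generate_input_covariance(net$N, config$cross_corr)
    x <- mvar_simulate(net, inp, T_obs = config$T_obs,
                       burn_in = 100)
    list(net = net, input = inp, x = x, N = net$N, density = density,
         wmin = wmin, wmax = wmax)
  })
}

#' Run a seeded benchmark sweep
#'
#' For each of `n_networks` seeded configurations: draw the network and
#' input covariance, simulate the panel, fit the MVAR model, run the
#' requested surrogate tests (and optionally the parametric GRc baseline),
#' and record false-alarm/miss rates and AUC.  Each network uses a seed
#' derived from the master seed, so results are reproducible and
#' independent of evaluation order; failures of individual networks are
#' recorded and the sweep continues.
#'
#' @param config an [sweep_config()] object.
#' @param seed master integer seed.
#' @param measures extra per-network measures: `"auc"` and/or `"spearman"`
#'   computed on the raw coefficient estimates.
#' @return long-form `data.frame` with one row per (network x method x
#'   test), columns `network`, `seed`, `N`, `density`, `T_obs`, `S`,
#'   `method`, `test`, `alpha`, `false_alarm`, `miss`, `auc`, `spearman`,
#'   `error`.
#' @export
run_sweep <- function(config, seed = 1, measures = character()) {
  rows <- list()
  for (k in seq_len(config$n_networks)) {
    net_seed <- derive_seed(seed, k)
    rec <- tryCatch({
      inst <- sweep_instance(config, net_seed)
      fit <- mvar(inst$x, order = config$order, keep_data = FALSE)
      a1 <- coef_matrices(fit)[[1L]]
      auc <- if ("auc" %in% measures)
        roc_auc(a1, inst$net)$auc else NA_real_
      spear <- if ("spearman" %in% measures)
        rank_match(a1, inst$net) else NA_real_
      out <- list()
      for (m in config$methods) {
        null <- build_null(inst$x, S = config$S, method = m,
                           estimator = if (config$order == 1) "order1"
                                       else "order2",
                           seed = derive_seed(net_seed, 1L, stream = 7L))
        for (tst in config$tests) {
          fun <- if (tst == "local") local_test else global_test
          lags <- seq_len(config$order)
          for (l in lags) {
            rep_l <- fun(fit, null, alpha = config$alpha,
                         tails = config$tails, lag = l)
            rates <- detection_rates(rep_l, inst$net, lag = l)
            out[[length(out) + 1L]] <-
              data.frame(network = k, seed = net_seed, N = inst$N,
                         density = inst$density, T_obs = config$T_obs,
                         S = config$S, method = m, test = tst, lag = l,
                         alpha = config$alpha,
                         false_alarm = rates$false_alarm, miss = rates$miss,
                         auc = auc, spearman = spear, error = NA_character_)
          }
        }
      }
      if (isTRUE(config$granger)) {
        grep_ <- granger_parametric_test(inst$x, kind = "GRc",
                                         alpha = config$alpha)
        rates <- detection_rates(grep_, inst$net)
        out[[length(out) + 1L]] <-
          data.frame(network = k, seed = net_seed, N = inst$N,
                     density = inst$density, T_obs = config$T_obs,
                     S = NA_integer_, method = "parametric", test = "grc",
                     lag = 1L, alpha = config$alpha,
                     false_alarm = rates$false_alarm, miss = rates$miss,
                     auc = auc, spearman = spear, error = NA_character_)
      }
      do.call(rbind, out)
    }, error = function(e)
      data.frame(network = k, seed = net_seed, N = NA_integer_,
                 density = NA_real_, T_obs = config$T_obs, S = config$S,
                 method = NA_character_, test = NA_character_, lag = NA,
                 alpha = config$alpha, false_alarm = NA_real_,
                 miss = NA_real_, auc = NA_real_, spearman = NA_real_,
                 error = conditionMessage(e)))
    rows[[k]] <- rec
  }
  do.call(rbind, rows)
}
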