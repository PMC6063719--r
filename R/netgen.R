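# Ground-truth network generators: random (Erdos-Renyi), modular
# (two groups bridged by hubs), hierarchical (center / intermediate / leaf)
# and excitatory-inhibitory connectivity, plus the mixed Gaussian input
# covariance used to drive the network.

#' Generate a ground-truth connectivity matrix
#'
#' Draws the directed connectivity of a noise-diffusion (MVAR) network.  The
#' entry `weights[i, j]` is the coupling strength of the connection j -> i, so
#' that network activity evolves as `x_t = A x_{t-1} + noise`.  Weights of
#' existing connections are drawn uniformly on `[wmin, wmax]`; source nodes
#' designated inhibitory (topology `"ei"`) have all their outgoing weights
#' negated.  Whenever the (companion) spectral radius of the drawn system
#' reaches 0.95 all weights are rescaled to bring it back to 0.95, which
#' guarantees stationarity; the factor applied is recorded in the result.
#'
#' @param topology one of `"random"`, `"modular"`, `"hierarchical"`, `"ei"`.
#' @param N number of nodes (ignored for `"hierarchical"`, where the layer
#'   draws determine the size).
#' @param density connection probability for each (directed) entry, diagonal
#'   included.  Fraction in `[0, 1]`.
#' @param wmin,wmax bounds of the uniform weight distribution.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @param order MVAR order: 1 (single matrix `A`) or 2 (matrices `A1`, `A2`;
#'   any given connection is placed in at most one of the two).
#' @param self_connections include diagonal entries at the same density
#'   (`"random"`/`"ei"` topologies).
#' @param inhib_ratio fraction of inhibitory source nodes for `"ei"`.
#' @param hub_frac fraction of hub nodes for `"modular"`; default drawn
#'   uniformly in `[0.05, 0.15]`.
#' @param n_intermediate,n_leaves branch counts for `"hierarchical"`;
#'   defaults drawn uniformly in `{5,...,10}`.
#' @param self_range optional length-2 range: give *every* node a
#'   self-connection with weight drawn uniformly in this range (overrides
#'   the density rule on the diagonal).  Strong positive self-coupling is
#'   the regime of slowly decaying autocovariances typical of smoothed
#'   population signals.
#' @param stability_limit spectral-radius ceiling triggering the rescale.
#' @return an object of class `mvar_network` with elements `weights`, `mask`
#'   (and `weights2`, `mask2` for order 2), `order`, `topology`,
#'   `node_labels`, `rescale`, `N`.
#' @seealso [generate_input_covariance()], [mvar_simulate()],
#'   [companion_spectral_radius()]
#' @examples
#' net <- generate_connectivity("random", N = 20, density = 0.2,
#'                              wmin = 0.01, wmax = 0.04, seed = 1)
#' sum(net$mask)
#' companion_spectral_radius(net)
#' @export
generate_connectivity <- function(topology = c("random", "modular",
                                               "hierarchical", "ei"),
                                  N = 70, density = 0.2,
                                  wmin = 0.005, wmax = 0.03,
                                  seed = NULL, order = 1,
                                  self_connections = TRUE,
                                  self_range = NULL,
                                  inhib_ratio = 0.2,
                                  hub_frac = NULL,
                                  n_intermediate = NULL, n_leaves = NULL,
                                  stability_limit = 0.95) {
  topology <- match.arg(topology)
  if (!is.numeric(N) || N < 2) stop("N must be >= 2", call. = FALSE)
  if (!is.numeric(density) || density < 0 || density > 1)
    stop("density must lie in [0, 1]", call. = FALSE)
  if (wmin > wmax) stop("wmin must not exceed wmax", call. = FALSE)
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2", call. = FALSE)

  with_seed(seed, {
    gen <- switch(topology,
      random = netgen_random(N, density, self_connections),
      ei = netgen_random(N, density, self_connections),
      modular = netgen_modular(N, density, hub_frac),
      hierarchical = netgen_hierarchical(n_intermediate, n_leaves))
    mask <- gen$mask
    N <- nrow(mask)
    labels <- gen$labels

    if (order == 2L) {
      # each drawn connection lives in exactly one of the two lag matrices
      pick1 <- matrix(runif(N * N) < 0.5, N, N)
      mask1 <- mask & pick1
      mask2 <- mask & !pick1
    } else {
      mask1 <- mask
      mask2 <- NULL
    }

    draw_weights <- function(m) {
      w <- matrix(0, N, N)
      w[m] <- runif(sum(m), wmin, wmax)
      w
    }
    w1 <- draw_weights(mask1)
    w2 <- if (order == 2L) draw_weights(mask2) else NULL
    if (!is.null(self_range)) {
      diag(w1) <- runif(N, self_range[1], self_range[2])
      mask1 <- w1 != 0
      if (!is.null(w2)) { diag(w2) <- 0; mask2 <- w2 != 0 }
    }

    inhibitory <- NULL
    if (topology == "ei") {
      if (inhib_ratio < 0 || inhib_ratio > 1)
        stop("inhib_ratio must lie in [0, 1]", call. = FALSE)
      n_inh <- round(inhib_ratio * N)
      inhibitory <- sample.int(N, n_inh)
      w1[, inhibitory] <- -w1[, inhibitory]
      if (!is.null(w2)) w2[, inhibitory] <- -w2[, inhibitory]
      labels <- rep("excitatory", N)
      labels[inhibitory] <- "inhibitory"
    }

    net <- structure(list(weights = w1, mask = mask1,
                          weights2 = w2, mask2 = mask2,
                          order = as.integer(order), topology = topology,
                          node_labels = labels, rescale = 1, N = N,
                          groups = gen$groups),
                     class = "mvar_network")
    stabilize_network(net, stability_limit)
  })
}

netgen_random <- function(N, density, self_connections) {
  mask <- matrix(runif(N * N) < density, N, N)
  if (!self_connections) diag(mask) <- FALSE
  list(mask = mask, labels = NULL, groups = NULL)
}

# Two equal groups of non-hub nodes bridged by hubs; hubs connect into and
# out of both groups, non-hub edges stay within their group.
netgen_modular <- function(N, density, hub_frac) {
  if (is.null(hub_frac)) hub_frac <- runif(1, 0.05, 0.15)
  n_hub <- max(1L, round(hub_frac * N))
  idx <- sample.int(N)
  hubs <- idx[seq_len(n_hub)]
  rest <- idx[-seq_len(n_hub)]
  g1 <- rest[seq_len(floor(length(rest) / 2))]
  g2 <- setdiff(rest, g1)
  mask <- matrix(FALSE, N, N)
  bern <- function(i, j) {
    m <- matrix(runif(length(i) * length(j)) < density, length(i), length(j))
    mask[i, j] <<- mask[i, j] | m
  }
  bern(g1, g1); bern(g2, g2)              # intra-group (incl. self)
  bern(g1, hubs); bern(g2, hubs)          # hub -> groups
  bern(hubs, g1); bern(hubs, g2)          # groups -> hubs
  bern(hubs, hubs)                        # hub <-> hub and hub self
  # every hub must project into both groups
  for (h in hubs) {
    if (!any(mask[g1, h])) mask[sample(g1, 1L), h] <- TRUE
    if (!any(mask[g2, h])) mask[sample(g2, 1L), h] <- TRUE
  }
  labels <- rep("group1", N)
  labels[g2] <- "group2"
  labels[hubs] <- "hub"
  list(mask = mask, labels = labels, groups = list(g1 = g1, g2 = g2, hubs = hubs))
}

# Three layers: one center node feeding intermediate nodes, each feeding its
# own leaves; every node keeps a self-connection.  Much sparser than the
# random topology by construction.
netgen_hierarchical <- function(n_intermediate, n_leaves) {
  B <- if (is.null(n_intermediate)) sample(5:10, 1L) else as.integer(n_intermediate)
  L <- if (is.null(n_leaves)) sample(5:10, 1L) else as.integer(n_leaves)
  N <- 1L + B + B * L
  mask <- matrix(FALSE, N, N)
  center <- 1L
  inter <- 1L + seq_len(B)
  mask[inter, center] <- TRUE
  leaf0 <- 1L + B
  for (b in seq_len(B)) {
    leaves_b <- leaf0 + (b - 1L) * L + seq_len(L)
    mask[leaves_b, inter[b]] <- TRUE
  }
  diag(mask) <- TRUE
  labels <- c("center", rep("intermediate", B), rep("leaf", B * L))
  list(mask = mask, labels = labels, groups = NULL)
}

# Rescale weights until the companion spectral radius drops below the limit.
stabilize_network <- function(net, limit = 0.95) {
  total <- 1
  for (k in 1:60) {
    rho <- companion_spectral_radius(net)
    if (rho < limit) break
    f <- limit / rho
    net$weights <- net$weights * f
    if (!is.null(net$weights2)) net$weights2 <- net$weights2 * f
    total <- total * f
    if (k == 60)
      stop("degenerate configuration: could not stabilize network", call. = FALSE)
  }
  net$rescale <- total
  net
}

#' Spectral radius of the (companion form of the) connectivity
#'
#' Largest eigenvalue modulus of `A` (order 1) or of the `2N x 2N` companion
#' matrix `[[A1, A2], [I, 0]]` (order 2).  Values below 1 guarantee a
#' stationary MVAR process.
#'
#' @param conn an `mvar_network`, a square matrix, or a list of two square
#'   matrices `(A1, A2)`.
#' @return the spectral radius (non-negative real scalar).
#' @export
companion_spectral_radius <- function(conn) {
  if (inherits(conn, "mvar_network")) {
    a1 <- conn$weights; a2 <- conn$weights2
  } else if (is.list(conn) && !is.data.frame(conn)) {
    a1 <- conn[[1]]; a2 <- if (length(conn) > 1L) conn[[2]] else NULL
  } else {
    a1 <- conn; a2 <- NULL
  }
  if (!is_square(a1) || (!is.null(a2) && !is_square(a2)))
    stop("connectivity must be square", call. = FALSE)
  if (!all(is.finite(a1)) || (!is.null(a2) && !all(is.finite(a2))))
    stop("connectivity must be finite", call. = FALSE)
  m <- if (is.null(a2)) a1 else companion_matrix(a1, a2)
  if (all(m == 0)) return(0)
  max(Mod(eigen(m, only.values = TRUE)$values))
}

companion_matrix <- function(a1, a2) {
  n <- nrow(a1)
  rbind(cbind(a1, a2), cbind(diag(n), matrix(0, n, n)))
}

#' Generate an input (innovation) covariance by mixing independent noise
#'
#' Builds `Sigma = M M'` with mixing matrix `M = D + c R`, where `D` is a
#' positive diagonal matrix and `R` a dense random matrix with
#' `N(0, 1/N)` entries.  `cross_corr_strength = 0` yields independent inputs
#' (diagonal `Sigma`); larger values give spatially correlated inputs, the
#' regime in which unconditional Granger tests lose control of false alarms.
#'
#' @param N number of nodes.
#' @param cross_corr_strength mixing strength `c >= 0`.
#' @param seed integer seed.
#' @param d_range range of the uniform draw for the diagonal of `D`.
#' @return an object of class `mvar_input` with elements `sigma` (the
#'   covariance) and `mixing` (`M`, used to draw exact `N(0, Sigma)` noise).
#' @examples
#' inp <- generate_input_covariance(5, cross_corr_strength = 0, seed = 1)
#' all(inp$sigma[upper.tri(inp$sigma)] == 0)
#' @export
generate_input_covariance <- function(N, cross_corr_strength = 0.1,
                                      seed = NULL, d_range = c(0.5, 1.5)) {
  if (!is.numeric(N) || N < 1) stop("N must be >= 1", call. = FALSE)
  if (!is.numeric(cross_corr_strength) || cross_corr_strength < 0)
    stop("cross_corr_strength must be >= 0", call. = FALSE)
  with_seed(seed, {
    d <- runif(N, d_range[1], d_range[2])
    m <- diag(d, N)
    if (cross_corr_strength > 0) {
      r <- matrix(rnorm(N * N, sd = 1 / sqrt(N)), N, N)
      m <- m + cross_corr_strength * r
    }
    structure(list(sigma = tcrossprod(m), mixing = m, N = as.integer(N)),
              class = "mvar_input")
  })
}

#' @export
print.mvar_network <- function(x, ...) {
  n_conn <- sum(x$mask) + if (is.null(x$mask2)) 0L else sum(x$mask2)
  cat(sprintf("MVAR network: %d nodes, topology '%s', order %d\n",
              x$N, x$topology, x$order))
  cat(sprintf("  connections: %d (density %.3f), spectral radius %.3f, rescale %.3g\n",
              n_conn, n_conn / (x$N^2 * x$order),
              companion_spectral_radius(x), x$rescale))
  invisible(x)
}

#' @export
print.mvar_input <- function(x, ...) {
  off <- x$sigma[upper.tri(x$sigma)]
  cat(sprintf("MVAR input covariance: %d nodes, mean var %.3f, mean |off-diag| %.3f\n",
              x$N, mean(diag(x$sigma)),
              if (length(off)) mean(abs(off)) else 0))
  invisible(x)
}
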