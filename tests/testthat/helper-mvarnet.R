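# Shared fixture builders for the test suite.  Everything is generated in
# code under fixed seeds; no stored data.

# A small random benchmark instance under the package's default study
# conditions (weak weights, mildly correlated inputs).
bench_instance <- function(seed, N = 30, density = 0.2, T_obs = 3000,
                           wmin = 0.01, wmax = 0.04, cross_corr = 0.1, ...) {
  net <- generate_connectivity("random", N = N, density = density,
                               wmin = wmin, wmax = wmax, seed = seed, ...)
  inp <- generate_input_covariance(N, cross_corr, seed = seed + 1000L)
  x <- mvar_simulate(net, inp, T_obs = T_obs, seed = seed + 2000L)
  list(net = net, input = inp, x = x)
}

# Equicorrelated (shared-source) input covariance used for the
# input-correlation sweeps.
equicorr_sigma <- function(N, rho) (1 - rho) * diag(N) + rho

off_diag <- function(m) m[row(m) != col(m)]
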