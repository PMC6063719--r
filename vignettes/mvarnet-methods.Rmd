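---
title: "Surrogate-based connectivity detection in MVAR networks: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surrogate-based connectivity detection in MVAR networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model and the detection problem

`mvarnet` infers directed connections in networks whose activity follows a
multivariate autoregressive (MVAR, "noise-diffusion") process

$$x^t = A\,x^{t-1} + \zeta^t, \qquad \zeta^t \sim \mathcal N(0, \Sigma)
\ \text{i.i.d.},$$

optionally of order 2, $x^t = A^1 x^{t-1} + A^2 x^{t-2} + \zeta^t$.  A
directed connection $j \to i$ exists when $A_{ij} \neq 0$.  The estimation
target is $A$ itself, obtained from the empirical lagged covariances

$$\hat Q^\tau_{ij} = \frac{1}{T - \tau_{\max} - 1}
\sum_{t=1}^{T-\tau_{\max}} (x_i^{t+\tau} - \bar x_i)(x_j^t - \bar x_j)$$

through the Yule–Walker relation $Q^1 = A Q^0$, giving the ordinary
least-squares estimate $\hat a = \hat Q^1 (\hat Q^0)^{-1}$ (`mvar()`,
`yule_walker()`).  For order 2 the block system
$(\hat a^1\ \hat a^2) = (\hat Q^1\ \hat Q^2)\,\tilde Q_0^{-1}$ with
$\tilde Q_0 = \bigl[\begin{smallmatrix}\hat Q^0 & \hat Q^1\\ (\hat
Q^1)^\top & \hat Q^0\end{smallmatrix}\bigr]$ is solved instead.

The inference question is which entries of $\hat a$ are significantly
different from zero.  The package's core contribution is a nonparametric
answer: build a null ensemble by re-estimating $\hat a$ on surrogate time
series whose cross-covariance structure has been destroyed, then compare
each observed coefficient against the null of *its own* matrix element
(the *local* test) or against the pooled null of all $S N^2$ elements (the
*global* test).

### Surrogate schemes

Four schemes are implemented in `make_surrogate()`, each applied to every
node's series independently: random permutation of time indices (RP),
random circular shift (CS), Fourier phase randomization (PR) and
replacement by Gaussian noise whose standard deviation is the per-node
standard deviation averaged over the network (STD).  RP and CS preserve the
marginal distribution; CS and PR additionally preserve the (circular)
autocovariance, which is why CS surrogates *cannot* test self-connections:
the null for a diagonal element is centred on the observed autoregressive
coefficient itself.  PR as written in the field's recipes does not
guarantee a real-valued inverse transform; we enforce realness by
conjugate-symmetric phase assignment (the alternative of taking the real
part of an unconstrained randomization is available via
`pr_real = "real-part"`; it halves the surrogate variance and makes the
test anti-conservative).

### Granger-causality baselines

The unconditional and conditional Granger log-ratios compare residual sums
of squares of nested lag-1 regressions (`granger_logratio()`,
`granger_matrix()`).  We define the score as
$\mathrm{GR} = \ln(\mathrm{RSS}_{\text{reduced}}/\mathrm{RSS}_{\text{full}})$
— the classic measure on the variance scale — while `residual_std()`
reports the residual *norm* $\sqrt{\sum_t (\epsilon^t)^2}$; the two differ
by a factor 2 in the log.  The variance-scale convention is the one under
which the single-restriction parametric F-test,
$$\exp(\mathrm{GR}) - 1 > \phi(\alpha, 1, d)/d, \qquad
d = T - 3 \ (\mathrm{GRu}), \quad d = T - N - 1 \ (\mathrm{GRc}),$$
attains its nominal level exactly under the null, which we verify by
simulation on white-noise networks.

## Exact level of the empirical-quantile test

The local test thresholds each connection at the type-1 (inverted ECDF)
empirical $(1-\alpha)$ quantile of its $S$ null values and declares strict
exceedances significant.  Under an exchangeable null the probability that
the observation exceeds the $\lceil S(1-\alpha)\rceil$-th order statistic
is

$$\alpha_S = \frac{S - \lceil S(1-\alpha)\rceil + 1}{S + 1},$$

e.g. $\alpha_S = 2.24\%$ at $S = 400,\ \alpha = 2\%$ and $2.05\%$ at
$S = 2000$.  The type-1 quantile was chosen because its thresholds are
always realized surrogate values and remain well defined at small $S$; the
price is this small, exactly quantifiable positive bias $\approx (1 -
\alpha)/S$, which vanishes as $S$ grows.  The calibration tests therefore
check the empirical false-alarm rate against $\alpha_S$, not against raw
$\alpha$ — a perfectly calibrated null would otherwise "fail" by
construction at finite $S$.  Reported p-values use the standard permutation
correction $p = (1 + \#\{\text{null} \geq \text{obs}\})/(S+1)$ and never
return 0.  In two-tailed mode the mass is split $\alpha/2$ per tail, which
is how negative (inhibitory) couplings are detected and signed.

One consequence worth knowing: at a fixed *desired* $\alpha$, small
ensembles ($S = 50$) run at a higher exact level ($3.9\%$ for
$\alpha = 2\%$), so they detect more connections — both false and true.
Comparisons across $S$ should therefore be read jointly with the realized
false-alarm rate; the local-vs-global comparison at fixed $S = 400$
(local misses fewer, especially among weak connections) is the robust
ordering.

## The synthetic study conditions

No external data is required: `generate_connectivity()`,
`generate_input_covariance()` and `mvar_simulate()` produce every benchmark
input.  Where the literature on this benchmark family leaves parameters
unstated, the package fixes them once as defaults and the benchmarks use
them unchanged:

* **Weight draws.**  Each random network draws its own uniform weight range
  with $w_{\min} \sim U(0.005, 0.02)$ and
  $w_{\max} - w_{\min} \sim U(0.01, 0.04)$ — effective couplings of order
  $10^{-2}$, which put per-node incoming weight sums at $O(0.1\!-\!1)$ and
  detection at $T = 3000$ in the informative mid-range (misses neither 0
  nor 1).  Stability is enforced by rescaling all weights by $0.95/\rho$
  whenever the companion spectral radius $\rho$ reaches 0.95; the factor is
  recorded in the `rescale` field.
* **Input covariance.**  $\Sigma = MM^\top$ with $M = D + cR$, $D =
  \mathrm{diag}\,U(0.5, 1.5)$, $R_{ij} \sim \mathcal N(0, 1/N)$ and default
  mixing strength $c = 0.1$: inputs are correlated but weakly (typical
  pairwise input correlations of a few percent).  This is the regime in
  which the local RP test's false-alarm control is near its exact level;
  stronger dense mixing degrades the control because the permutation null
  cannot represent input-driven cross-correlations (see Limitations).
* **Hierarchical topology.**  One centre, $B \sim U\{5,\dots,10\}$
  intermediates, each with $L \sim U\{5,\dots,10\}$ leaves, self-connections
  on all nodes.  The benchmark preset for this family draws strong tree
  weights ($w_{\min} \sim U(0.06, 0.1)$, span $U(0.02, 0.06)$): the sparse
  feed-forward tree is far from the stability boundary (its companion
  spectral radius is just the largest self-weight), representing the
  strongly detectable regime in which every connection class is recovered
  almost perfectly.
* **Modular topology.**  Two equal groups plus a hub fraction drawn in
  $[5\%, 15\%]$; intra-group and hub edges appear with the requested
  density, non-hub inter-group edges never do, and every hub is guaranteed
  at least one projection into each group.
* **Excitatory–inhibitory networks.**  A fraction `inhib_ratio` of source
  nodes has all outgoing weights negated; two-tailed testing recovers both
  the existence and the sign.
* **Input-correlation sweeps.**  The sweep that demonstrates the failure of
  the unconditional Granger F-test uses *shared-source* (equicorrelated)
  inputs, $\Sigma = (1-\rho) I + \rho \mathbf{1}\mathbf{1}^\top$, together
  with strong self-coupling (diagonal weights $U(0.3, 0.5)$ via
  `self_range`).  Both ingredients matter: a common noise source creates
  the pairwise input correlations, and the target's self-dynamics convert
  them into spurious lag-1 predictability that the bivariate GRu regression
  cannot distinguish from coupling, while the full-network GRc regression
  and the surrogate tests remain controlled.

### The electrode-signal fixture

`synth_electrode_fixture()` is a fully synthetic stand-in for
multielectrode array recordings (trials × channels × 1-kHz samples).  Each
channel's log-envelope follows an MVAR(1) with self-coefficient 0.7 per
4-ms step (exponentially decaying autocovariance) plus any planted directed
couplings; the envelope is the positive multiplicative process
$e = \text{baseline} \cdot \exp(u - \sigma_u^2/2)$, scaled by `onset_gain`
after stimulus onset; the raw trace is white noise amplitude-modulated by
the envelope.  The default modulation depth (≈50% relative s.d.) keeps the
envelope autocovariance visible above the rectification noise of the
carrier — with only 4 samples per bin, the rectified-carrier noise is
substantial, which is also true of real multiunit activity envelopes.

What the fixture does *not* emulate: spike waveforms, oscillatory
(band-limited) population rhythms, cross-frequency structure,
non-stationary adaptation within the post-stimulus window, or recording
artefacts.  Passing the pipeline tests therefore shows that the
preprocessing chain and the trial-averaged estimator recover envelope-level
linear couplings of the planted kind — not that every feature of real
recordings is handled.

`preprocess_muae()` implements the standard multiunit-activity-envelope
chain: decimation to 1 kHz (integer factors, with an anti-alias low-pass),
third-order Butterworth high-pass at 0.8 of Nyquist (400 Hz), zero-phase
filtering, rectification, and non-overlapping 4-ms bin means — exactly 250
bins covering the second around stimulus onset (400 ms before to 600 ms
after), with fixed 50-bin (200 ms) pre/post analysis windows.  The
"smoothing" step is deliberately the rectify-then-bin variant; a
moving-average-then-decimate chain would be a different dialect of the same
operation.  Channels whose mean envelope exceeds 5× the channel median can
be screened out (`muae_screen_channels()`), mirroring common practice of
discarding electrodes with outlying activity.

Multi-trial estimation centres each trial individually, averages the
lagged covariances across trials and inverts once; surrogate ensembles
shuffle every trial independently with the same scheme.

## Numerical choices

* Lagged covariances use a common summation window $t = 1..T-\tau_{\max}$
  for all lags and the divisor $T - \tau_{\max} - 1$; both are exposed as
  dialect switches (`common_window`, `divisor`) since other conventions
  exist.
* `yule_walker()` refuses inversion when the condition number of the lag-0
  block exceeds $10^{12}$ and names the lowest-variance nodes — silent
  noise amplification would otherwise corrupt every coefficient.
* The stationary covariance (`theoretical_covariance()`) is computed by
  fixed-point iteration of $Q^0 \leftarrow A Q^0 A^\top + \Sigma$
  (geometric convergence for $\rho(A) < 1$, tolerance $10^{-13}$), avoiding
  the $N^2 \times N^2$ Kronecker system.
* Granger scores clamp $\mathrm{RSS}_{\text{full}} \le
  \mathrm{RSS}_{\text{reduced}}$ and floor both by $10^{-12}$ before the
  log, absorbing rounding ties in nested least squares.
* Per-surrogate seeds derive from the master seed by a counter-based
  scheme, so ensembles are reproducible and independent of evaluation
  order; a surrogate whose covariance happens to be singular is re-drawn
  (at most 5 times) under a fresh substream.
* Initial simulation state is drawn from $\mathcal N(0, \Sigma)$ and 100
  burn-in steps are discarded; with spectral radii ≤ 0.95 the remaining
  transient is negligible at the benchmark horizons.

## Problem sizes

The test suite runs reduced-replicate versions of the benchmarks (8–10
networks per condition, and 30 for the AUC comparison); the acceptance
script (`scripts/acceptance.R`) runs the full desk-scale protocol — 30
random networks for the miss-rate comparison, 30 for the surrogate-method
comparison, 20 hierarchical networks — with every quantity recomputed from
scratch under the given seed.  These sizes are the package's chosen
trade-off between replicate noise and turnaround; the documented
generator defaults are used unchanged throughout.

## Known limitations

* The random-permutation null assumes exchangeability of each node's
  samples and cannot represent cross-node correlations injected by the
  inputs.  With strong dense input mixing the local test's false-alarm rate
  rises above its exact level (about 7% at mixing strength $c = 0.5$ in
  our scans); under the default weak mixing, and under shared-source
  correlations even of substantial strength, control is maintained.  The
  conditional Granger F-test is the more robust choice when inputs are
  known to be strongly and densely correlated — at the price of a markedly
  higher miss rate.
* Comparisons of the local test across different $S$ at a fixed desired
  $\alpha$ are confounded by the $S$-dependent exact level (see above).
* No multiple-comparison correction is applied anywhere; per-connection
  p-values are the intended output and any FDR or cluster-level procedure
  is downstream of this package's scope.
* Estimators are plain OLS/Yule–Walker: orders above 2, regularized or
  state-space estimators, and frequency-domain (spectral) causality are out
  of scope.
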