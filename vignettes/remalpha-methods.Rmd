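---
title: "Unsupervised REM detection from iEEG alpha rhythm: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised REM detection from iEEG alpha rhythm: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients implanted with depth electrodes for epilepsy monitoring are
recorded for one to two weeks, but the intracranial EEG (iEEG) montage
usually lacks the EOG and EMG channels that conventional sleep staging
needs most for one distinction: rapid-eye-movement (REM) sleep versus
wakefulness, whose cortical EEG is otherwise similar. One robust
electrophysiological difference survives in iEEG alone: the alpha rhythm
(8--12 Hz) is prominent in relaxed wakefulness and strongly attenuated in
REM sleep. `remalpha` turns that contrast into an unsupervised per-night
classifier: summarise every 30 s epoch by complex multitaper statistics of
the 10 Hz band across all contacts, cluster the epochs, and call the
cluster with the lowest alpha power REM.

## Pipeline

**Preprocessing.** Recordings (EDF/EDF+, concatenated in start-time order
when a night is stored in blocks) are notch-filtered at the power-line
fundamental and all harmonics below Nyquist with a single multiband
linear-phase FIR kernel applied by FFT convolution with the group delay
removed, so the net filter is zero-phase. The kernel length scales with
the sample rate (`4 * fs / half_width` taps) giving a fixed transition
width in Hz; measured attenuation inside each 2 Hz-wide notch is below
-55 dB while the gain at 10 Hz differs from unity by well under 0.1 dB.
Since the analysis happens at 10 Hz, the exact notch dialect is
non-critical; this one was chosen because its zero-phase property is
directly assertable (filtering commutes with time reversal). When the
line frequency is at or above Nyquist -- possible for decimated test
material -- the pipeline warns and skips the notch rather than failing.
Data are then cut into non-overlapping 30 s epochs (the sleep-scoring
unit; a trailing partial epoch is dropped), each epoch into five 6 s
subsections, and each subsection is centered by subtracting its own
sample mean. Centering is per subsection because the spectral transform
is applied per subsection.

**Multitaper features.** For each subsection and contact, the
discrete prolate spheroidal sequences (DPSS, Slepian tapers) of length
`N` (6 s of samples) and half-bandwidth `W = 2` Hz are applied and the
tapered discrete-time Fourier transform is evaluated directly at
`f = 10` Hz, giving one complex *eigencoefficient* per taper. The
dimensionless time-bandwidth product is `N * W * delta = 12` for any
sample rate (6 s times 2 Hz), so the taper basis is essentially the same
whether the hardware ran at 2 kHz or the simulation at 200 Hz. Tapers are
computed from the commuting symmetric tridiagonal matrix (bisection plus
inverse iteration in compiled code, so only the top ~30 eigenpairs are
ever touched), and each taper's band concentration
$\lambda_k = \nu^\top S \nu$ is evaluated exactly against the
band-limiting sinc kernel by FFT. Tapers with $\lambda_k$ above 0.98 are
kept.

A note on the taper count: at the flagship parameters
($N = 12000$, time-bandwidth 12) the exact concentrations are
$\lambda_{20} = 0.99673$ and $\lambda_{21} = 0.97972$, so the strict
0.98 threshold keeps **21** tapers, while the common rule of thumb
$K = 2NW - 2$ gives 22 -- the two conventions straddle a concentration
that misses the threshold by $3\times10^{-4}$. The package implements the
threshold rule as the generative definition (it is what the concentration
eigenvalues mean), and exposes `n_tapers` to pin the count explicitly for
reproducing analyses that used the $2NW-2$ convention (with `n_tapers =
22`, five subsections give the feature width $N_r = 5K = 110$).

The per-epoch feature is the complex matrix $Y \in \mathbb{C}^{N_c
\times N_r}$ (contacts by subsection-taper pairs, column $q = K(m-1) +
k$). The per-epoch, per-contact alpha power estimate is the unweighted
multitaper mean $\check S = \sum_{m,k} |Y_{m,k}|^2 / (5K)$; no adaptive
(Thomson-weighted) combination is used, keeping the estimator exactly the
plain eigencoefficient average the classifier models.

**Likelihood K-means.** Epochs are clustered by a modified K-means whose
distance is a cluster-conditional Gaussian log-density: the $N_r$ real
and $N_r$ imaginary columns of $Y$ are modelled as independent
$N_c$-variate normals with cluster-specific complex mean $\check\mu^{(j)}$
(the average of all member columns) and separate real/imaginary
covariances $\check R_r^{(j)}, \check R_i^{(j)}$ (sample covariances with
divisor $N_r Q_j - 1$). This form is motivated by the asymptotic
Gaussianity of tapered Fourier transforms of stationary processes and the
near-independence of eigencoefficients across orthogonal tapers. Cross
real--imaginary covariance is deliberately not modelled.

Two density conventions are provided. The default (`standard`) is the
honest joint log-density,
$$\ln P = -N_r N_c \ln 2\pi - \tfrac{N_r}{2}\big(\ln|\check R_r| +
\ln|\check R_i|\big) - \tfrac12\,\mathrm{tr}\,\big[(Y_r-\check\mu_r
1^\top)^\top \check R_r^{-1} (Y_r-\check\mu_r 1^\top)\big] -
\tfrac12\,\mathrm{tr}[\cdot]_i,$$
with the constant and determinant terms carrying the $N_r$ factor that
consistency with the $N_r$-column trace terms requires. The
`as_printed` variant uses $-N_c \ln 2\pi - \tfrac{N_c}{2}(\ln|\check
R_r| + \ln|\check R_i|)$ instead; the two differ only by terms constant
across clusters, so cluster assignments are identical and only the
model-selection criterion built on the values changes.

Numerical choices: covariances get a ridge of $10^{-8}\,\mathrm{tr}(R)/N_c$
on the diagonal before the Cholesky factorisation, enough to survive
near-singular clusters without measurably moving well-conditioned results
(the effect on the log-density is below $10^{-7}$ relative); a covariance
that is singular even then raises a labelled error. Assignment ties break
to the lowest cluster index. Convergence is a full pass with zero label
changes; the iteration cap is 500 (observed convergence is typically
under 10 passes on separable data).

**Restarts.** Labels are initialised uniformly at random. That
initialisation is fragile in a specific way: every cluster starts with
parameters near the grand mean, so an early reassignment pass can empty a
cluster even when the requested count is well supported, and single runs
can settle into local optima. `fit_kmeans` therefore draws `n_restarts =
10` independent initialisations and keeps the converged fit with the
highest total assigned log-density -- the same device as `nstart` in
`stats::kmeans`. Measured on planted three-cluster data at 8 standard
deviations of separation (12 contacts, $N_r = 110$), a single restart
emptied a cluster at the *true* cluster count in 7 of 20 seeded runs and
converged to a local optimum in 2 more, while best-of-10 recovered the
planted partition in 20 of 20. A cluster count the data cannot sustain
empties a cluster under every initialisation and still fails, so the
sweep's stopping rule (below) survives the restarts.

**Cluster-count selection.** Cluster counts 2..14 are fitted in turn,
stopping early if a count fails with an empty cluster, and the count
minimising the approximate AIC
$$\widetilde{AIC}(N_{cluster}) = N_{cluster}(N_c^2 + N_c) - 2\sum \ln P$$
is selected. The deviance sum has two conventions and the source
formulation is ambiguous between them. Summing $\ln P(Y^{(e)}|C=j)$ over
*all* cluster--epoch pairs makes the criterion monotone increasing in the
cluster count whenever clusters are separated at all (cross-cluster
log-densities are large negative numbers, and more clusters simply add
more of them); on planted three-cluster data it collapses to $k = 2$ in
20 of 20 runs. The default is therefore the assigned-cluster sum -- each
epoch's log-density under its own cluster, i.e. the maximised
log-likelihood, which is the standard AIC deviance; the all-pairs variant
remains available (`sum_over = "all"`). Users should know the criterion
is weak in a second way that no variant fixes: the penalty $N_c^2 + N_c$
counts only the covariance parameters and omits the complex mean's
$2N_c$, so it sits *below* the per-cluster parameter count
$N_c^2 + 3N_c$, and with hard assignments the criterion tends to
overselect (measured $\Delta\widetilde{AIC}(3\!\to\!4) \approx -2N_c$ on
well-separated planted data). In practice the selected count on clean
multi-state nights comes out a few above the planted state count; this
over-splitting is benign for REM detection -- it fragments the non-REM
stages while the REM epochs stay in the lowest-alpha cluster -- but the
chosen $k$ should not be read as an estimate of the number of sleep
stages.

**REM identification.** Per cluster and contact, alpha power is averaged
over member epochs; per contact, clusters are ranked (rank 1 = lowest
power; ties get average ranks, so fractional ranks are possible); each
cluster's *spectral rank* is the median of its ranks across contacts; the
cluster minimising the spectral rank is REM. If the minimum is attained
by more than one cluster the decision is flagged unreliable (the
lowest-index minimiser is still reported so downstream tooling can
proceed while excluding flagged nights). Two figures of merit accompany
the call: FOM1, the minimum over contacts of the alpha-power gap between
the two lowest-power clusters (small values flag a fragile separation);
and FOM2, the fraction of contacts where the REM cluster is not the
lowest-power cluster.

**Evaluation.** Against a manually scored hypnogram the package reports
the precision of the REM label (the fraction of called epochs that are
truly REM -- the headline "specificity" figure of this detector family),
the recall, and the correctly identified REM minutes (0.5 per epoch).
Two procedures probe robustness: stratified hold-out splits (REM, Wake
and, by default, every other stage split independently; the full
unsupervised pipeline re-run on each part; 50 repetitions), and a
matched-power baseline -- a plain alpha-power threshold test whose
threshold is set so it calls exactly as many REM epochs as the
clustering classifier, isolating label quality from statistical power.
Epochs labelled `U` (unscored) are excluded from metrics but participate
in clustering.

## The synthetic-data generator

Patient recordings cannot ship with the package, so every stage is
validated on synthetic nights with known hypnograms. The generator
emulates exactly the phenomenon the classifier exploits and little else:

* a narrowband alpha process (white noise band-passed to 8--12 Hz), one
  night-wide component shared across contacts mixed with per-contact
  independent components (`contact_coupling`, default 0.5, sets the
  shared variance fraction);
* a per-epoch amplitude that depends on the true stage, by default
  `W = 4, N2 = 2, N3 = 2, REM = 1` microvolts -- the 4:1 Wake-to-REM
  alpha contrast with NREM intermediate, so REM has the *lowest* alpha
  power as the identification rule assumes;
* first-order autoregressive background noise per contact (pole 0.95,
  sd 5 microvolts), a crude stand-in for the 1/f-like iEEG background --
  the slope is not a fidelity claim;
* a default 100-epoch (50 min) stage sequence with wake at both ends and
  two REM periods mid-night; metrics never depend on the ordering.

The default sample rate is 200 Hz rather than a clinical 2 kHz: the
10 Hz analysis band sits far below either Nyquist frequency, the taper
basis depends on rate only through the fixed time-bandwidth product 12,
and the lower rate keeps simulated validation runs light. The generator
accepts 2000 Hz unchanged. What the generator does **not** contain --
spindles, slow waves, eye-movement or muscle artifacts, interictal
discharges, non-stationary background -- bounds what passing tests show:
they demonstrate the pipeline recovers a planted alpha contrast through
the full signal path, not that it survives every artifact of clinical
recordings.

A second, feature-space mode draws the complex feature-matrix columns
directly from per-stage Gaussians. That is precisely the sampling model
the clustering stage assumes, which makes it the right fixture for
oracle tests of the cluster module (planted partitions at a chosen
separation in noise-sd units, via `planted_feature_config`, or with a
planted per-contact power ordering via `planted_alpha_config`).

## Validation scale

The shipped tests and the acceptance script run the pipeline at sizes a
laptop handles in minutes, chosen to exercise the same geometry as the
study conditions rather than the same arithmetic volume: planted
feature-space problems use 12 contacts and $N_r = 110$ (the real feature
dimensions) with 60 epochs; end-to-end signal runs use the generator
defaults (12 contacts, 200 Hz, 100 epochs) across 20 seeds; hold-out
consistency uses 50 stratified splits. The one full-rate computation kept
as-is is the taper basis at $N = 12000$ (6 s at 2 kHz), which takes
under a second.

## Known limitations

* The approximate-AIC sweep overselects the cluster count on clean data
  (see above); treat the chosen $k$ as operational, not inferential.
* The generator's defaults make Wake/REM nearly separable; real nights
  with drowsy wake, artifacts or atypical alpha topography will be
  harder, as the source method's own worst subjects show.
* One night at 2 kHz with many contacts is held in memory (~0.5 GB per
  12-contact 8 h night as doubles, twice that transiently during
  epoching); block-wise processing is not implemented.
* The notch assumes a 60 Hz mains fundamental by default; set
  `notch_base = 50` in `pipeline_config()` for 50 Hz grids.
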