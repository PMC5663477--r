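---
title: "Multidimensional models of cortical circuit activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multidimensional models of cortical circuit activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popcircuit)
```

popcircuit implements a chain of models for asking how low-level components
of a cortical microcircuit shape its population activity, and how much of
that activity structure a one-dimensional "excitation/inhibition balance"
description can capture. The chain has four levels, each exposed as ordinary
R functions with tibble outputs:

1. a biophysically detailed spiking network model of the layer 2/3 barrel
   cortex microcircuit, with a single-parameter perturbation sweep;
2. a two-parameter logistic input-output model per neuron (slope,
   threshold), with exact maps from those parameters to mean firing
   probability and pairwise correlation under a shared Gaussian drive;
3. a five-parameter population version (a 2D Gaussian over slope and
   threshold across neurons) fitted to three activity statistics by
   accept/reject stochastic descent;
4. an entropy estimator for large populations (the population tracking
   model) with a double-exponential standardization to 100-neuron
   populations.

Around these sit a calcium-imaging binarization pipeline, bootstrap group
statistics, and a synthetic-data generator that stands in for in vivo
recordings, so every stage can be validated closed-loop against known ground
truth.

## The spiking circuit model

The circuit is four reciprocally connected populations of conductance-based
leaky integrate-and-fire neurons — 1700 excitatory (E), 70 parvalbumin (PV),
115 5HT3aR, and 45 somatostatin (SOM) cells — driven by 1500 layer-4
excitatory spike sources. Membrane voltage follows

$$\frac{dV}{dt} = \frac{g_e (E_e - V) + g_i (E_i - V) - (V - V_{rest})}{\tau_m},$$

with synaptic conductances stored in units of each target's leak conductance
(so input resistance never appears explicitly in the integration) and
decaying exponentially between presynaptic events. Each presynaptic spike
gates every outgoing synapse through an independent Bernoulli release draw
(release probability 0.25 throughout). Connectivity is Bernoulli per
connection class; per-synapse PSP amplitudes are log-normal, parameterized
by the published mean/median pairs (location $\log m_{ed}$, ln-scale
variance $2 \log(\text{mean}/\text{median})$) and capped at 8 mV. Because
the literature reports synaptic strength as PSP amplitudes, peak
conductances are set analytically so the linearized single-synapse response
(bi-exponential in the membrane and synaptic time constants, driving force
at rest for EPSPs and at −55 mV for IPSPs) peaks at the requested amplitude;
the degenerate equal-time-constant case uses the alpha-function limit. The
conversion is verified against numerical ODE integration in the test suite
(agreement well within 1%).

A stimulation trial is 50 ms of forward-Euler integration at 0.01 ms: a
chosen fraction `f` of L4 sources each fires one spike at a time drawn from
a Gaussian with 2 ms s.d. A neuron is scored as responding if it crosses
threshold at least once; extra spikes are disregarded, and the reset
potential is the resting potential (a conventional choice; the E-cell
refractory period of 55.5 ms exceeds the trial anyway). A neuron's ON
probability at level `f` averages 10 random ON subsets × 10 release
repeats (spike times are drawn once per subset, so the repeats isolate
release noise). Integration is implemented in compiled code; everything
else is R.

Numerical notes: with all synapses removed each neuron relaxes to rest with
its membrane time constant (checked against the closed form to Euler
accuracy), and responses at `f = 0` are identically zero because the model
has no spontaneous drive.

### Stimulus levels

The package's default protocol spans `f = seq(0, 1, by = 0.1)`. With the
default parameter table the excitatory population's response transition lies
at high L4 fractions (roughly 0.7–1.0): a simple mean-drive estimate shows
why — at `f = 0.3`, an E cell receives on average $0.3 \times 1500 \times
0.15 \times 0.25 \approx 17$ released PSPs of ~0.8 mV against a 30 mV gap to
threshold, so the transition cannot sit at low fractions. The grid was
chosen to bracket the observed transition of the default model.

### Downscaled networks

`circuit_params(scale = s)` shrinks all five populations proportionally for
cheaper simulations. Convergence (synapses per neuron) shrinks with the
populations, so an uncompensated downscaled network receives `s`-fold less
synaptic drive and is silent at every feasible stimulus — a 4-fold reduction
leaves E cells below threshold even with every L4 source active. The default
`scale_compensation = "weights"` therefore multiplies all PSP amplitudes by
`1/s`, preserving the mean aggregate drive per neuron (the standard
downscaling compensation for network models); amplitude variance grows and
the 8 mV cap binds more often, so downscaled results are qualitative, not
quantitative, stand-ins for the full model. `"none"` disables compensation
for studying the uncompensated scaling itself.

### The perturbation sweep

`perturb_params()` changes one of 76 parameters by ±20%: counts,
probabilities, resistances, time constants and PSP amplitudes scale
multiplicatively (the 14 mean/median amplitude pairs move in tandem;
perturbed probabilities clamp at 1 with a warning), while voltages move
relative to a natural reference — resting potential toward spike threshold
by 20% of the gap, spike threshold away from rest likewise, excitatory
reversal potentials scaling their distance from rest, inhibitory reversal
potentials their distance from spike threshold. Refractory periods (scored
responses are any-spike) and the six absent connection classes are excluded.
`sweep_sensitivity()` reruns the full protocol per perturbation with the
same build and stimulus seeds as the default network, fits each neuron's
logistic response, and reports the shift in the excitatory population's mean
(slope, threshold); degenerate fits are excluded and counted. With common
seeds a null (0%) perturbation reproduces the default run exactly, which the
tests use as the negative control.

## The logistic response model

Each neuron's probability of responding is
$q(f) = 1/(1 + \exp(-\beta (f - f_{1/2})))$. For interpretability the
midpoint is converted to a *threshold*: the input at which the response
probability equals `q_thresh` (0.01 throughout),
$f_{thresh} = f_{1/2} + \log(q_{thresh}/(1-q_{thresh}))/\beta$. Per-neuron
fitting is binomial maximum likelihood with a logit link (`stats::glm`);
all-0/all-1 responses and perfect separation are flagged rather than fitted
(the slope is capped at $10^4$ under separation so the threshold conversion
stays finite), and non-monotone (negative-slope) fits are flagged
degenerate.

Fits from circuit simulations live on the L4-fraction scale; the analytic
model below places the same functional form on a standard-normal drive.
`logistic_fit` objects carry a `domain` tag so the two scales are not
silently mixed — no conversion between them is provided or implied.

For the analytic model the drive is $f \sim N(0,1)$ shared by all neurons,
and each neuron spikes conditionally independently given $q(f)$. Then

$$\mu = \int q(f)\,\phi(f)\,df, \qquad
  \mathrm{cov} = \int q_a(f) q_b(f) \phi(f) df - \mu_a \mu_b,$$

and the pairwise correlation normalizes by the Bernoulli variances
$\mu(1-\mu)$. Scalar evaluations (`mean_rate()`, `pair_correlation()`,
`rate_contour()`, `local_sensitivity()`) use adaptive quadrature split at
the sigmoid midpoint, accurate to ~1e−10 even for near-step slopes, and are
cross-checked in the tests against $10^7$-draw Monte Carlo (3 standard
errors) and against closed forms in the step ($\beta \to \infty$, where
$\mu = \Phi(-f_{1/2})$ and the correlation is 1) and flat ($\beta = 0$,
correlation 0) limits. Saturated neurons have zero variance; their undefined
correlation is reported as 0 and flagged via `corr_defined()`.

`rate_contour()` solves for the threshold achieving a target mean rate at
each slope (bracketed bisection, ~1e−10 in rate). Along the rate-0.1 contour
the homogeneous-pair correlation runs from below 0.001 at slope 0.1 up to
0.96 at slope 50 — the quantitative core of the argument that fixing firing
rates leaves correlations essentially free. `local_sensitivity()` takes
central finite differences (relative step $10^{-3}$, one-sided with a flag
if a downward slope step would cross zero); halving the step changes
estimates at second order, and the threshold derivative is verified against
the analytic integrand $-\beta \int q(1-q)\phi$. In the sub-saturation
regime ($\mu < 0.5$) where the recorded populations live, increasing slope
or decreasing threshold raises both rate and correlation; at rates above
~0.5 the correlation's threshold-derivative changes sign, which is why the
tests pin the claim to the data regime rather than "everywhere".

## The population model and its fit

Cell-to-cell heterogeneity is modeled by drawing each neuron's (threshold,
slope) once from a 2D Gaussian with five parameters: two means, two standard
deviations, and a correlation. Slopes are truncated at zero during both
integration and sampling so responses stay monotone (the truncation is
immaterial for physiological parameter mass). `predict_stats()` maps the
five parameters to three observables — mean rate, s.d. of per-neuron rates,
and mean pairwise correlation over independently drawn parameter pairs
sharing the drive — by tensor Gauss–Hermite quadrature (12 nodes per
parameter dimension, 101 drive nodes by default; deterministic given the
order). The pair expectation reduces to a quadratic form in the per-node
response profiles, so a full evaluation costs well under 10 ms and the
predictions match the empirical statistics of large sampled rasters within
Monte-Carlo error.

`fit_population()` implements accept/reject stochastic descent on the summed
squared error of the three statistics: perturb all five parameters with
zero-mean Gaussian noise, keep the proposal only if the error decreases,
stop below tolerance. The paper-stated procedure leaves the proposal scale,
tolerance, iteration budget, and initialization open; the package defaults
are a 2% relative proposal s.d., tolerance 1e−6, 2×10⁴ iterations, 5
seeded restarts, and a moment-matching initialization (slope and threshold
from inverting the homogeneous rate/correlation maps, threshold s.d. from
the local rate sensitivity). A fixed proposal scale cannot reach tight
tolerances — the probability of landing in an ever-smaller error ball
vanishes — so by default the proposal s.d. halves after every 100
consecutive rejections; with `adapt = FALSE` the fit instead returns
best-so-far with a non-convergence flag after the patience window. Error
trajectories are non-increasing by construction and fully reproducible given
a seed. With three observables and five parameters the model is
underdetermined: closed-loop tests assert recovery of the *statistics* (to
1e−6 summed squared error across a 3×3×3 physiological grid), not of the
parameters; empirically the moment-matched initialization keeps fitted mean
slope/threshold close to generating values when heterogeneity is moderate.
`validate_fit()` draws a raster from fitted parameters and compares sampled
statistics with the target under block-bootstrap error bars.

## Calcium binarization

dF/F traces are converted to firing rates by low-pass Butterworth filtering
(normalized cutoff 0.16 — read as a normalized cutoff frequency; order 2 and
zero-phase forward-backward application are package choices, as the original
processing states neither), inverse filtering of the 2 s single-exponential
indicator kernel ($y[n] - a\,y[n-1]$, $a = e^{-1/(\tau f_s)}$), zeroing of
everything below twice the s.d. of the negative deconvolved points, and
scaling by 78.4 to spikes/s (an empirical cell-attached calibration).
Rates become 1-s-bin ON probabilities through an inhomogeneous Poisson
model, $p_{on} = 1 - e^{-\lambda}$ with $\lambda$ the expected spike count
of the bin. The population is summarized by the mean and s.d. across neurons
of time-averaged ON probability and the mean pairwise Pearson correlation of
the ON-probability series (constant series are skipped and counted).

The synthetic fluorescence generator is the forward counterpart: spikes
placed uniformly within their 1-s bin on a 3.9 Hz frame grid, convolved with
the same exponential kernel, plus i.i.d. Gaussian noise. The per-spike dF/F
amplitude (default 0.1) and noise s.d. (default 0.02) are generator knobs
for exercising the pipeline — realistic orders of magnitude for a
single-action-potential transient of a synthetic-dye recording, but no claim
about indicator photophysics (no nonlinearity, bleaching, or neuropil terms
are modeled). Round-trip tests check that spike bins rank above empty bins
and that sub-floor noise leaves the binarized output unchanged.

One caveat the synthetic closed loop makes explicit: noise-free
ON-probability traces from the generative model are near-perfectly
correlated across neurons (all share the drive), unlike estimates recovered
from noisy fluorescence. Pipeline-level analyses therefore compute
statistics from binary spike rasters on the direct route, and from
dF/F-derived ON probabilities on the calcium route.

## Entropy via the population tracking model

The pattern distribution over $2^N$ binary population states is approximated
by two components fitted from data: the synchrony distribution $p_K$ (how
many neurons are ON per bin) and the conditional per-neuron ON probabilities
given the count, $p_{cond}(i, k)$. A pattern $x$ with count $k$ has
probability $p_K(k)\, w(x|k) / Z_k$ with Bernoulli-product weights $w$ at
the count-$k$ conditionals. Probabilistic rasters are first converted to
spikes by 20 seeded Bernoulli draws per bin (an exact Poisson-binomial path
for $p_K$ is available for validation); $p_K$ gets an additive pseudocount
of 1 and the conditional counts a Jeffreys 0.5 (the original method's
regularization is not restated in its summary description, so these are
package choices). Conditional columns are renormalized to sum to $k$ by a
common logit shift rather than probability scaling: the tilt preserves
between-neuron odds ratios, so distributions representable by the weight
family (independent neurons in particular) remain exactly representable.
Counts never observed fall back to the homogeneous profile $k/N$.

Normalizers and conditional moments need no enumeration: $Z_k$ is a
Poisson-binomial pmf value, and because $\log w$ is linear in the pattern,
the within-count entropy has the closed form
$H(X|K{=}k) = \log_2 Z_k - \sum_i [m_i \log_2 p_i + (1-m_i)\log_2(1-p_i)]$
with $m_i = P(x_i{=}1|K{=}k)$ obtained by leave-one-out deconvolution of the
Poisson-binomial (run from whichever end is stable per neuron). The default
entropy is therefore *exact* for any population size, at $O(N^3)$ cost;
full-enumeration ($N \le 20$) and model-sampling estimators are kept as
independent cross-checks and agree to numerical precision and to sampling
error respectively. Entropy per neuron is bounded by 1 bit for binary
neurons, a bound the estimator inherits structurally because it scores a
genuine probability distribution.

`entropy_vs_N()` estimates entropy/neuron for random subsets of 10–100
neurons (20 subsets per size by default), fits
$H/N = A e^{-bN} + C e^{-dN} + e$ by Levenberg–Marquardt from several starts
with $e \ge 0$, and evaluates the fit at $N = 100$ — a standardization that
makes recordings with different neuron counts comparable. With five
parameters on ten points the curve fit is deliberately over-parameterized;
only the interpolated value at 100 neurons is used downstream, and on
noiseless synthetic curves it is recovered to numerical precision. If the
fit fails, the largest-size empirical value is returned with a flag.

## Group statistics

Group-mean differences are tested by pooled-null bootstrap: pool both
groups, redraw groups of the original sizes with replacement, and take the
two-sided tail mass of the null mean-difference distribution at the observed
value, with an add-one correction ($p = (1 + \#\{|d| \ge |d_{obs}|\})/(B+1)$)
so p is never exactly zero — the integral form of the tail mass is a density
idealization. The default is $10^5$ resamples ($10^7$ matches the original
setting when small p-values matter). Two-dimensional mean shifts get a 95%
confidence ellipse from the bootstrap covariance of the mean and the
chi-squared quantile with 2 degrees of freedom (semi-axes
$\sqrt{\chi^2_{0.95,2}\,\lambda_i}$ along the eigenvectors); groups are
resampled independently for between-group shifts, and rank-deficient
covariances are flagged degenerate. Calibration — type-I error near 5% and
ellipse coverage near 95% — is checked by simulation in the test suite.

## The synthetic cohort

`cohort_spec()`/`run_cohort()` wire the stages end-to-end over labelled
groups of synthetic "animals" (per-animal seeds derived deterministically
from a master seed, so results are order-independent and bit-reproducible;
a failing animal is flagged and skipped without aborting the cohort). The
generator mirrors the recordings the analysis was built for: tens to ~200
neurons per animal, 3-minute movies at 3.9 Hz (≈180 one-second bins),
per-neuron parameters fixed across time, i.i.d. drive across bins. What it
deliberately lacks — temporal correlation in the drive, measurement
artifacts, non-Poisson spiking — bounds what passing tests show: they
validate the estimators under the model's own assumptions, not the
assumptions themselves.

## Problem sizes used in the checks

The shipped tests and the results script run at desk scale, chosen to
exercise every code path with comfortable statistical margins: simulator
checks use downscaled networks (scale 0.1–0.25) with the perturbation
direction checks at scale 0.25 averaged over 3 seeds; fit-recovery uses a
3×3×3 grid of targets; the entropy sweep covers rates 0.01–0.5,
correlations 0–0.5 and populations of 10–100 neurons at 2000 bins; bootstrap
calibration uses 1000 replicate experiments at $10^5$ resamples. Full-scale
(1930-neuron) network simulations are supported and take tens of seconds
per stimulus level on one core.

## Known limitations

- The circuit model inherits the simplifications of its source: homogeneous
  5HT3aR cells, no layer 2 vs 3 split, random connectivity, no short-term
  plasticity.
- The analytic model has no temporal correlations and no private noise
  beyond Bernoulli sampling; slope/threshold from circuit fits
  (L4-fraction scale) and from the analytic model (standard-normal scale)
  are not interconvertible.
- The population fit is underdetermined (3 constraints, 5 parameters);
  parameter-level interpretations should be restricted to the mean slope
  and threshold and checked with `validate_fit()`.
- Downscaled networks are qualitative tools; quantitative parameter
  sensitivities should come from the full-scale model.
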