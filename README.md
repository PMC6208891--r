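# mptrescale

Goodness-of-fit tools for marked point-process models of neural population
spiking, built on a generalized time-rescaling transform.

## The problem

Statistical models of population spiking — whether built on spike-sorted
units or directly on unsorted events and their waveform features
("clusterless" models) — are naturally written as marked point processes:
spikes at times $s_j$ with mark vectors $m_j$ (per-channel peak
amplitudes, or a unit label), governed by a joint mark intensity
$\lambda(t, m \mid H_t)$. Classical spike-train goodness-of-fit tools
(KS plots on rescaled interspike intervals) apply to one neuron at a time
and do not carry over directly to such joint models.

The transform implemented here rescales **each spike individually along
its own mark**,

$$\tau_j = \int_0^{s_j} \lambda(t, m_j \mid H_t)\,dt,
\qquad b(m) = \int_0^T \lambda(t, m \mid H_t)\,dt ,$$

so that, if the candidate model is correct, the pairs $(\tau_j, m_j)$ are
independently uniform on the stochastic region
$R = \{(\tau, m) : 0 \le \tau \le b(m)\}$ and the spike count is
Poisson($|R|$). Any uniformity test then becomes a model check:

* **Pearson chi-square** over subregions of $R$
  (`pearson_uniformity()`) — sensitive to misfit in the *mark* structure;
* **KS tests** on the superposed, second-rescaled, boundary-normalized, or
  mark-subspace processes (`ks_pipeline()`) — sensitive to misfit in the
  *rate* over time;
* **interval autocorrelation** (`isi_autocorrelation()`) — sensitive to
  residual dependence.

The package is aimed at computational neuroscientists who fit place-field,
mixture-of-Gaussians, or kernel ("KB") clusterless intensity models and
need calibrated diagnostics for them. It includes the model families, an
exact simulator (Poisson count + rejection + time inversion, with an
iterative variant for history-dependent models), maximum-likelihood and
method-of-moments fitting, leave-one-out bandwidth selection, and three
reproducible simulation studies.

## Worked example

Simulate a two-place-cell population (Gaussian spatial tuning on an AR(1)
position covariate, overlapping Gaussian mark clusters), then ask whether
four candidate intensities fit it — the truth, the truth uniformly scaled
by 0.56 and by 1.6, and a component-wise scaling (0.56, 1.6) that roughly
preserves the overall rate:

```r
library(mptrescale)
s2 <- run_study2(seed = 42, n_steps = 10000)
s2$results[, c("model", "n", "pearson_p", "ks_D", "ks_p")]
#>             model   n    pearson_p       ks_D         ks_p
#>              true 590 2.651471e-01 0.03064352 6.367212e-01
#>       scaled_0.56 590 2.651471e-01 0.22370621 4.517173e-26
#>        scaled_1.6 590 2.651471e-01 0.17131966 1.819242e-15
#>  component_scaled 590 3.614750e-23 0.04998513 1.048481e-01
```

Reading the table: the true model passes both tests (p = 0.27 and 0.64).
The uniformly scaled models leave the Pearson p-value untouched — scaling
cancels out of the subregion probabilities — but the KS test rejects them
overwhelmingly, and the sign of the CDF deviation (`s2$results$ks_sign`)
identifies whether the intensity was under- or over-estimated. The
component-scaled model preserves the overall rate, so the KS test passes
(p = 0.10), but the distorted mark structure drives the chi-square
p-value to $10^{-23}$. The two tests are complementary diagnoses, not
substitutes.

Lower-level building blocks are exported individually: `rescale_marked()`
produces the rescaled pattern and boundary, `superposed_intensity()` /
`second_rescale()` / `normalize_boundary()` / `restrict_subspace()`
implement the univariate reductions, `simulate_marked()` /
`simulate_marked_history()` generate data from any model, and
`fit_place_mark_mle()` / `estimate_lag_moment()` / `fit_mog()` /
`kb_bandwidth_cv()` estimate parameters. A thin command-line front end
ships at `inst/scripts/mpp-gof.R` (subcommands `simulate`, `rescale`,
`gof`, `study1`, `study2`, `power`, `fixture-tetrode`).

See `vignettes/marked-rescaling.Rmd` for the model class, numerical
conventions, and design choices.

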