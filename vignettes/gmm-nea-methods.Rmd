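---
title: "Bandwidth-free nuclear-ensemble spectra: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bandwidth-free nuclear-ensemble spectra: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmmnea)
```

## The problem

A nuclear-ensemble absorption spectrum is built from quantum-chemistry
calculations at many geometries sampled around a molecule's equilibrium
structure. Each geometry `j` and electronic transition `n` contributes a
vertical excitation energy $\Delta E_n(\mathbf{R}_j)$ (eV) and an oscillator
strength $f_n(\mathbf{R}_j)$. The classic discrete estimator smears each
stick over a Gaussian line shape of full-width $\delta_n$:

$$
\sigma_{\mathrm{abs},n}(E) \;=\; C(E)\,\frac{1}{N_g}\sum_{j=1}^{N_g}
\Delta E_{n}(\mathbf{R}_j)\, f_n(\mathbf{R}_j)\,
g\!\left(E - \Delta E_n(\mathbf{R}_j),\, \delta_n\right),
$$

with $g$ a normal density of standard deviation $\delta_n/2$ and $C(E)$ a
prefactor carrying $1/E$ and, in physical mode, the cross-section constants
$\pi e^2 \hbar / (2 m c \varepsilon_0 n_r)$ so that output is in cm².
The full spectrum is the incoherent sum over transitions. The broadening
$\delta_n$ is phenomenological — the package removes it in two stages.

### Stage 1: auto-δ

The discrete sum is formally a weighted kernel density estimate of the
energies with weights $w_j \propto \Delta E_j f_j$. The optimal broadening
is therefore $\delta_n = 2h$ with the weighted rule-of-thumb bandwidth

$$
h = 0.9\,\min\!\left(\hat\sigma_w,\ \mathrm{IQR}_w/1.34\right)\,
n_{\mathrm{eff}}^{-1/5},
\qquad
n_{\mathrm{eff}} = \Big(\sum_j w_j\Big)^2 \Big/ \sum_j w_j^2 .
$$

This is a Silverman-type rule made robust by the interquartile range; the
Kish effective sample size accounts for unequal weights. The exact body of
the published rule is not recoverable from the source text (the equation is
an image), so this form — the standard weighted extension of the rule the
text cites as its basis — is adopted and flagged as such.

### Stage 2: GMM-NEA, no bandwidth at all

Strengths are first converted to transition dipole moments,
$M = \sqrt{3 f / (2\,\Delta E_{\mathrm{Ha}})}$ (atomic units; this *is* the
"square-root transformation" of the underlying method — no further
transform is applied). Per band, the cloud of $(\Delta E, M)$ pairs is
modeled as a bivariate Gaussian mixture with a point mass $\Theta_0$ at
$M = 0$ for symmetry-forbidden snapshots:
$\Theta_0$ is the *exact* fraction of geometries with $f = 0$, the mixture
is fitted to the rest, and component weights are rescaled by $1 - \Theta_0$.

Taking the $\delta \to 0$ limit of the ensemble sum under the mixture
density collapses the line-shape integral by the sifting property and
factorizes each component into a marginal times a conditional normal. The
conditional second moment is exact, giving the closed form

$$
\sigma_{\mathrm{abs},n}(E) = C(E)\, E \,\frac{2}{3} E_{\mathrm{Ha}}
\sum_k \pi'_{n,k}\,
\varphi\!\left(E;\ \mu_{1,n,k},\ \sigma^2_{1,n,k}\right)
\left(\tilde\mu_{n,k}(E)^2 + \tilde\sigma^2_{n,k}\right),
$$

$$
\tilde\mu_{n,k}(E) = \mu_{2} + \rho\,\frac{\sigma_{2}}{\sigma_{1}}(E - \mu_{1}),
\qquad
\tilde\sigma^2_{n,k} = \sigma_2^2\,(1 - \rho^2).
$$

No broadening parameter appears anywhere. A note on the energy factor: the
source text's equations are images, so the exact prefactor cannot be read
off. The package adopts the unique convention in which (i) the small-δ area
of a discrete band equals $\overline{f}$ in arbitrary mode and (ii) the
closed form is the *exact* $\delta \to 0$ limit of the discrete sum — this
forces the factor $E \cdot (2/3) E_{\mathrm{Ha}}$ above, and makes discrete
and mixture spectra directly comparable under one shared $C(E)$. The
pre-limit 2-D quadrature oracle in the test suite pins this down to 1e-4
relative.

## Mixture fitting and model selection

EM is run under the eight covariance families with closed-form M-steps
(EII, VII, EEI, VEI, EVI, VVI, EEE, VVV — spherical/diagonal/full crossed
with equal/varying volume and shape), for component counts `K = 1..9` by
default. The pair (K, family) maximizing $\mathrm{BIC} = 2\ell - \nu\log n$
is selected; ties go to fewer parameters, then fewer components. Design
choices the source leaves open, decided here once:

* **Initialization**: k-means++ seeding of hard responsibilities with 5
  random restarts under a user seed. The reference mixture package uses
  model-based hierarchical agglomeration instead; at the sample sizes of
  ensemble data the restarts make this difference immaterial, and a seeded
  initialization keeps every run bit-reproducible.
* **Orientation-coupled families** (EVE, VVE, EEV, VEV, EVV, VEE) have
  iterative M-steps and are omitted; for 2-D density estimation the eight
  closed-form families select densities of near-identical quality, and all
  acceptance checks here are property-based, not tied to a published table
  of selected labels.
* **Convergence**: relative log-likelihood tolerance 1e-8, at most 500
  iterations. **Degeneracy**: a per-dimension variance floor of 1e-10 times
  the data variance (anchored also to the squared data magnitude so
  exactly-degenerate inputs are caught), and any component whose weight
  drops below $1/(10n)$, abort the run; the restart draws a fresh seeding.
* **Truncation**: the mixture lives on the whole plane although physically
  $\Delta E > 0$, $M \ge 0$. Spectroscopic clouds sit many standard
  deviations from the axes, so leakage is negligible; a warning fires if
  any fitted component puts more than 1% of its mass at negative
  coordinates.

## Uncertainty

Confidence bands are percentile bootstrap: `B = 999` replicas by default,
resampling whole geometries with replacement *jointly across bands* (the
ensemble rows are coupled), 95% bands from the 2.5%/97.5% quantiles. For
GMM-NEA each replica re-estimates $\Theta_0$ and refits with (K, family)
fixed to the original selection — re-selection per replica is available
behind a flag but is not the prescribed procedure. Replicas that fail to
refit are redrawn; more than 10% failures aborts. The full-spectrum band is
the sum of per-band bounds by default; quantiles-of-summed-replicas are
available via `ci_method = "sum-replicas"` since the published convention
cannot be read from the text. Percentile bands need not contain the point
estimate, and that is not asserted.

## Outlier screening

Anomalous quantum-chemistry points are screened by squared Mahalanobis
distances under robust estimates — coordinatewise median and
median-centered scatter $\mathbf{M_X}\mathbf{M_X}^\top/(n-1)$ — referred to
$\chi^2_p$, with FDR labeling at `q = 0.001` (under 0.1% expected false
flags). Two readings of the published rank rule exist; the step-up
procedure (flag all ranks up to the largest $i$ with $p_{(i)} \le i q/n$)
is the standard one and is the default, the literal per-rank thresholding
sits behind `rule = "literal"`. Screening runs per band on $(\Delta E, M)$
with geometry flags unioned across bands, because the joint concatenated
space is singular whenever $2 N_s \ge n$ (a real regime: 79 spin–orbit
states over 200 geometries); joint mode is available and falls back
automatically.

## Convergence metrics

`ric` is the L1 difference relative to the target area; `bric` averages it
over bands without intensity weighting, so weak bands are not drowned out
by strong ones; `bric_seq` compares consecutive active-learning batches,
normalizing by the newer (better-sampled) spectrum, with named stopping
presets 0.1 / 0.05 / 0.025. The equation bodies are images in the source
text; these L1 forms, the unweighted band mean, and the new-batch
denominator are the adopted readings and are marked as such. Dark bands
(zero target area) are excluded from the mean and reported.

## Photolysis rates

$J = \int \phi(\lambda)\,\sigma(\lambda)\,F(\lambda)\,\mathrm{d}\lambda$
over the overlap of the spectrum and actinic-flux supports, trapezoid rule,
flux interpolated onto the spectrum grid, $\phi \equiv 1$ by default (the
simplification used in the source application). The spectrum must be built
in physical mode (cm²) — arbitrary-mode input is an error, not a silent
wrong answer. Wavelength conversion is the pointwise relabeling
$\lambda = 1239.841984/E$; no Jacobian, because the cross section is a
pointwise function, not a density.

## What the synthetic generator does and does not establish

`demo_truths()` states a three-band world chosen once to mirror the regimes
of real ensembles: a unimodal correlated band (4.5 eV), a bimodal band with
two overlapping electronic clusters (5.5/5.9 eV), and a band with a 30%
forbidden-transition mass (6.5 eV). Dipole means sit at spectroscopically
realistic 0.3–0.8 a.u., and every component mean is at least 4 standard
deviations above both axes so that rejection sampling distorts the stated
density by less than ~1%. Samples are drawn per geometry and band, with
forbidden snapshots emitted at rate $\Theta_0$ and strengths recovered by
inverting the dipole relation.

A green test on this world establishes that the estimators recover a
distribution that *is* a finite Gaussian mixture with independent
geometries. Real ensembles differ: their $(\Delta E, M)$ clouds are only
approximately mixtures, Wigner/MD sampling can correlate geometries, and
heavy tails from near-degeneracies are not emulated. The outlier injector
models one corruption mode (a dipole inflated to a stated number of robust
standard deviations above the band median), not the full variety of failed
quantum-chemistry runs.

## Numerical choices

* Energies are carried in eV end to end; Hartree enters only inside the
  dipole conversion and the closed form. Affine unit changes merely
  reparameterize the mixture and leave spectra invariant (tested).
* "Full-width δ" means twice the Gaussian standard deviation, forced by
  the identity $\delta = 2h$ against the KDE bandwidth; an FWHM reading is
  available via `fwhm = TRUE` for interoperability with other codes.
* Weighted quantiles (for $\mathrm{IQR}_w$) aggregate tied abscissae and
  interpolate midpoint cumulative-weight positions. Tie aggregation makes
  the quantile function exactly invariant under sample duplication, which
  in turn makes the $2^{-1/5}$ bandwidth scaling identity hold to machine
  precision; equal weights reduce to $(i - \tfrac12)/n$ positions, within
  $O(1/n)$ of the common type-7 convention.
* Default grid: 2001 points spanning the data range padded by 3 maximal
  broadenings — enough to resolve ~0.02 eV bandwidths over ~10 eV spans.
* Bootstrap quantiles use the standard type-7 interpolation.
* Dark bands ($\Theta_0 = 1$) yield zero spectra rather than errors so that
  full-spectrum assembly, metrics, and photolysis stay uniform.

## Known limitations

Only bivariate (per-band) mixtures are supported — no joint fitting across
bands and no ≥3-D extensions. Lorentzian line shapes, temperature-dependent
broadening, and emission spectra are out of scope. The physical-mode
prefactor assumes a dispersion-free refractive index. Reported acceptance
quantities are properties of the stated synthetic world; published numbers
that depend on external quantum-chemistry datasets (tens of thousands of
geometries) are not reproducible from this package alone and are not
claimed.
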