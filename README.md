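# gmmnea

Reconstruction of electronic absorption cross-section spectra from
nuclear-ensemble quantum-chemistry output — without choosing a broadening
by hand.

## Who this is for

Computational photochemists who have run excited-state calculations
(TD-DFT, CASPT2, ...) at an ensemble of sampled geometries and now hold,
for each geometry *j* and transition *n*, a vertical excitation energy
ΔE<sub>n</sub>(**R**<sub>j</sub>) (eV) and an oscillator strength
f<sub>n</sub>(**R**<sub>j</sub>). The classic nuclear-ensemble estimator

σ<sub>abs,n</sub>(E) = C(E) · (1/N<sub>g</sub>) Σ<sub>j</sub>
ΔE<sub>n,j</sub> f<sub>n,j</sub> g(E − ΔE<sub>n,j</sub>, δ<sub>n</sub>)

needs a phenomenological full-width δ<sub>n</sub> per band. This package
provides:

* **auto-δ** — δ<sub>n</sub> = 2h, with h the weighted-KDE rule-of-thumb
  bandwidth 0.9·min(σ̂<sub>w</sub>, IQR<sub>w</sub>/1.34)·n<sub>eff</sub><sup>−1/5</sup>
  computed from weights w<sub>j</sub> ∝ ΔE<sub>j</sub>f<sub>j</sub>;
* **GMM-NEA** — no broadening at all: per band, the (ΔE, M) cloud
  (M the transition dipole, M² = 3f/2ΔE<sub>Ha</sub> in atomic units) is
  fitted by a BIC-selected bivariate Gaussian mixture with a point mass
  Θ₀ for forbidden snapshots, and the spectrum is the closed-form δ→0
  limit
  σ(E) = C(E)·E·(2/3)E<sub>Ha</sub>·Σ<sub>k</sub> π′<sub>k</sub>
  φ(E; μ<sub>1k</sub>, σ²<sub>1k</sub>)·(μ̃<sub>k</sub>(E)² + σ̃²<sub>k</sub>);
* percentile-bootstrap confidence bands (B = 999, geometries resampled
  jointly across bands, fixed (K, model) per replica);
* robust-Mahalanobis / χ² outlier screening of QM points with FDR control
  (q = 0.001 default);
* RIC / bRIC / bRIC_seq convergence metrics with active-learning stopping
  presets (0.1, 0.05, 0.025);
* photolysis rates J = ∫ φ(λ) σ(λ) F(λ) dλ against actinic-flux tables;
* a seeded synthetic-ensemble generator so the whole stack is testable
  without any external dataset.

See `vignettes/gmm-nea-methods.Rmd` for the models, assumptions, and every
numerical choice.

## Worked example

```r
library(gmmnea)

truths <- demo_truths()                         # stated 3-band ground truth
tab <- sample_ensemble(truths, 500, seed = 1)   # 500 geometries x 3 bands
tab[1:3, ]
#>   geom_id state  delta_E          f
#> 1  g00001     1 4.537971 0.09472030
#> 2  g00001     2 6.055795 0.01258892
#> 3  g00001     3 6.376235 0.00000000

auto_delta(extract_band(tab, 1))                # stage 1: data-driven delta
#> <kde_bandwidth> state 1: h = 0.042229 eV, delta = 0.084458 eV (n_eff = 463.9)

cfg <- fit_config(K_range = 1:3, restarts = 2, seed = 2)
grid <- energy_grid(3.5, 7.5, 2001)
spec <- full_spectrum_gmm(tab, cfg, grid = grid) # stage 2: bandwidth-free
band_fit_report(attr(spec, "band_fits"))[, c("state","theta0","K","model","pro","mu1","mu2")]
#>   state theta0 K model       pro      mu1       mu2
#> 1     1  0.000 1   EEE 1.0000000 4.493823 0.8008483
#> 2     2  0.000 2   EEI 0.4183233 5.896528 0.3512377
#> 3     2  0.000 2   EEI 0.5816767 5.489776 0.5007005
#> 4     3  0.312 1   EEI 0.6880000 6.506306 0.4008095

truth <- truth_spectrum(truths, grid)
bric(spec$bands, truth$bands)$value              # band-wise relative error
#> [1] 0.0497
```

Reading the fit report: band 2's two overlapping electronic clusters are
recovered (K = 2, means at 5.49/5.90 eV vs the true 5.5/5.9), and band 3's
31.2% of exactly-forbidden snapshots is the counted Θ̂₀, with the component
weights rescaled so they sum to 1 − Θ̂₀. The bRIC of 0.0497 says the
reconstructed bands differ from the analytic truth by ~5% in integrated
absolute deviation, each band weighted equally; the same 500-geometry draw
reconstructed with auto-δ gives 0.1186, illustrating why the mixture route
is preferred at small sample sizes.

Bootstrap bands and outlier screening:

```r
boot <- bootstrap_spec(B = 999, alpha = 0.05, seed = 3)
ci <- full_spectrum_gmm(tab, cfg, grid = grid, boot = boot) # 95% bands

qc <- fdr_screen(tab, q = 0.001)        # robust Mahalanobis + FDR, per band
flagged_geometries(qc)
```

## Command line

```sh
Rscript -e 'quit(status = gmmnea::nea_cli())' simulate --n-geoms 500 --seed 1 --out ens.csv
Rscript -e 'quit(status = gmmnea::nea_cli())' spectra --input ens.csv --method gmm-nea --out spec.csv
Rscript -e 'quit(status = gmmnea::nea_cli())' qc --input ens.csv --q 0.001 --out qc.csv
Rscript -e 'quit(status = gmmnea::nea_cli())' photolysis --spectrum spec.csv --flux flux.txt
```

Exit codes: 0 ok, 1 validation error, 2 fit failure, 3 I/O error.

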