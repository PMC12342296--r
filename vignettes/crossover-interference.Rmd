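---
title: "Modelling crossover interference from synaptonemal-complex cytology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling crossover interference from synaptonemal-complex cytology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coimeio)
```

## The measurement and the model

At pachytene of meiotic prophase I, each pair of homologous chromosomes is
held by a synaptonemal complex (SC) whose axis can be traced and measured
in spread nuclei, and each class-I crossover (CO) is marked by an MLH1
focus on that axis. A fully scored spermatocyte therefore yields, per
bivalent: the axis length (µm), the centromere position, and the ordered
CO positions along the axis. `coimeio` analyses exactly this kind of
table: per-cell CO frequencies, CO positions relative to the centromere,
crossover interference, and — from separately staged cells — RPA focus
counts tracking double-strand-break (DSB) turnover through prophase I.

Crossover interference is modelled the standard way: distances between
adjacent COs are treated as draws from a gamma distribution. Writing
$\nu$ for the shape and $\lambda$ for the CO intensity (expected COs per
µm), inter-CO gaps are

$$X \sim \mathrm{Gamma}(\nu,\ \mathrm{rate} = \nu\lambda),
\qquad E[X] = 1/\lambda,\qquad \mathrm{CV}[X] = \nu^{-1/2}.$$

$\nu = 1$ is a Poisson (no-interference) placement; larger $\nu$ means
more evenly spaced COs. The complementary, model-free view is the
coefficient of coincidence (CoC): each arm is scaled to its length and
cut into 20 segments, and for every segment pair the observed frequency
of arms with a CO in *both* segments is divided by the product of the
single-segment frequencies. CoC $\approx 0$ at short separations and a
return to 1 at large separations is the signature of interference.

The package is organised around one estimator, `coi_fit()`, which fits
the gamma model by maximum likelihood to the distances between the two
MLH1 foci of two-CO SCs, computes the CoC curve, and locates the
interference distance (first separation where CoC reaches 1). Its
`simulate()` method closes the loop by regenerating synthetic datasets
under the fitted parameters.

## The synthetic-data generator

Downstream analyses are exercised on data from `simulate_dataset()`,
which draws cells with the statistical structure the analyses assume:

* **Stationary gamma renewal per arm.** CO positions are a renewal
  process with Gamma($\nu$, $\nu\lambda$) gaps. The first event is drawn
  from the equilibrium (forward-recurrence) distribution — sampled as
  $U \cdot G$ with $U$ uniform and $G$ a length-biased
  Gamma($\nu+1$, $\nu\lambda$) gap — so the process is
  translation-invariant and the marginal CO intensity is constant along
  the axis. An origin-anchored renewal would pile events near the origin;
  the stationary construction avoids that artefact, and it makes the
  expected event count on an interval equal to $\lambda \times$ length
  for every $\nu$.
* **Karyotype profile.** 17 bivalents (2n = 34), SCs 1 and 4 metacentric
  with the centromere at 45% of the axis, the rest acrocentric. Rank
  lengths interpolate the reference morphometry: ranks 1–4 linearly from
  130.5 to 111.9 µm, ranks 5–17 geometrically from 80.6 down to 17.3 µm,
  the whole profile scaled so the grand mean SC length is exactly
  60.31 µm. The geometric short-SC decay is what makes the printed rank
  extremes and the printed grand mean mutually consistent. Per-cell and
  per-SC lognormal noise (CV 8% and 4%, mean one) reproduce realistic
  spread without moving expected lengths.
* **Axis shrinkage.** One multiplier on all lengths models the
  temperature-induced axis shortening (e.g. 48.31/60.31 for a 20 °C-like
  condition). Whether a condition changes $\nu$, $\lambda$ or only
  shrinkage is deliberately left as three independent knobs.
* **Obligate CO.** Each SC is resampled (placement *and* thinning) until
  at least one focus survives, so conditioning respects suppression. The
  upward bias this puts on the realised intensity is absorbed by
  `calibrate_intensity()`, which bisects the per-µm intensity against
  batched simulation at a fixed calibration seed until the mean focus
  count per cell matches the target (default 20.18).
* **Centromere suppression.** Foci within 10% of the arm measured from
  the centromere are removed independently with probability 0.9. The
  radius matches the 10% analysis window of `centromere_effect()`; the
  probability is a package choice representing the strong pericentromeric
  suppression seen at the optimum temperature (the source data show a
  centromere effect but quantify no thinning rate).
* **Metacentric arms** are independent renewal processes — no
  interference acts across the centromere — matching the convention of
  analysing p and q arms separately.
* **RPA counts.** Per stage, counts are negative-binomial with the size
  parameter solved from the configured mean/SD
  ($\mathrm{size} = \mu^2/(\sigma^2-\mu)$; Poisson when
  $\sigma^2 \le \mu$). Defaults follow the 28 °C stage profile
  (leptotene 105.55 ± 32.57 down to pachytene 19 ± 30.35); the
  unreported early-zygotene mean is set to 85 ± 30, between its
  neighbours.

What the generator does *not* emulate: focus-detection error and fusion
of nearby foci, per-animal random effects, the non-interfering (class II)
CO pathway, and within-cell SC length evolution. Tests passing on
simulated data therefore certify the estimators against their own model
class, not against microscope-level noise.

## Estimation choices

**Gamma fit.** `fit_gamma_ml()` solves the profile score equation
$\log s - \psi(s) = \log \bar x - \overline{\log x}$ by Newton iteration
from the moment start $\bar x^2 / s_x^2$ (bisection fallback), stopping
at $10^{-8}$ on the gradient; the rate is $s/\bar x$. A Wald CI comes
from the profile information $n(\psi'(s) - 1/s)$. Degenerate inputs
(constant distances) and small samples (n below 30 by default) are
refused rather than fitted.

**Distance pooling.** Only SCs with exactly two foci enter the fit, and
distances default to raw µm. Under the per-µm renewal model the gap law
is the *same* for every SC in µm, so raw distances pool cleanly; dividing
by SC length (the `normalize = TRUE` variant, provided because scoring
pipelines differ) makes each SC contribute on its own scale and biased
the recovered shape by tens of percent at low $\nu$ in our recovery
experiments. Cross-centromere distances on metacentrics are included by
default (`include_metacentric`), but recovery studies exclude them: the
generator places the two arms independently, so a two-CO metacentric
with one CO per arm contributes an interference-free distance that
attenuates the fitted shape (measured: $\nu = 12$ recovered near 11.5
without metacentrics, near 8 with them).

**CoC.** Interval occupancy is binary (an arm either hits a segment or
not), pairs with zero expected frequency are excluded and counted, and
pair ratios at one separation are averaged with equal weight (arm counts
are common to all pairs of one dataset). The vectorised implementation is
tested for exact equality against a naive double-loop count.

**Interference distance.** The first upward crossing of CoC = 1, located
by linear interpolation between adjacent curve points, no smoothing; if
the curve never reaches 1 the maximum separation is returned with a
`reached = FALSE` flag. Two caveats, both visible in simulation:
(i) when arms of very different length and sub-unity CO load are pooled,
single-CO arms keep the CoC below 1 at *all* separations, so the
crossing may simply not occur; (ii) at a fixed intensity the crossing
point tracks the mean inter-CO distance, and a *larger* $\nu$ sharpens
the rise so the curve crosses 1 slightly earlier — the robust signature
of stronger interference is the deeper and wider trough (e.g. the CoC =
0.5 recovery distance), not the CoC = 1 crossing. A longer CoC = 1
distance in real data is therefore evidence about the joint
intensity/interference configuration, which is exactly how the package
reports it.

**Null bias of the two-CO harvest.** Conditioning a Poisson placement
with mean 2 on *exactly two* COs on a unit bivalent makes the two
positions iid uniform, so their distance has density $2(1-x)$ — and the
ML gamma shape fitted to that law is $\approx 1.40$, not 1. The
interference-free reference value of the two-CO harvesting procedure on
short bivalents is thus above 1; fitted shapes should be read
comparatively across conditions, not as absolute distances from the
Poisson null. (On long axes with many COs the bias vanishes; it is a
finite-interval conditioning effect.)

## Other conventions and degenerate inputs

* Positions are stored in µm from a fixed origin: the centromeric end for
  acrocentrics, the p-telomere for metacentrics. Fractions are always
  derived.
* A metacentric focus exactly at the centromere belongs to the q arm.
* Relative-position histograms use half-open bins $[k/10, (k+1)/10)$ with
  the last bin closed so `pos_frac = 1` is countable.
* SC ranking assigns 1–17 by descending length with metacentrics pinned
  to the reference metacentric ranks; ties break by centromere position
  (nearer the midpoint first), then input order — deterministic by
  construction. Cells without exactly 17 scored SCs are excluded and
  logged.
* The t-test defaults to Welch; two constant, equal samples return
  p = 1 by convention. The class chi-squared pools classes with expected
  counts below 5 into the adjacent lower class before testing, without
  continuity correction.
* Stage is a closed four-level factor (leptotene, early zygotene, late
  zygotene, pachytene); Tukey HSD comparisons run across temperatures
  within a stage by default, with an across-stage mode.

## Problem sizes

The shipped tests run the generator at desk scale: condition-level
checks use 120–300 cells, parameter-recovery uses 20 replicates of 500
two-CO distances per $\nu \in \{2, 4, 8, 12\}$ (median relative shape
error required below 15%), Monte-Carlo identities (gap CV, stationarity,
Poisson reduction) use $2\times10^4$–$10^5$ draws, and the CoC null uses
5,000 Poisson arms. These sizes were chosen so each statistical check
has comfortable Monte-Carlo headroom at its stated tolerance.

## A worked run

```{r example, eval = FALSE}
cfg <- sim_config(nu = 8.35, target_mean_foci_per_cell = 20.18,
                  n_cells = 230, seed = 8)
ds <- simulate_dataset(cfg)
fit <- coi_fit(ds)
fit
plot(fit)                   # CoC curve
plot(fit, which = "gamma")  # distance histogram + fitted density
sims <- simulate(fit, nsim = 3, seed = 1)
```

`run_pipeline(run_config(sim = list(...), out_dir = "out"))` executes the
same analyses end to end and writes tidy CSV tables stamped with the
configuration hash and seed, so identical configurations give
byte-identical bundles.
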