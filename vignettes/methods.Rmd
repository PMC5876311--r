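---
title: "Methods: age-conditional vital-sign centile modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-conditional vital-sign centile modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pedcentiles)
```

This vignette records the statistical model, its assumptions, and the
design decisions behind `pedcentiles`, in the spirit of a methods section:
everything a maintainer would need to know about *why* the code is the way
it is. No empirical claim is made here that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The model

For a positive vital-sign measurement $y$ at age $t$, both supported
families transform $y$ through the Box–Cox map

$$z = \begin{cases}
  \dfrac{(y/\mu)^\nu - 1}{\nu\,\sigma}, & \nu \neq 0,\\[1ex]
  \dfrac{\log(y/\mu)}{\sigma}, & \nu = 0,
\end{cases}$$

and model $z$ with a standardized symmetric kernel:

* **BCPE** — a power exponential with exponent $\tau$, scaled by
  $c(\tau) = [2^{-2/\tau}\Gamma(1/\tau)/\Gamma(3/\tau)]^{1/2}$ so that
  $\mathrm{Var}(Z)=1$ and $\tau = 2$ is *exactly* the standard normal.
  With $\tau = 2$ the family is the Box–Cox normal (LMS) family.
* **BCT** — an unscaled Student $t$ with $\tau$ degrees of freedom, which
  converges to the Box–Cox normal as $\tau \to \infty$. Used for
  respiratory rate, whose raw distributions are strongly leptokurtic and
  right-skewed.

$\mu$ is the exact median (the kernel median is 0), $\sigma$ the relative
dispersion, $\nu$ the skewness power, $\tau$ the kurtosis parameter.
Quantiles are closed-form: $y_p = \mu(1 + \nu\sigma z_p)^{1/\nu}$ (or
$\mu e^{\sigma z_p}$ at $\nu = 0$). A z-score is
$\Phi^{-1}(F(y))$, the standard-normal equivalent deviate.

**Truncation.** The Box–Cox map is only defined for
$1 + \nu\sigma z > 0$, i.e. the model formally assigns a small mass
outside $y > 0$. For the parameter ranges seen in vital signs
($\sigma|\nu| \lesssim 0.3$) the missing mass is negligible
($< 10^{-9}$), so quantile, cdf and z-score omit the truncation
correction — standard centile-construction practice that keeps the
quantile closed-form. The density can be renormalized exactly on request
(`bc_pdf(..., renormalize = TRUE)`); a centile request beyond the domain
bound $z = -1/(\sigma\nu)$ is reported as a *tail-truncation breach*
(warning + `NaN`) rather than silently clamped. Whether the original
fitting software included the truncation constant in its density is not
documented; both options are therefore available for the density, and the
omitted-constant convention is used everywhere else.

**Numerical switch.** The $\nu = 0$ log branch takes over for
$|\nu| < 10^{-5}$; the two branches agree to machine precision well
before the switch.

## 2. Inverting published centile rows

`fit_params_to_centiles()` recovers $(\mu, \sigma, \nu, \tau)$ from a set
of $(p, y_p)$ points. With more than four points it minimizes the sum of
squared quantile residuals over $(\log\mu, \log\sigma, \nu, \log\tau)$
(Nelder–Mead, then BFGS polish, from a normal-case moment-matched start);
with exactly four points the least-squares solution is polished by damped
Newton iteration on the $4\times4$ system to residuals below $10^{-8}$.
$\tau$ is box-constrained to $[0.5, 200]$ (BCPE) and $[1, 10^6]$ (BCT).

Two facts about published tables matter:

* Printed integers can *tie* between neighboring centiles (the RR table
  ties C2.5 = C5 at several adolescent ages). The least-squares path
  therefore accepts non-decreasing values; only decreases are rejected as
  genuinely non-monotone. The exact four-point inversion still requires
  strict monotonicity.
* The shape parameters $\nu$ and $\tau$ are barely identified from 11
  integer-rounded quantiles: many $(\nu,\tau)$ pairs fit a row almost
  equally well, so per-row inverted $\tau$ sequences can swing wildly
  across age (values from ~5 to ~150 on the RR table) while the implied
  *quantiles* barely move. Every use of these parameters downstream
  treats the implied quantile function, not the raw parameters, as the
  anchor; all 880 printed cells are reproduced within ±1 unit
  (integer-rounding tolerance), with a hard error if any row fails.

## 3. Cleaning rules

One observation per encounter, built in this stage order (reason recorded
for the first failing stage):

1. `missing_vital` — HR, RR or TMP never recorded;
2. `discordant_duplicates` — two or more values for one vital at the same
   recorded minute whose range exceeds 10% of the largest value (HR, RR)
   or 3% (TMP); concordant duplicates are averaged, discordant sets
   exclude the *encounter*;
3. `not_within_15min` — no (HR, RR, TMP) triple with all pairwise time
   gaps ≤ 15 minutes; when several qualify, the "initial" triple is the
   one whose latest member is earliest (ties by input order) — the source
   rule says only "initial", so this is a documented choice;
4. `extreme_value` — HR < 30 or > 300 bpm (30 and 300 themselves are
   *kept*), RR = 0 or ≥ 120 (120 is dropped), TMP < 30 or > 46 °C
   (bounds inclusive);
5. `trauma`, 6. `chronic_dx` — flag-based exclusions. The original
   diagnosis-code list is not available; the pipeline takes the flag
   directly (a configurable code list would slot in upstream of it).

Duplicate resolution must precede triple assembly (a discordant
simultaneous set invalidates the encounter outright), which is why stage
2 sits before stage 3 even though a reason enumeration might list them
otherwise. Ages are categorical (integer months below 2 years, integer
years above) and each category is represented by its midpoint in years —
0–1 month is 0.042 years, 17 years is 17.5.

## 4. Age-smooth fitting

Each distribution parameter gets a link (log for $\mu,\sigma,\tau$;
identity for $\nu$) and a predictor $\eta_k(t) = B(t^\zeta)\beta_k$ with:

* cubic B-splines on 20 equally spaced interior knots over the
  transformed-age range (Eilers–Marx construction),
* a second-order difference penalty, with the penalty weight solved at
  each cycle so the smoother matches a *target effective df* (this makes
  "edf" the user-facing smoothing dial, as in standard centile practice),
* the power parameter $\zeta \in [0.01, 1]$ spreading out the rapidly
  changing infant ages.

Fitting is cyclic backfitting of RS type: for each parameter in the
stepwise order $\mu \to \sigma \to \nu \to \tau$, compute per-observation
score $u_i = \partial\ell_i/\partial\eta$ and curvature
$w_i = -\partial^2\ell_i/\partial\eta^2$ (central differences at
$h = 10^{-3}$ on the predictor scale; non-positive curvatures replaced by
the median positive value), form the working variable
$z_i = \eta_i + u_i/w_i$, and solve the penalized weighted least-squares
problem aggregated over the distinct age bins. A step-halving line search
keeps the penalized deviance non-increasing; cycles stop when its
relative change falls below `tol` ($10^{-6}$). With a single distinct
age the problem degenerates to a direct four-parameter ML fit, which is
what the code then does.

Respiratory rate is preprocessed by `rr_preprocess()`: zero-mean Gaussian
noise, *standard normal truncated to ±2 breaths/min* on the raw scale,
then the natural log. The truncation form is not documented in the
original description ("up to ±2"); the truncated standard normal is the
simplest distribution meeting it and is recorded here as the package's
choice. A dithered value that would be non-positive (possible only for
RR ≤ 2) is redrawn. The dither seed is stored in the fitted model for
provenance.

**Model selection.** SBC $= -2\log L + \ln(n)\,\mathrm{edf}_{total}$.
The search is two-stage and deterministic: $\zeta$ on its grid (default
$\{0.01, 0.05, 0.1, \dots, 1.0\}$) at a fixed starting edf, then
per-parameter edf by one pass of coordinate descent in the stepwise order
over the grids $\{2,3,5,8,12\}$ ($\mu,\sigma$) and $\{2,3,5\}$
($\nu,\tau$). Whether the original power-parameter search was nested
inside or outside smoothing selection is not documented; the full
cartesian product (≈2,250 fits) is computationally indefensible for no
expected gain, so the two-stage search is this package's design. The
returned model always has the smallest SBC among the fits evaluated.

**Defaults.** For direct (non-search) fits the package defaults follow
what SBC selection chooses on table-anchored synthetic data at scale:
$\zeta = 0.3$–$0.4$, edf $(\mu, \sigma, \nu, \tau) = (12, 8, 5, 5)$.
These are starting points, not dogma — `select_model()` re-derives them
from any given data set.

## 5. Reference tables

`make_centile_table()` evaluates the fitted quantiles on the canonical 40
age midpoints × 11 centile levels (440 cells per vital);
`make_zscore_table()` uses $z \in \{-3.0, -2.5, \dots, +3.0\}$ (13
columns; the 0.5 step of the original supplementary sheets is assumed, as
the main text does not state it). Log-scale models are exponentiated
before tabulation. Cells are rounded half-away-from-zero to integers
(the publication prints integers; the rounding rule is unstated, and
half-away-from-zero is the convention monitors and clinicians expect);
unrounded grids ride along as an attribute, and all internal comparisons
(validation cutoffs, sensitivity analysis input) use unrounded values —
rounding is presentation only. Non-crossing of centile curves at a given
age is structural: quantiles are strictly increasing in $p$ for any valid
parameter vector, so crossing could only enter through an invalid
($\sigma, \tau \le 0$) prediction, which the link functions exclude and
the fitter additionally asserts.

## 6. Validation machinery

* `split_sample()` — per age category, a random $\lfloor 2n/3 \rfloor$
  records train, the rest test; reproducible by seed.
* `count_extremes()` — strict inequalities against the age-matched
  training-model cutoffs; the four groups (>99th, >95th, <5th, <1st) are
  counted independently, so >99th is numerically nested in >95th.
* `compare_proportions()` — the published table annotates its tests with
  "df = 1", which identifies a one-degree-of-freedom chi-square; the
  default is therefore Pearson's chi-square without continuity
  correction, with Fisher's exact test as an option (`method =
  "fisher"`). "Exact chi-square" is ambiguous between the two; both are
  provided and documented.
* `holm_adjust()` — step-down Bonferroni with family size 4 per vital
  (the four centile groups, adjusted separately for HR and RR).
  Recomputing adjustments from *printed rounded* raw p-values reproduces
  the printed adjusted values only where rounding does not interfere
  (e.g. raw 0.09 printed against adjusted 0.37 implies an unrounded raw
  ≈ 0.0925); the test suite asserts exactly the entries that are
  recomputable from the printed precision.
* `sensitivity_compare()` — cellwise comparison of two rounded 40×11
  tables (with vs without the trauma/chronic exclusions), reporting
  count, location and magnitude of discrepancies.

## 7. The synthetic-data generator

The generator's defaults restate the documented structure of the source
cohort — they are a *stated world*, not tuning knobs:

* age mix = the published per-category encounter shares (sum
  1,203,042);
* HR drawn from the age category's inverted BCPE parameters, rounded to
  integers (monitor convention); RR drawn from the inverted log-scale BCT
  parameters and exponentiated;
* even-digit preference in recorded RR: with probability 0.6 a value is
  rounded to the nearest even integer, otherwise to the nearest integer.
  The source documents the *phenomenon* (digit bias reducing apparent
  variation), not its form or strength; 0.6 is an exposed placeholder
  chosen to exercise the dither, and no claim about the real data;
* simultaneous duplicates on 7% of encounters (the documented "about
  7%"), of which 10% are discordant — the split into concordant and
  discordant is undocumented, and 10% makes both paths testable;
* trauma + chronic flags on 0.4% of encounters (documented "~0.4%"),
  split evenly;
* implausible outliers on 0.2% of encounters (undocumented in the
  source, which only defines the exclusion bounds; 0.2% gives the
  cleaning tests a measurable signal without distorting the fits);
* body temperature from a truncated normal, mean 37.2 °C, SD 0.8,
  bounds [34, 42] — an invented marginal that exists only so the
  15-minute triple rule and the TMP duplicate rule are exercised
  (temperature is otherwise unused, mirroring the source's decision to
  drop temperature correction);
* measurement times within a 10-minute window, so triples qualify by
  construction; window breaches enter the tests through handcrafted
  cases instead.

Whether the documented 7% duplicate share counts encounters or
measurements is ambiguous; the generator reads it as the fraction of
encounters carrying at least one duplicated vital.

**What a green test does and does not establish.** The generator
reproduces the *marginal* per-age distributions and the documented
artifact rates. It does not emulate hospital-level clustering,
seasonality, diagnosis mix, within-category age gradients (ages sit at
category midpoints), or correlation between HR and RR within a child. A
green end-to-end test therefore establishes that the pipeline recovers
known distributional structure through cleaning, dithering, fitting and
tabulation — not that it would reproduce the published tables from the
original records.

## 8. Known numerical limits

* The per-row inversion leaves $\nu, \tau$ weakly identified (§2); treat
  inverted parameters as a quantile oracle, not as physiology.
* P-splines with a second-order penalty carry some bias at the age-range
  boundaries. In the parameter-recovery acceptance check (n = 50,000
  over 40 bins, 2% pointwise tolerance on C5/C50/C95) the first age bin
  (0.042 years) shows ~1% smoothing bias plus ~1.3% Monte Carlo scatter
  for the RR C95, so that single cell sits at the power limit of the
  check: at the committed seed it misses by 0.14 percentage points, and
  across other seeds roughly half the realizations land just inside or
  just outside. The check is kept at its stated tolerance rather than
  widened; the remaining gap is sampling scatter at the stated n, not an
  implementation defect (HR passes everywhere with ≤1.4% error).
* Backfitting convergence is declared on relative penalized-deviance
  change ($10^{-6}$); the deviance trace is stored in the model for
  inspection, and a non-converged fit warns rather than fails.
* `select_model()` evaluates a deterministic, data-independent grid; two
  runs on the same data give the same model.

## 9. Interchange formats

Input: `encounters.csv` (encounter_id, age_value, age_unit, sex,
trauma_flag, chronic_dx_flag) and `measurements.csv` (encounter_id,
vital, value, time_offset_min), UTF-8, comma-separated, flags 0/1.
Output: `clean_observations.csv`, `exclusion_log.csv`, tab-separated
reference tables mirroring the published column layout, and a fitted
model as self-describing JSON (family, scale flag, ζ, knots,
coefficients, edf, n, SBC, dither seed). A small command-line driver
(`inst/cli/pedcentiles-cli.R`) wires these together for
simulate / clean / fit / tables / validate runs.
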