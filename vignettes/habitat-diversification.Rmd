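---
title: "Habitat-driven diversification models: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Habitat-driven diversification models: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefdiv)
```

`reefdiv` asks whether a time-dependent environmental variable — here the
fragmentation (patch count) or surface area of tropical shallow-reef
habitat — drove speciation and extinction in clades of reef fishes. This
vignette documents the statistical model, the numerical machinery, the
choices made where the design was genuinely open, and what the synthetic
data used for validation does and does not emulate.

## 1. The reconstructed birth–death process

The data are an ultrametric chronogram (branch lengths in Myr, tips at the
present) and a sampling fraction $f$: the probability, assumed homogeneous
across lineages, that an extant species is included in the tree. Time $t$
runs backwards from the present everywhere in the package.

With speciation rate $\lambda(t)$ and extinction rate $\mu(t)$, let
$r = \lambda - \mu$, $R(t) = \int_0^t r$, and
$J(t) = \int_0^t e^{R(u)}\lambda(u)\,du$. Two standard quantities follow:

$$\Phi(t) = 1 - \frac{e^{R(t)}}{1/f + J(t)}, \qquad
  \Psi(s,t) = e^{R(t)-R(s)}\left[\frac{1/f + J(s)}{1/f + J(t)}\right]^2,$$

$\Phi(t)$ being the probability that a lineage alive at age $t$ leaves no
sampled descendant today, and $\Psi(s,t)$ the density factor contributed
by a reconstructed branch spanning ages $s \le t$. The tree likelihood is

$$L = f^{\,n}\,\prod_{i=1}^{n-1}\lambda(x_i)\;
      \prod_{b}\Psi(s_b,t_b)\; \big/\;
      \lambda(t_c)\,\bigl(1-\Phi(t_c)\bigr)^2 ,$$

with $x_i$ the branching times and $t_c$ the crown age. Because $\Psi$
factorizes over branch endpoints, the branch product telescopes into a
function of branching times only; `tree_loglik()` uses the telescoped
form by default and retains the explicit per-branch product
(`method = "branches"`) as a permanently available cross-check — the two
must agree to numerical precision, and the test suite enforces this.

**Conditioning.** The likelihood is conditioned on the crown age and on
both crown lineages having sampled descendants (the division by
$\lambda(t_c)(1-\Phi(t_c))^2$). Published tools differ in this
convention, and absolute log-likelihoods are not comparable across
conventions; `reefdiv` therefore fixes one convention package-wide, uses
it identically for shift and environmental models so their AICc values
are comparable, and states it in every output header. Consequences: only
model *rankings*, not absolute likelihoods, should be compared against
other software.

## 2. Model families and their parameters

Eight families are available. `M1` is the constant-rate null. The six
environmental families make $\lambda$, $\mu$, or both a linear
($\alpha + \beta v(t)$) or exponential ($\alpha e^{\beta v(t)}$) function
of the environmental curve $v(t)$; mixed linear/exponential combinations
are deliberately not offered. `SHIFT(k)` is piecewise constant with $k$
change points.

Units: rates are events · lineage⁻¹ · Myr⁻¹; $\beta$ carries the inverse
units of $v$ (per patch, or per km²). Defaults that matter:

* **ΔAICc window = 2** — models within 2 units of the best are reported
  as comparably supported.
* **Shift-candidate spacing = 5 Myr**, candidates strictly inside
  $(0, t_c)$; the scan is exhaustive for up to 2 shifts and greedy
  (forward addition) beyond, where the combinatorics explode. Candidate
  sets that leave any inter-shift interval without a branching event are
  skipped — the interval's rates would be unidentifiable.
* **Posterior sample size = 1000** trees by default in
  `load_tree_sample()`; the first 1000 are taken (posterior draws are
  exchangeable), with a seeded random draw as an option.
* **Sampling threshold = 0.5** — clades are flagged (not refused) when
  $f \le 0.5$, since likelihood surfaces degrade with sparser sampling.
* **Rate-through-time grid = 0.1 Myr**, summarized by the median and the
  1st/9th deciles.

**Parameter counts.** AICc needs both $k$ and $n$. The package counts
$n$ = number of branching times ($n_{tips}-1$), the number of events the
likelihood factorizes over. For shift models the estimated change points
are counted as free parameters, $k = 3m + 2$ for $m$ shifts: the scan
profiles over candidate times, so treating them as free is the honest
count. Both conventions are open questions in the literature; outputs
state the one used.

**Constraints.** $\lambda(t) > 0$ and $\mu(t) \ge 0$ are enforced on a
1000-point grid over $[0, t_c]$; a violation (possible for the linear
families) yields $-\infty$ rather than an error so optimizers can walk
the boundary. $\mu = 0$ (pure birth) is admissible; on small trees the
maximum-likelihood $\hat\mu$ may legitimately sit well above 0 even for
pure-birth truth — the "pull of the present" — which is why recovery is
asserted on medians over replicates, never on single trees.

## 3. Habitat metrics

Habitat maps are 0/1 grids on a regular latitude–longitude lattice, one
per time slice. Fragmentation is the number of connected components of
habitat cells. The field definition ("patches surrounded by non-habitat
cells") does not fix the adjacency rule, so both are exposed:
**8-connectivity is the default** (diagonally touching reef cells belong
to one tract) and the **antimeridian wrap is on by default** whenever the
lattice spans 360°, so tracts are not split at the date line. There is no
wrap across the poles. Patch counts are computed as graph components
(`igraph`); an independent hand-written flood fill serves as the test
oracle.

Areas avoid map projection entirely: the area of a cell spanning
latitudes $[\phi_1,\phi_2]$ and longitudes $[\theta_1,\theta_2]$ on a
sphere of radius $R$ = 6371 km is
$R^2(\theta_2-\theta_1)(\sin\phi_2-\sin\phi_1)$ — exactly the area any
cylindrical equal-area (Behrmann) projection preserves, so the analytic
form gives identical results with no projection code. The test suite
checks that all cell areas close the sphere to $10^{-10}$ relative.

$v(t)$ interpolates the per-slice metric values. **Linear interpolation
is the default**: it cannot overshoot, preserves non-negativity, and
introduces no tuning knob. A smoothing-spline option
(`interpolation = "spline"`, with configurable degrees of freedom,
clamped at 0) is provided because upstream paleo-environment tooling
commonly smooths such curves; whether smoothing is appropriate is a
scientific choice left to the user. Outside the knot range $v$ is
extrapolated as a constant — relevant for clades older than the map
stack, and stated here because it flattens any environmental dependence
beyond the oldest map. Missing or non-binary raster cells are coerced to
non-habitat with a logged count (conservative for both metrics).

## 4. Numerical machinery

* **Integrals.** For piecewise-constant rates, $R$ and $J$ accumulate
  analytically per interval ($J$ adds
  $e^{R(a)}\lambda_i(e^{r_i\Delta}-1)/r_i$, with the $r_i\to 0$ limit
  $\lambda_i\Delta$). For environmental rates, composite 7-point
  Gauss–Legendre quadrature on segments cut at every knot of $v(t)$ and
  every evaluation age; integrands are smooth within segments, so the
  rule is effectively exact (the suite cross-checks against an
  independent adaptive ODE solver at $10^{-8}$ and against segment
  refinement). During optimization the quadrature geometry is fixed, so
  $v(t)$ at all nodes is cached once per tree and each likelihood
  evaluation is pure arithmetic.
* **Optimization.** Seeded multi-start Nelder–Mead (default 10 restarts,
  relative tolerance $10^{-8}$): positive parameters on the log scale,
  slopes $\beta$ unconstrained but internally measured against
  $v/\max|v|$ so the simplex sees O(1) coordinates whether $v$ is a
  patch count (~10) or an area (~10⁸ km²). Restart 1 starts from a
  Yule-flavoured guess $\hat\lambda \approx (n-2)/\text{tree length}$;
  later restarts jitter it log-normally. Everything is deterministic
  given the seed.
* **Ties.** Polytomies are resolved with zero-length branches and the
  coincident branching times evaluated as coincident events — no jitter.
  Ultrametricity is enforced to $10^{-4}$ relative to the crown age;
  beyond that the parser fails naming the worst tip rather than fitting
  a non-ultrametric tree.
* **Quantiles.** Rate-through-time deciles use the inclusive
  linear-interpolation convention (`quantile(type = 7)`), chosen because
  it is R's default and exact for the identity checks (identical curves
  give median = deciles).

## 5. What the synthetic data emulates

`simulate_tree()` draws reconstructed trees by forward simulation from
two crown lineages with time-varying hazards, using thinning (rejection
against a global bound on $\lambda + \mu$) — exact, with no time
discretization. Extinct lineages are pruned, tips are retained
independently with probability $f$, and rejection conditions the sample
on ≥ 2 tips with both crown lineages represented, matching the
likelihood's conditioning (a mismatch there would bias every recovery
experiment). The generator stops at a fixed crown age; a target tip
count is honoured by solving $E[n] = 2fe^{R(T)}$ for $T$ — a deliberate
design choice that keeps the simulation exactly crown-conditioned rather
than implementing a separate tip-count-conditioned sampler.

`simulate_habitat_stack()` builds slices containing exactly $k(t)$
disjoint square blobs with ≥ 2-cell sea gaps (also across the date
line), so the true patch count and area are known by construction under
either connectivity.

The reference study conditions used by the test suite and
`scripts/acceptance.R`, chosen once from the branching-process
expectation $E[n] = 2fe^{rT}$:

* constant-rate recovery: $\lambda = 0.2$, $\mu = 0.05$, $f = 0.8$,
  crown age 31 Myr (≈ 200 tips), 50 replicates, medians within 25%;
* shift detection: $\lambda$ drops 0.3 → 0.05 at 10 Ma ($\mu = 0$),
  crown age 20 Myr (≈ 60 tips), 50 replicates;
* selection calibration: 100 trees at crown age 25 Myr under M1
  ($\lambda = 0.18, \mu = 0.05$) and under M2.2 with a strong slope
  ($\alpha = 0.04, \beta = 0.13$ against a fragmentation ramp from 2 to
  20 patches over 31 slices, giving $\lambda$ from ≈ 0.05 to ≈ 0.5);
* end-to-end study: 2 clades × 10 posterior trees on a 20-slice stack,
  run twice and required to be byte-identical.

What this does **not** emulate: real posterior samples correlate
topology and dates across trees (ours are independent draws);
real sampling is taxonomically clumped, not homogeneous; real habitat
maps have ragged, spatially autocorrelated patches rather than clean
blobs; and real environmental curves are measured with error that the
models treat as absent. Passing the recovery tests therefore shows the
estimators work *under the model's own assumptions* — it cannot certify
them against violations of those assumptions.

## 6. Known limitations

* Environmental and shift effects can masquerade as each other on single
  trees; with one realized tree per history, $\lambda$- and
  $\mu$-dependence are only weakly separable (the per-class posterior
  frequencies, not single-tree winners, are the interpretable output).
* Diversity-dependence, trait-dependence, and mass-extinction sampling
  events at shift times are out of scope.
* The environmental models treat $v(t)$ as known and global; regional
  structure in habitat would require per-region curves and trees.
* Absolute log-likelihoods depend on the conditioning convention (§1)
  and are not comparable to tools using another one.
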