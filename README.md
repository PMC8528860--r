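# reefdiv

Did the fragmentation and shrinkage of tropical shallow-reef habitat over
the Cenozoic leave a measurable signal in the diversification of
reef-associated fish clades? `reefdiv` implements the full analysis chain
needed to ask that question from a time-calibrated phylogeny and a stack of
dated paleo-habitat maps, for people working on diversification analyses in
macroevolution: it turns gridded 0/1 habitat maps into fragmentation and
area curves v(t), fits constant-rate, birth–death-shift and
environment-dependent birth–death models to chronograms with incomplete
present-day sampling, selects models by AICc across posterior tree
samples, and summarizes net diversification through time.

## The models

All models describe a reconstructed birth–death process on an ultrametric
tree with n tips, branching times x₁ ≥ … ≥ x₍ₙ₋₁₎ (Myr before present,
t = 0 today), crown age t_c = x₁, and a homogeneous sampling fraction
f ∈ (0, 1] (each extant species appears in the tree with probability f).
With speciation rate λ(t) and extinction rate μ(t), define

    r(t) = λ(t) − μ(t),   R(t) = ∫₀ᵗ r(u) du,   J(t) = ∫₀ᵗ e^{R(u)} λ(u) du

    Φ(t)    = 1 − e^{R(t)} / (1/f + J(t))                (no sampled descendant)
    Ψ(s, t) = e^{R(t) − R(s)} [(1/f + J(s)) / (1/f + J(t))]²   (branch factor)

and the likelihood, conditioned on the crown age and survival of both
crown lineages,

    L = fⁿ · ∏ᵢ λ(xᵢ) · ∏_branches Ψ(s_b, t_b) / [λ(t_c) (1 − Φ(t_c))²].

Because Ψ factorizes over branch endpoints, the branch product telescopes
to a function of the branching times alone; both routes are implemented
and must agree (`tree_loglik(..., method =)`).

Eight model families are supported (`constant_rates()`, `shift_rates()`,
`env_rates()`):

| model | λ | μ |
|-------|---|---|
| M1 | constant | constant |
| M2.1 | α + β v(t) | constant |
| M2.2 | α e^{β v(t)} | constant |
| M3.1 / M3.2 | constant | linear / exponential in v(t) |
| M4.1 / M4.2 | linear / exponential | linear / exponential |
| SHIFT(k) | piecewise constant | piecewise constant |

v(t) is an environmental curve — here the number of habitat patches
(fragmentation) or the total habitat area in km² computed from the map
stack. Patch counts are connected components of habitat cells (8- or
4-connectivity, optionally joined across the date line); areas are exact
spherical cell areas, i.e. what a Behrmann cylindrical equal-area
projection preserves. For piecewise-constant rates the integrals R and J
accumulate analytically; for environmental rates they are evaluated by
composite Gauss–Legendre quadrature split at the knots of v(t).

Model choice uses AICc = −2 logL + 2k + 2k(k+1)/(n−k−1) with n the number
of branching times; models within ΔAICc ≤ 2 of the best are treated as
comparably supported. `shift_scan()` places candidate shift times every
5 Myr and selects the number of shifts by AICc;
`posterior_frequencies()` tabulates how often each model — and each
dependence class (cst / λ / μ / λ,μ) — wins across a posterior tree
sample.

## Worked example

Everything below is synthetic and seeded, so it reproduces exactly.

```r
library(reefdiv)

# a 31-slice habitat stack whose fragmentation ramps from 2 to 20 patches
hab <- simulate_habitat_stack(31, k = round(seq(2, 20, length.out = 31)),
                              seed = 99)
env <- build_env_series(hab$stack, "patch_count")

# a clade whose speciation rate truly tracks fragmentation
# (lambda = 0.04 e^{0.13 v(t)}, mu = 0.02), 90% sampled
tr <- simulate_tree(env_rates("M2.2", c(alpha = 0.04, beta = 0.13, mu = 0.02),
                              env),
                    f = 0.9, crown_age = 25, seed = 7)
tr
#> chronogram: 36 tips, crown age 25 Myr, f = 0.9

fits <- lapply(c("M1", "M2.1", "M2.2", "M3.1", "M3.2", "M4.1", "M4.2"),
               function(m) fit_model(tr, m, env = env, seed = 1))
as.data.frame(select_models(fits))
#>   model_id   logL k  AICc delta_AICc within
#> 1     M2.2 -116.0 3 238.8     0.0000   TRUE
#> 2     M2.1 -116.1 3 239.0     0.1159   TRUE
#> 3     M4.2 -114.8 4 239.0     0.1676   TRUE
#> 4     M3.2 -116.4 3 239.7     0.8253   TRUE
#> 5       M1 -118.2 2 240.8     1.9377   TRUE
#> 6     M4.1 -116.0 4 241.3     2.5000  FALSE
#> 7     M3.1 -118.2 3 243.2     4.3459  FALSE

fits[[3]]
#> bd_fit M2.2: logL = -116.0321, k = 3, AICc = 238.8385
#>   alpha = 0.06458, beta = 0.11717, mu = 0.13116
```

The generating family M2.2 ranks first and the fitted slope (β̂ = 0.117)
sits close to the simulated truth (β = 0.13); on a single 36-tip tree its
margin over rival families is small — which is exactly why the package
reports selection *frequencies* over posterior samples rather than single
winners. A shift scan on the same tree keeps the 0-shift model (ΔAICc of
the best 1-shift model is 0.42), as it should for smoothly varying rates:

```r
shift_scan(tr, seed = 1)$table
#>   m shift_times   logL  k  AICc delta_AICc
#> 1 0             -118.2  2 240.8     0.0000
#> 2 1          20 -114.6  5 241.2     0.4209
#> ...
```

For a full study — environment curves, per-clade shift scans, seven-model
comparisons on consensus + posterior trees, and rate-through-time
summaries — describe the clades and maps in a YAML/list config and call
`run_study()`; see `?run_study` and the vignette in `vignettes/`.

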