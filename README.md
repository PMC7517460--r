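# renyimix

Multiplicative decomposition of Rényi heterogeneity for mixture
distributions — discrete mixtures and Gaussian mixtures on continuous
spaces, under both non-parametric and parametric pooling.

## The problem

A system's heterogeneity can be measured as the exponential of its Rényi
entropy of order *q* — the Hill number of ecology, the Hannah–Kay index of
economics — which expresses diversity as a *numbers equivalent*: the number
of equally likely states (discrete) or the volume of the cube carrying a
uniform density (continuous) with the same index value. For a composite
system, the pooled heterogeneity Π<sub>q</sub><sup>γ</sup> factors
multiplicatively,

Π<sub>q</sub><sup>γ</sup> = Π<sub>q</sub><sup>α</sup> · Π<sub>q</sub><sup>β</sup>,

where α is the effective size *per component* and β = γ/α is the effective
*number of distinct components*. For categorical data this is the classical
Jost partition. `renyimix` extends it to continuous Gaussian mixtures, where
the answer depends on how the pooled system is defined:

* **non-parametric pooling** — the pooled density is the literal finite
  mixture f̄(x) = Σᵢ wᵢ N(x | μᵢ, Σᵢ). γ must be computed numerically
  (adaptive quadrature in 1-D, Monte Carlo in any dimension, or a
  well-separated asymptotic approximation). β is bounded by 1 from below —
  at q = 1 for any weights, at every q > 0 for equal weights — and
  saturates at the component count N once components stop overlapping.
* **parametric pooling** — the pooled distribution is a single Gaussian with
  the mixture's moment-matched mean μ\* = Σ wᵢμᵢ and covariance
  Σ\* = −μ\*μ\*ᵀ + Σ wᵢ(Σᵢ + μᵢμᵢᵀ), as in a Gaussian mixed-effects
  (random-effects meta-analysis) model. Everything is closed-form; β ≥ 1 is
  guaranteed at q = 1 but can fail at q ≠ 1, and β keeps growing with the
  spread of the component means instead of plateauing. This makes β a
  replication-consistent alternative to the between-study variance τ² of
  meta-analysis.

Audience: anyone who needs an effective-number-of-components summary of a
mixture — meta-analysts, ecologists working with continuous trait or
embedding spaces, and machine-learning practitioners measuring the diversity
of latent representations.

## Worked example

```r
library(renyimix)

# two univariate Gaussian components, sd 0.5, means 6 apart
mix <- gaussian_mixture_1d(c(0, 6), sds = 0.5)
nonparametric_decompose(mix, q = 1)
#> Renyi heterogeneity decomposition (q = 1, nonparametric pooling, quadrature)
#>   gamma = 4.13273
#>   alpha = 2.06637
#>   beta  = 2
#>   gamma error estimate: 3.77e-08

parametric_decompose(mix, q = 1)
#> Renyi heterogeneity decomposition (q = 1, parametric pooling, closed_form)
#>   gamma = 12.5692
#>   alpha = 2.06637
#>   beta  = 6.08276
```

Each component on its own has effective volume ≈ 2.07 (an sd-0.5 Gaussian at
q = 1 occupies as much event space as a uniform on an interval of length
√(2πe)·0.5), so α ≈ 2.07. Under non-parametric pooling the mixture covers
two such disjoint volumes: γ ≈ 4.13 and β ≈ 2 — two effectively distinct
components. Under parametric pooling the single moment-matched Gaussian must
also span the empty region between the components, so γ (and hence β)
is much larger and would keep growing if the means were pulled further
apart.

A command-line front end wraps the same functions:

```sh
inst/cli/renyimix decompose --mixture mix.json --q 1
inst/cli/renyimix reproduce separation --out separation.csv
```

where `mix.json` is, e.g., the shipped
[`inst/extdata/two_component_mixture.json`](inst/extdata/two_component_mixture.json):
`{"type":"gaussian","components":[{"weight":0.5,"mean":0,"sd":0.5},{"weight":0.5,"mean":6,"sd":0.5}]}`.

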