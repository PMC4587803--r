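# micca

Parameter similarity and identifiability analysis for ODE models of
biochemical dynamics, via canonical correlations of sensitivity subspaces.

## The problem

Systems-biology models carry many kinetic parameters but are observed
through few species at few time points. A parameter can be impossible to
estimate for two reasons: the observations are insensitive to it, or
changes in it can be *compensated* by coordinated changes in other
parameters. Pairwise correlations miss group-level compensation — three
parameters with low pairwise correlations can be jointly non-identifiable.
micca is for modellers who want to know, **before** collecting data, which
parameters a set of experiments can pin down, which parameter groups
compensate each other, and which new perturbation would help.

## The method

For a model *dy/dt = F(y, θ)* and experiments observing components
*y⁽q⁾* at times *t₁ < … < tₙ*, the sensitivity vector of *θᵢ* is
*Sᵢ = (zᵢ⁽q⁾(t₁), …, zᵢ⁽q⁾(tₙ))* with *zᵢ = ∂y/∂θᵢ*, computed by the
forward sensitivity ODE and stacked across experiments into the
sensitivity matrix *S* (Fisher information *FI(θ) = SᵀS* under
unit-variance Gaussian error). Similarity between parameter groups
*θ_A*, *θ_B* is measured by the canonical correlations
*1 ≥ ρ₁ ≥ … ≥ ρ_m ≥ 0* (cosines of principal angles between the spanned
subspaces, *m = min(|A|, |B|)*), summarised as the asymptotic mutual
information between the estimator blocks:

    I(θ_A, θ_B) = −(1/m) Σᵢ log(1 − ρᵢ²)      [nats]

A parameter is **(δ, ζ)-identifiable** when ρ(θᵢ, θ₋ᵢ) < δ and ‖Sᵢ‖ > ζ.
With log-parametrisation (the default), ζ = 1 demands better than an
order-of-magnitude estimate and δ = 0.95 allows at most a ~10-fold
variance inflation (1/(1−δ²) ≈ 10.26). A modified agglomerative
clustering merges the most mutually informative parameter groups,
verifies the δ-condition inside each new cluster, prunes the
most-compensated members, and returns a dendrogram (Newick/JSON) plus the
identifiable set. An experiment screen ranks candidate perturbations by
the number of parameters they render identifiable.

## Worked example

The bundled two-state gene expression model (mRNA `r` produced at rate
`kr`, degraded at `gr`; protein `p` translated at `kp`, degraded at `gp`)
observed once at steady state:

```r
library(micca)
fx <- geneExpressionFixture()
S <- buildSensitivityMatrix(fx$model, fx$experiments["steady_state"])
deltaZetaTest(S, delta = 0.95, zeta = 1)
#> (delta, zeta)-identifiability at delta=0.95, zeta=1: 0 of 4 identifiable
#>  parameter sensitivity_norm fim_diag rho_rest zeta_pass delta_pass identifiable
#>         kr            1.740    3.028        1      TRUE      FALSE        FALSE
#>         kp            1.667    2.778        1      TRUE      FALSE        FALSE
#>         gr            1.740    3.028        1      TRUE      FALSE        FALSE
#>         gp            1.667    2.778        1      TRUE      FALSE        FALSE
```

Every parameter is *sensitive* (ζ-pass) yet none is identifiable: the
steady state `(kr/gr, kr·kp/(gr·gp))` constrains only rate ratios, so each
parameter is perfectly compensated by the rest (ρ = 1). Clustering shows
by whom:

```r
clusterParameters(S, delta = 0.95, zeta = 1)
#> ClusterTree over 4 parameter(s) (delta=0.95, zeta=1)
#>  step  left right    height removed
#>     1    kp    gp 0.000e+00      gp
#>     2    kr    gr 2.220e-16      gr
#>     3 kp,gp kr,gr 8.257e-02      kp
```

The compensative pairs `{kp, gp}` and `{kr, gr}` merge at (numerically)
zero height — within each pair a perturbation of one rate is exactly
undone by the other — while the two pairs join at positive height 0.083:
similar, but not fully interchangeable (ρ₁ = 0.958 between the pair
subspaces, MI = 1.25 nats). Screening a relaxation experiment (both
concentrations pushed above steady state, transient sampled) against this
baseline:

```r
screenExperiments(fx$model, fx$experiments["steady_state"],
                  list(fx$experiments$decay))
#> Experiment screen: base design has 0 identifiable parameter(s)
#>  candidate  name n_identifiable gain rank
#>          1 decay              4    4    1
```

The decay experiment breaks the ratio compensations and makes all four
parameters identifiable. The same workflow runs on models declared in a
YAML config (`inst/extdata/gene_expression.yaml`; schema stub for the full
NF-κB pathway model in `inst/extdata/nfkb_stub.yaml`) and from the shell
via `inst/scripts/micca` (subcommands `cluster`, `identifiability`,
`similarity`, `screen`, `simulate`).

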