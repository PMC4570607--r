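# splicemix

Model-based clustering of tissues by the relative abundance of
co-expressed mRNA splice variants.

## The problem

A single gene can produce several alternatively spliced mRNA isoforms, and
different tissues splice them in different proportions. The motivating
application is the human IGF-1 gene, whose 3'-splicing generates the Ea,
Eb and Ec variants: given quantitative real-time PCR (qPCR) measurements
of the three isoforms across a panel of tissues — with two or three
technical replicates per tissue — which tissues share the same splicing
profile? Simple pairwise comparisons of expression levels do not give a
formal clustering; `splicemix` provides one through finite mixture
models.

The data are first *equalized*: each isoform quantity (obtained from raw
threshold cycles by the comparative CT method, 2^-ΔΔCT) is divided by the
summed quantity of all isoforms in the same sample, giving compositional
ratios that satisfy the unit constraint Ratio1 + Ratio2 + Ratio3 = 1.
Because of that constraint only the couple (Ratio1, Ratio2) = (Ea, Eb) is
modelled.

## The models

**FMM — finite mixture of bivariate Gaussians.** Pooling all
tissue-replicate units as independent observations x_ir, the marginal
density is

    f(x) = Σ_g π_g N(x | μ_g, Σ_g),   g = 1..G,

fitted by EM (posterior weights w_irg in the E step, weighted moments in
the M step) after a short classification-EM (CEM) initialization. The
component covariances can be constrained through the eigenvalue
decomposition Σ_g = λ_g D_g A_g D_g' into scale, shape and orientation;
the families EII, VII, EEE, VVV and EEV (equal scale, equal shape,
variable orientation) are available. G and the family are chosen by
minimizing BIC = -2 logL + k log n. Units are allocated by maximum a
posteriori (MAP), with uncertainty measured by the normalized Shannon
entropy -Σ_g w_g log w_g / log G ∈ [0, 1].

**FMLMM — finite mixture of linear mixed models.** Technical replicates
of one tissue are not independent. Stacking a tissue's R replicates of
the two ratios into a 2R-vector x_i, component g specifies

    x_i = V (α_g + u_ig) + e_ig,
    u_ig ~ MVN(0, Φ_g),   e_ig ~ MVN(0, Ω_g),   Ω_g = diag(V σ²_g),

where V = [[1_R, 0_R], [0_R, 1_R]] is the replicate design matrix, α_g
the component-level means, u_ig a tissue-level random effect shared by
all replicates (Φ_g non-diagonal, so the two ratios of a tissue may be
correlated) and σ²_g per-variant measurement error variances. All
replicates of a tissue then share one mixture component, and the marginal
component covariance is V Φ_g V' + Ω_g. The model is fitted by EM over
tissues, with BIC on the number of tissues; random effects are predicted
by their posterior means (BLUP-type estimators).

A synthetic-data module generates panels with exactly this structure, so
the whole pipeline is testable without access to raw tissue data;
`igf1FmmParams()` and `igf1FmlmmParams()` ship the component estimates
published for a 20-tissue human IGF-1 panel as realistic generators.

## Worked example

Simulate a 20-tissue triplicate panel from the published FMLMM estimates,
explore it, and cluster it with both models:

```r
library(splicemix)

sim <- simulateFmlmmPanel(igf1FmlmmParams(), nTissues = 20,
                          nReplicates = 3, seed = 1)
sim$panel
#> TissuePanel: 20 tissues, 60 units, ratio values
#>   isoforms: Ea, Eb, Ec
#>   replicates per tissue: 3 x 20

round(summaryStats(panelValues(sim$panel)["Ea", ]), 4)
#>    min     q1 median   mean     q3    max
#> 0.6276 0.7931 0.8277 0.8189 0.8677 0.9397

d <- kdeEvaluate(panelValues(sim$panel)["Ea", ], h = "silverman")
countModes(d)
#> [1] 2        # the Ea ratio is multimodal: subpopulations exist

sel <- fmmSelect(ratioPoints(sim$panel), Gs = 1:6, families = "EEV", seed = 2)
selectionTable(sel)
#>   G family   loglik df       bic
#> 1 1    EEV 206.7226  5 -392.9734
#> 2 2    EEV 227.8218  9 -418.7945
#> 3 3    EEV 235.2615 13 -417.2966
#> ...

fl <- fmlmmSelect(sim$panel, Gs = c(2, 3), seed = 3)
fl
#> FmlmmFit: G = 3, n = 20 tissues
#>   marginal loglik = 301.8015, BIC = -534.7012 (501 EM iterations)
#>   pi: 0.4873, 0.3628, 0.15
round(componentMeans(fl), 4)
#>        [,1]   [,2]   [,3]
#> [1,] 0.8629 0.8224 0.6696
#> [2,] 0.1285 0.1453 0.3099
```

The FMLMM recovers the generating structure: a component with a
distinctly lower Ratio1 mean (0.6696, near the generating 0.6742) and two
overlapping high-Ratio1 components. At this small sample size the pooled
FMM prefers the more parsimonious G = 2 (BIC -418.8 vs -417.3): the two
overlapping components are hard to resolve from 60 pooled points, which
is exactly why the replicated-panel model and larger simulations are
interesting. Cross-method agreement is summarized by a confusion matrix:

```r
al <- allocationTable(sel)
confusionMatrix(setNames(al$tissues$label, al$tissues$tissue),
                setNames(allocationTable(fl)$units$label, fl@tissue),
                "FMM", "FMLMM")
#> Confusion matrix: FMM (rows) vs FMLMM (columns)
#>      FMLMM
#> FMM    1  2  3 Sum
#>   1   10  7  0  17
#>   2    0  0  3   3
#>   Sum 10  7  3  20
```

`runPipeline()` executes the full chain (simulate/load → equalize → KDE →
FMM → FMLMM → compare) and writes every table as CSV plus a run log.

## Package layout

- `R/` — S4 classes (`TissuePanel` extending SummarizedExperiment,
  parameter and fit classes), preprocessing, KDE, FMM, FMLMM, reporting.
- `tests/testthat/` — unit, property and end-to-end recovery tests.
- `vignettes/splicemix-methods.Rmd` — the methods vignette: model
  assumptions, estimation details, numerical choices and limitations.
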