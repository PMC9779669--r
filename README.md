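# tfnoise

Tools for studying **gene expression noise** — the cell-to-cell variability
in expression among genetically identical cells — and the role the
**transcription-factor (TF) binding process** plays in generating it.

The package is aimed at systems/regulatory genomics analysts who want to

* quantify noise from single-cell expression matrices in a
  mean-independent way,
* engineer the promoter- and TF-level features (binding sites, site
  overlaps, positional counts, nucleosome occupancy, tAI) that predict
  noise,
* measure each feature's explanatory and predictive power with a
  repeated train/test regression protocol, and
* model mechanistically how independent, cooperative and competitive TF
  binding shape noise with a stochastic two-state promoter simulator and a
  parameter-space sampler.

## The models at the core

**Mean-adjusted noise.** For gene *g*, CV<sub>g</sub> = sd<sub>g</sub>/mean<sub>g</sub>
across cells. Because CV falls with abundance, a polynomial trend
*f*(log mean) is fitted by least squares (order selected by 10-fold CV over
orders 1–7) and the noise statistic is the vertical residual

> adjusted noise<sub>g</sub> = CV<sub>g</sub> − *f*(log mean<sub>g</sub>).

Genes are stratified into 20 noise bins with equally spaced interior edges
and open-ended end bins.

**Regression protocol.** With standardized features, noise is modelled as
Noise = β₀ + β₁·feature₁ + … + βₙ·featureₙ + ε on a random 80% training
split (training R² = *fraction of variation explained*), then evaluated on
the held-out 20% as *predicted R²* = 1 − SSE/SST; both are averaged over
repeated splits (1000 at full scale). Feature sets come from lasso/ridge
selection refined by bidirectional stepwise AIC.

**Telegraph simulator.** A promoter switches off→on with rate λ_on and
on→off with rate λ_off (exponential waiting times); while on, transcription
runs at β_m, translation at β_p, and removal at α_m, α_p:

```
M[t+dt] = M[t] + (β_m − α_m·M[t])·dt      (β_m present only while active)
P[t+dt] = P[t] + (β_p·M[t] − α_p·P[t])·dt
```

Scenarios: a single TF; *k* independent TFs (active if ≥ 1 bound, rates
add); cooperative TFs (all-or-none: all *k* must be bound; λ_off is
recalibrated to match the single-TF mean, since cooperativity otherwise
drives the mean down); competitive TFs sharing one site (one TF chosen
uniformly at each activation, with unequal strengths 1.3/0.7 by default).
Noise is the CV of protein levels pooled across cells and time points;
burst frequency is the fraction of time active. A greedy "MCMC-style"
sampler explores the rate space toward a target mean-expression window and
compares scenario noise at matched means.

## Worked example

Noise quantification on a synthetic single-cell matrix with a planted
order-5 CV trend (5000 genes × 127 cells):

```r
library(tfnoise)
se    <- simExpressionMatrix(seed = 1)        # counts + ground truth
rec   <- computeCV(se)
trend <- fitNoiseTrend(rec, seed = 1)
trend
#> TrendFit: polynomial order 5 (selected by 1se rule)
#>   CV MSE per order: 1=0.01561  2=0.01502  3=0.01487  4=0.01487  5=0.0144  6=0.01439  7=0.01437
rec     <- adjustedNoise(rec, trend)
rec$bin <- binByNoise(rec$adjustedNoise)
head(rec[, c("gene", "mean", "cv", "adjustedNoise", "bin")], 3)
#>       gene     mean        cv adjustedNoise bin
#> 1 gene0001 12.33071 0.8675829    0.09291029  10
#> 2 gene0002 19.18898 0.6587523   -0.03101719   6
#> 3 gene0003 32.83465 0.5762319   -0.08144897   4
```

The selected order is the planted one, and each gene's adjusted noise is
its CV excess over same-abundance genes (gene0001 is noisier than its
abundance predicts; bins 1 and 20 hold the extremes).

Scenario comparison at matched mean protein levels (1000 cells each):

```r
base <- simParams("single", nCells = 1000, seed = 2024)
compareScenarios(base, matched = TRUE, seed = 2024)
#>      scenario meanProtein proteinCV        cvSE burstFrequency
#> 1      single    12535.40 0.2124337 0.002416222      0.5031601
#> 2 independent    24963.44 0.1552357 0.002065843      0.7515902
#> 3 cooperative    12550.68 0.2498154 0.004329894      0.5053232
#> 4 competitive    12568.17 0.2550012 0.002943517      0.5053534
```

Two independent TFs keep the gene on more of the time and *reduce* noise
relative to a single TF (CV 0.155 vs 0.212), while cooperative and
competitive binding *increase* it (0.250 and 0.255) at the same mean — the
mechanistic signature that more regulators per se do not make a gene noisy,
but coupled binding dynamics do.

A thin command-line wrapper over the same functions is installed at
`system.file("scripts", "tfnoise.R", package = "tfnoise")` with
subcommands `synth-expression`, `synth-promoters`, `synth-features`,
`noise`, `scan`, `simulate`, `regress`; every subcommand is deterministic
under `--seed`.

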