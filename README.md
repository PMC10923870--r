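# allokin

Kinetic, binding and ensemble-network analysis of multi-level allosteric
regulation in NADPH-dependent aldo-keto reductases.

## The problem

Oligomeric aldo-keto reductases can be regulated on three levels at once:

1. **Concerted (MWC) cofactor activation.** The tetrameric allosteric unit
   populates two symmetric pre-existing states — dormant (T) and active
   (R) — with equilibrium constant *L*₀ = [T]/[R]; NADPH binds the R state
   preferentially and pulls the whole unit active, producing positive
   cooperativity at micromolar cofactor.
2. **Cofactor inhibition.** At sub-millimolar NADPH a second cofactor
   molecule occupies the substrate pocket as a dead-end inhibitor, so the
   rate law is substrate inhibition,
   *v* = *V*max / (1 + *K*m/[S] + [S]/*K*ᵢ), rather than
   Michaelis–Menten.
3. **Remote substrate activation.** A second substrate molecule bound ~15 Å
   from the active site acts as a positive allosteric modulator, giving
   sigmoidal Hill kinetics (*v* = *V*max[S]ⁿ/(*K*₀.₅ⁿ+[S]ⁿ), *n* > 1) that
   is transmitted through loop dynamics rather than a large conformational
   change.

The package provides, for anyone analysing such systems:

* every rate law, exponential transient, quench isotherm,
  conformational-selection/induced-fit relaxation model, the MWC
  saturation function and the dormant/active/cofactor/inhibitor
  ("three-step") scheme, as plain evaluable functions;
* `kin_fit()` — bounded multi-start nonlinear least squares returning a
  classed fit with `print`/`summary`/`coef`/`predict`/`plot`/`simulate`/
  `residuals` methods — plus AICc model comparison (`compare_models()`),
  case-resampling bootstrap intervals (`bootstrap_ci()`) and a
  reproducible cooperativity call (`classify_cooperativity()`);
* structural measurements: PDB/mmCIF ingestion, named-group distances,
  Shrake–Rupley pocket SASA;
* the allosteric-network workflow on coordinate ensembles: superposition,
  PCA, loop-RMSD state clustering, contact-persistence residue graphs
  (below 8 Å in ≥ 75% of frames), motion-covariance edge lengths
  *d*ᵢⱼ = −ln *c*ᵢⱼ, and Dijkstra shortest pathways;
* seeded synthetic-data generators (kinetic datasets, planted-correlation
  Gaussian ensembles, equilibrium endpoints) so every stage is testable
  without raw experimental data.

## Worked example

Fit the substrate kinetics of a synthetic triplicate assay generated at
the published wild-type constants (*V*max = 4.65 s⁻¹, *K*₀.₅ = 278 µM,
*n* = 1.76) with 3% relative noise:

```r
library(allokin)
ref <- akr_reference_params()
g <- gen_kinetic_dataset("hill", ref$tylosin_hill,
                         c(50, 100, 200, 300, 450, 650, 900, 1250, 1650,
                           2050, 2500),
                         noise_sd = 0.03, replicates = 3, seed = 42)
fit <- kin_fit(g$data, model = "hill", weights = "inv_y2")
summary(fit)
#> Model 'hill' fit (33 observations)
#>   vmax =   4.6494 (se 0.0533)
#>   k_half = 278.8700 (se 6.1000)
#>   n_hill =   1.7416 (se 0.0231)
#>   R-squared = 0.9982, AICc = -211.16
#>   residual sigma = 0.1345
#>   cooperativity: positive
compare_models(fit, kin_fit(g$data, model = "michaelis", weights = "inv_y2"))
#> Model comparison (preferred: hill )
#>    model_id r_squared     aicc delta_aicc
#> 1      hill   0.99822 -211.159       0.00
#> 2 michaelis   0.91288  -85.287     125.87
```

The fitted Hill coefficient (1.74 ± 0.02) recovers the generative value
1.76, is classified as positive cooperativity (more than two standard
errors above 1), and the Hill model is decisively preferred over the
hyperbola (ΔAICc ≈ 126).

The network workflow, end to end on a synthetic ensemble with a planted
high-correlation chain A1…A6:

```r
ge <- gen_ensemble(30, 2000, planted_chain = 1:6, chain_rho = 0.9,
                   background_rho = 0.05, seed = 42)
rep <- run_network(list(ensemble = ge$ensemble, source = "A1",
                        target = "A6", seed = 42))
rep$results$path
#> Pathway (total length 1.2241):
#>   A1 -> A2 -> A3 -> A4 -> A5 -> A6
```

The shortest −ln-covariance path recovers exactly the planted chain
against the weakly correlated background.

## Command line

A thin wrapper over the pipeline stages is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/akr-pipeline.R", package="allokin"))')" \
    kinetics --config config.yaml --out outdir
```

Exit codes: 0 success, 2 input error, 3 numerical failure.
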