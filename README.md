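# EnsembleMetrics

Scoring and diagnostics for protein conformational ensembles in R.

Generative ensemble models (diffusion samplers, flow models, coarse-grained
surrogates) emit stacks of 3D structures that have to be judged against
reference molecular-dynamics sampling. EnsembleMetrics implements the
standard evaluation battery for that job, plus the thermal-stability
machinery needed to turn foldedness-versus-temperature series into apparent
melting temperatures, plus seeded synthetic-ensemble generators so that
every score is testable offline with known ground truth.

## What it computes

| Quantity | Function | Definition |
|---|---|---|
| Side-chain torsion divergence | `chiJsd()` | mean Jensen–Shannon divergence between 9-bin torus histograms of consecutive χ-angle pairs; 0 = identical, ln 2 ≈ 0.693 = disjoint |
| Secondary-structure preservation | `ssep()` | ensemble-mean fraction of natively H/E residues (hydrogen-bond-based 3-state assignment) retaining their native state |
| Fraction of native contacts | `qFraction()` | Q = mean of 1/(1 + exp(β(d − λd⁰))) over native contacts (d⁰ ≤ 10 Å, \|i−j\| ≥ 3), β = 5 Å⁻¹, λ = 1.2 |
| Folded-state fraction | `foldedStateFraction()` | fraction of frames with Q > 0.6 |
| Melting temperature | `fitSigmoid()`, `meltingTemperature()` | least-squares fit of f(T) = y_min + (y_max − y_min)/(1 + exp(−(T − T̂m)/k̂)) with asymptotes fixed to the series extremes |
| Cα fluctuations | `rmsfProfile()`, `rmsfPcc()`, `initRmsd()` | RMSF after Kabsch superposition onto the initial structure; Pearson correlation of profiles; per-frame Cα RMSD |
| Compactness / contacts | `radiusOfGyration()`, `contactMap()` | heavy-atom Rg; Cα contact frequencies at 9 Å |
| Landscapes | `fitLandscape()`, `projectLandscape()`, `freeEnergyGrid()` | PCA on non-adjacent Cα–Cα distances; G = −RT ln P on a 50×50 grid |
| Integrity | `countHeavyClashes()`, `countPeptideViolations()`, `integrityReport()` | clashes: d < ½(rᵢ+rⱼ) between non-adjacent residues; violations: \|b − 1.348\|/0.029 ≥ 3 |
| Clash relaxation | `relaxEnsemble()` | restrained minimization removing clashes while tethering φ/ψ/χ and adjacent Cα–Cα distances to their input values |

Synthetic generators: `buildIdealChain()` (ideal-geometry chains from
torsions, exact inverse of `computeTorsions()`), `twoStateEnsemble()`
(logistic folded probability in temperature), `rotamerEnsemble()`
(categorical rotamer-bin sampling), `gaussianNoiseEnsemble()`,
`injectDefects()` (verified clash/bond-stretch injection with manifests).

## Worked example

```r
library(EnsembleMetrics)

native    <- buildIdealChain("AEKLFDAQSMIRAEKL", preset = "helix")
reference <- torsionJitterEnsemble(native, sigma = 6, nFrames = 100, seed = 11)
proposed  <- torsionJitterEnsemble(native, sigma = 9, nFrames = 100, seed = 22)

compareEnsembles(reference, proposed, getFrame(native, 1))
#> MetricReport
#>   scalars:
#>     rmsf_pcc         0.96281
#>     chijsd           0
#>     ssep             0.99071
#>     fsf              1
#>     mean_init_rmsd   1.1401
#>     mean_rg          7.833
#>     mean_clashes     0.5
#>     mean_violations  0
```

Reading the numbers: both ensembles jitter around the same native, so their
RMSF profiles correlate strongly (0.96) and the proposed ensemble stays
folded (FSF 1, SSEP 0.99). chiJSD is exactly 0 because ±9° of χ jitter never
leaves the 120°-wide rotamer bins — the histograms coincide. The proposed
ensemble averages 0.5 heavy clashes per snapshot (larger jitter occasionally
collides side chains) and no peptide-bond violations (the builder constructs
C–N bonds at the reference length).

A melting-temperature workflow on the two-state fixture (true Tm = 400 K):

```r
temps <- seq(330, 470, by = 20)
sweep <- lapply(seq_along(temps), function(i)
  twoStateEnsemble(native, temps[i], trueTm = 400, trueK = 20,
                   nFrames = 100, seed = 100 + i))
fits <- meltingTemperature(sweep, getFrame(native, 1), "both")
fits$fsf
#> MeltFit: Tm = 397.95 K, k = -18.23 K, y in [0.050, 0.980], rss = 0.0026 (converged)
fits$ssep
#> MeltFit: Tm = 398.01 K, k = -18.21 K, y in [0.054, 0.980], rss = 0.00296 (converged)
fits$tmDifference
#> [1] -0.06
```

Both observables recover the generator's melting temperature within ~2 K
(the fitted k is negative because foldedness decreases with temperature),
and they agree with each other to 0.06 K.

## Command line

A thin CLI over the same functions ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ensemblemetrics.R", package = "EnsembleMetrics"))')
Rscript $CLI synth --mode two_state --sequence AEKLFDAQ --frames 100 \
    --temperature 430 --out gen.pdb --manifest gen.json --seed 7
Rscript $CLI compare --ref ref.pdb --gen gen.pdb --out report.json
Rscript $CLI melt --manifest series.txt --native native.pdb --out fit.json
Rscript $CLI relax --in clashy.pdb --out relaxed.pdb --diagnostics diag.tsv
```

`series.txt` lists one ensemble per line: `<path> <temperature-in-K>`.

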