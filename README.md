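# fieldQSAR

CoMFA-style 3D-QSAR modelling of a 126-member combinatorial library of
6,N²-diaryl-1,3,5-triazine-2,4-diamines screened against breast cancer cell
lines, for medicinal chemists and cheminformaticians who want a fully
scripted, open re-implementation of the field-based model behind the
series' structure–activity analysis.

## What it computes

All members share one rigid scaffold (aromatic triazine + exocyclic NH₂ +
anilino NH–aryl (R²) + C-aryl (R¹)) and differ only in the R¹/R² ring
substituents, so the series supports comparative molecular field analysis:

1. **Library enumeration** — compounds 1–126 assembled from the packaged
   R¹/R² substituent table, with canonical SMILES, Hill formulas and
   elemental compositions as structure oracles.
2. **Activity preparation** — the 10 µM viability screen selects actives
   (≤ 50 % viability on MDA-MB231, plus one explicit override), and GI₅₀
   potencies become the response via pGI₅₀ = 6 − log₁₀(GI₅₀ [µM]).
3. **Conformers and alignment** — one minimum-energy, Gasteiger-charged 3D
   conformer per compound (OpenBabel build + MMFF94 minimization), rigidly
   superposed (Kabsch) on the nine shared scaffold atoms of the most potent
   compound.
4. **Field grids** — on a common 2 Å lattice with 4 Å margin:
   electrostatic energies of a +1 e probe under a distance-dependent
   dielectric, E(p) = Σᵢ 332.06 qᵢ/r²ᵢₚ, and steric 12-6 Lennard-Jones
   energies of a 1.5 Å carbon probe, both truncated at ±30 kcal/mol and
   concatenated 50/50 into the descriptor matrix.
5. **PLS regression** — NIPALS PLS1 on the explicit 19/6 train/test split
   (test = {58, 73, 78, 99, 101, 120}), component count chosen by
   leave-one-out q² (capped at 5); r² (squared Pearson) and RMSE reported
   for training and pooled rows.
6. **Contour maps** — STDEV×COEFF coefficient grids per field,
   80th/20th-percentile favorable/unfavorable regions, exported as Gaussian
   cube or OpenDX files.

A synthetic-data generator with a planted sparse linear field–activity
signal (smoothed, clamped Gaussian fields) validates the regression and
contour stages independently of any structure generation.

## Worked example

```r
library(fieldQSAR)

lib <- buildLibrary()
lib
#> CompoundLibrary with 126 compounds
#>   substituent tokens: 20

head(libraryRecords(lib)[, c("id", "r1", "r2", "formula", "mw")], 3)
#>   id r1      r2   formula       mw
#> 1  1 Ph      Ph  C15H13N5 263.2972
#> 2  2 Ph 2-FC6H4 C15H12FN5 281.2877
#> 3  3 Ph 4-FC6H4 C15H12FN5 281.2877

round(elementalComposition("C15H12FN5"), 2)   # compound 2 oracle
#>     C     F     H     N
#> 64.05  6.75  4.30 24.90

buildQsarDataset(loadPotency())
#> QsarDataset: 25 compounds, MDA-MB231
#>   pGI50 range: 4.82 .. 7.22

run <- runQsarPipeline(qsarConfig())
run$report
#> QsarReport: 25 compounds ( 19 train / 6 test )
#>   training r2 = 0.962, RMSE = 0.121 (5 components)

head(reportTable(run$report), 4)
#>   id experimental predicted    residual split
#> 1 14     5.035740  4.873863  0.16187719 train
#> 2 16     4.881735  4.853910  0.02782572 train
#> 3 17     5.402305  5.609995 -0.20769024 train
#> 4 18     5.209012  5.220899 -0.01188763 train

run$contours[["electrostatic"]]
#> ContourSet ( electrostatic ): 386 favorable / 386 unfavorable points
```

The report rows mirror the study's experimental/predicted table: each
compound's measured pGI₅₀, the model's prediction, their difference and the
split label. The training r² of 0.96 and RMSE of 0.12 clear the reference
analysis's reported 0.81 / 0.31; exact equality is not expected because the
charges, force field, grid and alignment replace unpublished internals of
the commercial protocol (see the methods vignette). Held-out predictions
for the 6 test compounds are in the same table (`split == "test"`).

`runQsarPipeline(config, outdir = "out")` additionally writes the SMILES
list, aligned conformer SDF, dataset/descriptor/report TSVs, model JSON,
contour grids and a manifest with MD5 digests that are identical across
reruns of the same configuration.

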