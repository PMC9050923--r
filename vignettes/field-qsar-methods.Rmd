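---
title: "Methods: CoMFA-style 3D-QSAR of the diaryltriazine library"
author: "fieldQSAR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CoMFA-style 3D-QSAR of the diaryltriazine library}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The modelling problem

The package models the antiproliferative potency of a congeneric series of
6,N2-diaryl-1,3,5-triazine-2,4-diamines against the triple-negative
MDA-MB231 breast cancer cell line. All 126 library members share one rigid
scaffold — an aromatic 1,3,5-triazine carrying an exocyclic NH2, an anilino
NH with an aryl group (R2 ring), and a C-linked aryl group (R1 ring) — and
differ only in the R1/R2 substituents. That makes the series ideal for
comparative molecular field analysis (CoMFA): after aligning all molecules
on the common scaffold, the spatial pattern of steric and electrostatic
probe energies around them can be regressed against potency.

The response variable is pGI50, the negative decadic logarithm of the molar
50%-growth-inhibition concentration. With GI50 in micromolar units,

    pGI50 = 6 - log10(GI50 [uM]).

This convention reproduces every experimental pGI50 in the packaged
reference table to two decimals, which is how it was validated.

# Dataset assembly

Compounds whose 10 uM screen left at most 50% viable MDA-MB231 cells were
selected for GI50 determination. One compound (110, printed viability 51%)
nevertheless appears in the potency table; the package keeps the selection
rule pure (`selectActives()` is a strict threshold filter) and adds 110
through an explicit `includeOverride`, so the default dataset has the same
25 members as the published one. Censored potencies (">20", ">25" uM, on
the other cell lines) are carried with a `censored` flag and refused by the
modelling dataset — they are never imputed.

One row of the packaged experimental/predicted reference table is printed
with the label 71 although its experimental value matches the potency of
compound 81 (which is otherwise absent while 71 never had a measured GI50).
The fixture stores both the printed and the resolved id, and the default
mapping resolves the row to 81.

# Structure building and alignment

Each member is assembled as a SMILES string from a fixed scaffold template
and a hand-built token-to-fragment vocabulary (19 substituents). Fragments
are written ipso-atom-first, so the nine shared scaffold heavy atoms
(triazine ring, both exocyclic nitrogens, the C6-aryl ipso carbon) occupy
computable atom indices — this gives an exact scaffold atom map without a
substructure search, and the mapped elements are verified after every
toolkit round trip.

3D conformers come from OpenBabel's structure builder followed by MMFF94
minimization and a weighted rotor search. This replaces an interactive
"align to the minimum energy" protocol of a commercial suite whose CHARMm
force field and field-consensus alignment are not openly specified. Two
consequences:

* a single deterministic minimum-energy conformer is used per compound
  (the rotor search is itself a multi-start over torsions; the build is
  bit-reproducible on one platform, so the pipeline needs no RNG seed for
  geometry);
* alignment is a rigid Kabsch superposition of the mapped scaffold atoms
  onto a reference compound — the standard congeneric-series practice,
  well-posed because all members share the nine mapped atoms. The default
  reference is compound 101, the most potent member. Observed scaffold
  RMSDs on the built set are below 0.05 A (the test suite enforces a loose
  0.5 A bound).

Partial charges default to Gasteiger-Marsili (an MMFF94 option is exposed);
net molecular charge is checked to vanish within 0.01 e.

# Field grids

A common axis-aligned grid is built over the union bounding box of the
aligned set, padded by a margin and snapped outward to the lattice.
Defaults are the classic CoMFA choices: 2.0 A spacing and 4.0 A margin
(the study the package reproduces states neither). Grid points are ordered
x-fastest; every exporter and reader in the package uses that documented
order.

Electrostatic field: a +1 e point-charge probe under a distance-dependent
dielectric eps(r) = r (the CHARMm-style RDIE convention), so

    E_ele(p) = sum_i 332.06 q_i / r_ip^2   [kcal/mol],

with probe-atom distances floored at 0.05 A; the floor's exact value is
irrelevant because energies are truncated anyway.

Steric field: a Lennard-Jones 12-6 carbon probe of radius 1.5 A and well
depth 0.105 kcal/mol (sp3 carbon), Lorentz-Berthelot-combined with a
packaged UFF-derived per-element parameter table:

    E_ste(p) = sum_i eps_ij [ (R_ij / r_ip)^12 - 2 (R_ij / r_ip)^6 ].

Both fields are clamped to +/- 30 kcal/mol, the truncation of the original
protocol, so near-atom singularities cannot dominate the regression.

The descriptor row of a compound is the concatenation of the two fields
weighted 50/50 (the stated steric/electrostatic weighting is applied at
descriptor assembly; the same sentence in the original protocol could also
be read as an alignment-scoring weight, but scaffold superposition makes
that reading moot). Columns with standard deviation below 1e-6 kcal/mol
across compounds (constants, mostly far-field and deep-core points) are
dropped, with a retained column index for contour back-mapping.

# PLS model

`fitPls()` is a NIPALS PLS1 on column-centered descriptors and centered
response; columns are not variance-scaled because all descriptors share
kcal/mol units (standard CoMFA practice). At full admissible rank the fit
equals the minimum-norm least-squares solution, which the tests verify
against a pseudoinverse oracle.

The component count is not stated in the reference analysis; the package
selects it by leave-one-out q2 (explicit refit loop, `looQ2()`) over 1..5
components, ties toward fewer. The cap of 5 is conventional CoMFA practice
for a 19-compound training set and guards against trivial overfit.

The train/test split defaults to the explicitly published 6-compound test
membership {58, 73, 78, 99, 101, 120}; a seeded greedy-maximin "diverse
molecule" mode exists for fresh datasets.

Reported statistics follow the reference analysis's conventions: r2 is the
squared Pearson correlation between observed and predicted training
values ("correlation coefficient r2"), with the coefficient of
determination reported alongside; RMSE is the root-mean-square residual.
Because the original RMSE recomputed from the printed table rows differs
slightly from the printed summary value, the package reports training and
pooled statistics separately and treats the published r2/RMSE as bounds
(the acceptance script checks r2 >= 0.81 and RMSE <= 0.31 on the training
set), not equalities — charges, force field, grid and alignment are open
stand-ins for the commercial implementation's internals.

# Contour maps

Displayed values are STDEV*COEFF: the regression coefficient of each
retained column times its training-set standard deviation, back-mapped to
its grid point (dropped columns show 0). Raw coefficients would be
dominated by high-variance near-atom columns. Favorable/unfavorable
regions are the points above the 80th / below the 20th percentile of the
nonzero values — percentile thresholds replace the unstated iso-levels of
the original renderings and are exposed in the configuration. Grids export
as Gaussian cube (header in bohr, z-fastest on disk, converted from the
package's x-fastest order) and OpenDX text files; a JSON summary carries
region counts and centroids.

The qualitative reading — an electron-density-favorable region near the
para position of the R1 ring, consistent with the high potency of the
4-dimethylamino compound — is a manual check on the exported grids, not an
automated assertion.

# Synthetic data

`generateSyntheticQsar()` plants a known sparse linear signal in a
descriptor matrix that mimics truncated field grids: per molecule an
i.i.d. Gaussian field on the grid is smoothed with a one-pass 3x3x3 moving
average (so neighbouring columns are correlated, as real fields are),
scaled to 1 kcal/mol standard deviation and clamped at +/- 30. The support
of the planted coefficient vector is a contiguous block in grid space.
Field scale 1 makes the default noise ladder {1.0, 0.3, 0.1} a meaningful
signal-to-noise sweep and matches the order of magnitude of the
informative columns of the real descriptor matrix; the clamp then engages
only in rare tails, as it does on real grids.

What the generator does and does not show: the smoothing plus contiguous
support makes support columns nearly collinear, so no regression method
can attribute the signal to exact columns — top-k recovery overlaps the
support partially and plateaus as noise shrinks (the tests pin the
seed-exact values). Exact coefficient recovery is only identified in the
determined regime (more molecules than descriptors), where the noiseless
held-out R2 exceeds 0.999; with the default 25 molecules and 125
descriptors, noiseless fits are exact on training rows but extrapolation
to held-out rows is necessarily imperfect for full-rank fields. Passing
these tests therefore demonstrates correct regression mechanics under
realistic collinearity, not that contour maps pinpoint causal grid points
on real data.

# Numerical choices and degenerate inputs

* Coulomb constant 332.06 kcal A / (mol e^2); IUPAC atomic masses to >= 4
  significant figures (needed to hit two-decimal elemental targets).
* Distance floor 0.05 A under the Coulomb singularity; truncation makes it
  inert.
* `modelStats()` raises an error on zero-variance inputs (r2 undefined)
  rather than returning NaN; censored potencies and unknown substituent
  tokens are errors, never silent skips; an all-zero coefficient grid
  yields empty contour masks, not an error.
* NIPALS stops early if the residual is numerically exhausted; component
  counts are capped at min(n - 1, p) (n - 2 during leave-one-out).
* Maximin splitting breaks ties by the first index; the only randomness is
  the seeded first pick.

# Problem sizes

The default end-to-end run (126-compound enumeration, 25 conformers,
roughly 1900 grid points, leave-one-out over five component counts) takes
a few seconds on one CPU; the synthetic recovery runs use up to 200
molecules on a 5x5x5 grid. These sizes were chosen to exercise every stage
at the scale of the real study.

# Known limitations

* Gasteiger charges and UFF-derived probe parameters are stand-ins for the
  original CHARMm treatment; absolute field energies differ even though
  the regression surface is comparable (hence bound-style acceptance).
* Single-conformer, rigid-scaffold alignment ignores substituent
  conformational ensembles; torsions stay at their minimized values.
* The model is trained on 19 compounds with thousands of collinear
  descriptors: training statistics are optimistic and external predictive
  power (the 6-compound test set) is weak, as expected at this dataset
  size.
* Only steric and electrostatic probes are implemented; no hydrophobic or
  hydrogen-bond fields, no applicability-domain estimate, no y-scrambling.
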