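Package: fieldQSAR
Title: CoMFA-Style 3D-QSAR Modelling of a Diaryltriazine Anticancer Library
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative molecular field analysis (CoMFA-style
    3D-QSAR) of a congeneric series of 6,N2-diaryl-1,3,5-triazine-2,4-diamines
    screened against breast cancer cell lines. Enumerates the 126-member
    combinatorial library from its R1/R2 substituent table, prepares pGI50
    responses from GI50 potencies, builds minimum-energy Gasteiger-charged 3D
    conformers aligned on the shared triazine scaffold, samples steric
    (Lennard-Jones carbon probe) and electrostatic (+1e probe,
    distance-dependent dielectric) interaction energies on a rectangular grid,
    fits partial least squares models with leave-one-out component selection,
    and extracts STDEV*COEFF contour regions exportable as Gaussian cube or
    OpenDX grids. Includes a synthetic descriptor/activity generator with a
    planted sparse linear signal for validating the regression stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    ChemmineOB,
    ChemmineR,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    MASS
Config/testthat/edition: 3
biocViews: Cheminformatics, StructuralPrediction, Regression
RoxygenNote: 7.3.3
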