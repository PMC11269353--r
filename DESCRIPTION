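Package: stdbind
Title: STD-NMR Build-Up Fitting, Epitope Mapping and Plasma Protein Binding Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis chain for characterizing small-molecule binding to
    human serum albumin by ligand-observed NMR and equilibrium separation
    methods. Fits saturation transfer difference (STD) build-up curves to a
    mono-exponential saturation model, derives initial growth rates (STD0)
    and normalized epitope-binding maps, assigns Sudlow binding sites from
    competition-probe attenuation of STD0, classifies WaterLOGSY responses,
    computes protein-binding degrees from equilibrium dialysis or
    ultrafiltration concentrations, solves 1:1 and competitive two-site
    binding equilibria, and interconverts binding free energies and
    dissociation constants. Includes a synthetic-data generator with
    embedded ground truth for validating the full chain.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
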