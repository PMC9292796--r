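Package: qmorsa
Title: Radical-Scavenging Kinetics from Quantum-Chemical Free Energies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Post-processing pipeline for computed antioxidant kinetics:
    converts per-channel Gibbs free energies of activation and reaction
    (hydrogen atom transfer, radical adduct formation, single electron
    transfer, and direct chalcogen oxidation) into thermal rate constants
    via transition state theory with Wigner tunneling and Marcus electron
    transfer barriers, applies standard-state and solvent-cage corrections,
    caps rates by Smoluchowski/Stokes-Einstein diffusion through
    Collins-Kimball coupling, and aggregates channels into mechanism-level
    apparent rate constants, branching ratios, and overall scavenging
    activity. Ships a curated free-energy dataset for the phenothiazine,
    phenoselenazine and phenotellurazine scaffolds reacting with HO., HOO.
    and CH3OO. radicals in aqueous and lipid media, together with a
    reproduction harness and a seeded synthetic channel generator.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
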