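Package: dfmol
Title: Discrete Flow Matching for 3D De Novo Molecule Generation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Benchmarking machinery for discrete flow matching (DFM) on 3D
    molecules. Implements four interchangeable categorical flow formulations
    (fully continuous flows from a Gaussian prior, SimplexFlow linear
    interpolants on the probability simplex, Dirichlet flows, and
    continuous-time Markov chain mask flows) together with a Euclidean
    coordinate flow, a small CPU-trainable denoiser, Euler/jump samplers,
    a molecule-quality metric suite (valency-based stability, RDKit
    sanitization validity, MMFF energy Jensen-Shannon divergence,
    SMARTS structural-alert rates, out-of-distribution ring-system rates),
    and atom-type assignment-time diagnostics. Ships a deterministic
    synthetic toy-molecule generator so all variants can be trained,
    sampled, and ranked on a desktop CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: Python (>= 3.8) with RDKit, available as 'python' on
    the PATH (used for sanitization validity, MMFF94 energies, SMARTS
    matching and canonical ring-system keys)
RoxygenNote: 7.3.3
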