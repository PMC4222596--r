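Package: contactstack
Title: Stacked Random-Forest Refinement of Protein Residue Contact Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Residue-residue contact predictions from coevolution-based
    methods are noisy and treat residue pairs independently, although true
    contacts cluster into secondary-structure patterns (beta-sheet ladders,
    helix packing stripes). contactstack implements a multi-layer stack of
    random-forest learners in which every layer re-predicts each residue
    pair from the ordinary pair features (base prediction maps, sequence
    separation, sequence profile, predicted secondary structure and surface
    accessibility) concatenated with a square receptive field of the
    previous layer's predicted contact probabilities around the pair. The
    package includes contact-map extraction from PDB structures under the
    CASP contact definition, alignment statistics (effective sequence
    counts, profiles), mutual-information baselines with average product
    correction, top-L positive-predictive-value evaluation with separation
    and secondary-structure breakdowns, and a synthetic protein-family
    generator so the full pipeline runs end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
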