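Package: gnncv
Title: Graph Neural Network Approximators for Nucleation Collective Variables
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building, training and deploying graph-based
    approximators of nucleation collective variables (CVs). Implements the
    analytical reference CVs they learn (a smooth coordination-number count
    n and the sixth-order-Steinhardt crystalline-particle count n(Q6)) with
    exact gradients, periodic-boundary neighbor-list graph construction, a
    permutation-invariant message-passing model with hand-coded reverse-mode
    gradients, dataset construction with roto-translational and permutational
    augmentation, and a desk-scale Lennard-Jones Langevin simulator with
    pulling, umbrella sampling plus WHAM, and well-tempered metadynamics
    driven by either analytical or learned CVs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
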