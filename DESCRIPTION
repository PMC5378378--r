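Package: neurolandscape
Title: Landscape View of Multi-Channel Neural Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: State-space analysis of multi-channel binary neural activity:
    density-based clustering of +/-1 state-space time series with a modified
    mean-shift algorithm (adaptive flat-kernel radius, sign-of-mean updates,
    mass-weighted refinement), Hopfield network Monte Carlo and basin-of-
    attraction diagnostics, inverse-Ising coupling inference by Minimum
    Probability Flow in both the full pairwise and a centroid-reduced
    parametrization, a multi-modular spiking network of adapting
    integrate-and-fire neurons whose inter-module couplings are learned by a
    pseudo-Boltzmann/Rprop rule to match prescribed spatial correlations, and
    symbolic-dynamics complexity analysis (normalized Lempel-Ziv complexity,
    Markov surrogates, triplet statistics) of the clustered dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
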