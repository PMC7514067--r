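Package: effcode
Title: Efficient Sensory Coding of Multidimensional Stimuli
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for constructing information-optimal heterogeneous
    populations of Poisson tuning curves encoding multidimensional
    (2-D) stimuli. Solves the density-remapping equation
    det(I + H(v)) = p/u for a scalar encoding potential whose gradient
    warps a uniform lattice of tuning curves so that neuronal density
    becomes proportional to stimulus probability at constant gain.
    Includes exact and approximate Fisher-information calculations, a
    mutual-information lower bound, closed-form one-dimensional
    machinery used as numerical oracles, and randomized
    slice-measurement experiments relating one-dimensional tuning
    sharpness and gain to joint stimulus probability.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
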