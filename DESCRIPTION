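Package: pherocircuit
Title: Neuron Morphology Similarity and Intracellular Response Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for matching neuron morphology to physiology in identified
    cell classes. Implements a point-and-tangent (dot-property) similarity
    score for registered neuron skeletons with Ward hierarchical clustering;
    spike extraction from current-clamp recordings by thresholding the second
    derivative of a binomially smoothed trace; odor-response quantification
    and significance testing (exact one-sided Poisson test with
    Benjamini-Hochberg false discovery rate control, peak firing rates,
    lifetime sparseness); subthreshold response testing against a
    pseudo-response null by permutation; a synaptic-latency estimator for
    glomerular stimulation experiments; and seeded generators for synthetic
    morphologies and recordings so every stage of the pipeline can be
    exercised and calibrated without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
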