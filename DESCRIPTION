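Package: multisyn
Title: Quantal Synchrony, Dendritic Overlap and Cholinergic Imaging Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying multi-directed cholinergic transmission in
    the retina: detection and kinetic analysis of quantal excitatory
    postsynaptic currents (EPSCs), event-triggered-average synchrony
    statistics for paired recordings with a Fisher-z shuffle test,
    nearest-neighbor-distance profiles between dendritic skeletons,
    noise-correlation-based segmentation and direction-tuning analysis of
    fluorescent neurotransmitter-sensor movies, and a synaptic-cleft
    diffusion/receptor-kinetics model. Includes seeded synthetic-data
    generators (paired quantal trains, co-fasciculated arbor pairs,
    direction-tuned sensor movies) with ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    signal,
    deSolve,
    minpack.lm,
    jsonlite,
    withr,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    tiff,
    tidyr
Config/testthat/edition: 3
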