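Package: cofoldviz
Title: Batch Visualization of Cotranscriptional RNA Folding Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reads time-course output of cotranscriptional RNA folding
    simulations (a whitespace-separated table of structure lineages, time
    points, ensemble occupancies, dot-bracket structures and free energies)
    and renders composite SVG figures and frame series: an occupancy-weighted
    treemap of secondary-structure drawings at each time point, plus a
    whole-simulation overview strip on a combined linear/logarithmic time
    axis with the end of transcription pinned at 75% of the axis width.
    Helices are colored by the imaginary center of their base pairs so that
    recurring structural motifs keep their color across time points and
    panels. Includes deterministic force-directed structure layout, a
    validated trajectory parser with pseudoknot support, and a synthetic
    trajectory generator for testing and demonstration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    stats,
    utils,
    xml2,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
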