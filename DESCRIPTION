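Package: neuroschematics
Title: Neural Schematics for Large-Scale Neural Network Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A formal graphical notation for large-scale neural network
    structures described at the level of neuron populations and projections.
    Provides a validated in-memory data model (populations, projections,
    cortical layers, areas, non-cortical regions and functional units), a
    JSON-dialect serialization (NNSD), export to and import from a constrained
    declarative PyNN subset, a deterministic automatic layout engine with
    orthogonal edge routing, and an SVG renderer implementing the notation's
    visual grammar (solid population rectangles, arrowhead-free projections
    with empty-circle inhibitory terminators, dotted layer and region
    delimiters, dashed unit boxes, no color, no attribute-scaled glyphs).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
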