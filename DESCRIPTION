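Package: ExhibitSpace
Title: Space Use, Territoriality and Exhibit Preference Analysis for
    Enclosed Animal Groups
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing scan-sampled animal locations inside a
    bounded enclosure: georeferencing of digitised coordinates, kernel
    utilization distributions with the enclosure boundary as a barrier,
    95% home-range and 50% core-area isopleths, dyadic overlap via the
    utilization distribution overlap index (UDOI) across space-use
    levels to detect territoriality, overlap degree and seasonal overlap
    networks, and Vanderploeg-Scavia electivity indices for exhibit
    features, together with nonparametric group comparisons and a
    synthetic scan-data generator for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'geometry-utils.R'
    'exhibit-map.R'
    'electivity.R'
    'homerange.R'
    'inference.R'
    'observations.R'
    'overlap.R'
    'synthetic.R'
    'pipeline.R'
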