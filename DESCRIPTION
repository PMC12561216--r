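Package: leafletlab
Title: Parametric Transcatheter Heart-Valve Leaflet Design and Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative evaluation of closed and semi-closed
    transcatheter heart-valve leaflet designs. Generates parametric
    trileaflet surface geometries (opening degree, free-edge shape),
    simulates stent crimping (oversizing) plus diastolic pressure loading
    with a nonlinear membrane finite-element solver including
    leaflet-leaflet contact, extracts the Pinwheeling Index from deformed
    or digitized free-edge traces, and computes ISO-5840-style
    hydrodynamic metrics (transvalvular pressure gradient, effective
    orifice area, regurgitation fraction) from pulse-duplicator
    pressure/flow waveforms, including a synthetic right-heart waveform
    generator for fully reproducible end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    pracma,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
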