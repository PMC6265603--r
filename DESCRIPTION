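Package: ogtpn
Title: Continuous Petri Net Models of PI3K/Akt-OGT Crosstalk in Diabetes
    and Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A continuous Petri net modelling engine (places, transitions,
    standard and inhibitory arcs, mass-action firing semantics, stiff ODE
    integration, P-invariant structural analysis) together with programmatic
    builders for three variants of the insulin-stimulated PI3K/Akt signalling
    pathway coupled to the hexosamine biosynthetic pathway and the
    O-GlcNAc cycling enzymes OGT and OGA: a normal adipocyte, an
    insulin-resistant adipocyte, and a hyperglycemic breast cancer cell.
    A declarative intervention layer applies in-silico perturbations (shRNA
    knockdown of OGT mRNA, the covalent OGT inhibitor BZX, Metformin as a
    proliferation inhibitor, and their combinations) and an analysis layer
    computes trajectory readouts, fold changes, direction calls and dose
    sweeps. Nets are exchanged as PNML; configurations as YAML.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    xml2,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
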