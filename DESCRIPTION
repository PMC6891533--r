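Package: PromCliff
Title: Compound Promiscuity Profiling and Promiscuity-Cliff Analysis for
    Qualitative Screening Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analyzing multitarget activity (promiscuity) of small
    molecules in large qualitative screening matrices. Aggregates per-assay
    active/inactive calls into consistent compound activity profiles, removes
    assay-artifact-prone chemistry (PAINS substructures, colloidal-aggregation
    likeness, medicinal-chemistry structural alerts), computes promiscuity
    degrees and their census, assigns protein targets to drug-target classes
    and identifies multiclass ligands, detects matched molecular pairs with
    transformation size restrictions, derives promiscuity cliffs between
    highly promiscuous compounds and their inactive or single-target analogs,
    and analyzes the resulting bipartite cliff network (hubs, alternating
    pathways). Includes a deterministic synthetic screening-data generator
    with planted ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ChemmineR,
    ChemmineOB,
    igraph,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
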