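Package: bootGSA
Title: Bootstrap Gene-Set Analysis of Time-Course Expression Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies "dynamically expressed" gene sets in an injury
    time-course expression matrix. Each gene's temporal profile is z-scaled,
    a set's mean profile is compared to the background (all-gene mean)
    profile by Euclidean distance, and significance is assessed against a
    bootstrap null built from size-matched random gene sets, with a
    plus-one-corrected empirical p-value and false discovery rate control.
    Includes an exhaustive-enumeration oracle for small universes, a
    synthetic time-course generator with ground-truth dynamic sets
    (early-transient and late-sustained injury-response phases), and
    command-line entry points for running the pipeline on expression TSV
    and GMT gene-set files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
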