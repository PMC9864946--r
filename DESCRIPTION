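Package: germsync
Title: Germination Synchrony, Dormancy and Seedbank Cycling Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying germination synchrony from replicate-level
    germination time courses. Computes the pairwise-overlap synchrony index Z
    and the Shannon-entropy asynchrony index (bits) per replicate, summarises
    them across treatment groups, models thermal-time germination under the
    six types of non-deep physiological dormancy, and simulates germination
    trials, dormancy-breaking treatments (after-ripening, cold stratification)
    and seasonal seedbank dormancy cycling with monthly exhumation assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
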