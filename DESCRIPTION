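Package: bioeventnet
Title: Post-Processing of Biomolecular Text-Mining Events into Gene Association Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns corpora of recursive biomolecular text-mining events
    (BioNLP shared-task style standoff annotations) into canonicalized,
    family-generalized, confidence-ranked and structurally refined events;
    typed pairwise gene associations (binding, regulation, indirect
    regulation); and indirect, hypothesis-level associations such as
    coregulators and shared binding partners. Includes a reader/writer for
    the standoff annotation dialect, a polarity algebra for flattening
    nested regulation chains, classifier-margin confidence aggregation and
    binning, a deterministic synthetic-corpus generator with planted ground
    truth, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
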