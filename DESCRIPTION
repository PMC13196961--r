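Package: rwibald
Title: Range-Weighted Branch Length Difference for Branch-Level Endemism
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores every branch of a rooted phylogeny by the difference
    between its length on the range-weighted observed tree and on a
    range-weighted equal-branch-length comparison tree (RWiBaLD), selects
    highly range-restricted branches with a maximum-Euclidean-distance
    elbow threshold, and classifies them as neo-, meso-, or paleo-endemic.
    Includes the unweighted analogue (BaLD), per-branch and per-grid-cell
    summaries, annotated Newick export, a synthetic-data generator with
    planted endemics for validation, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
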