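Package: tfbench
Title: Ligand-Centric Target Fishing and Per-Query Benchmarking
Version: 0.1.0
Authors@R: person("Benchmark", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A ligand-centric target-fishing baseline and its evaluation
    framework. Targets of a query small molecule are predicted as the union
    of the known targets of its k most similar database molecules, with
    similarity measured by the Dice coefficient on 166-key structural
    fingerprints. Bioactivity tables are curated with explicit qualification
    filters (activity type, relation, units, assay type, curator confidence,
    target type, potency threshold, minimum ligands per target), and each
    query is scored as a binary classification over the qualifying target
    universe (accuracy, precision, recall, Matthews correlation). Includes
    benchmark partition construction with a random control group,
    polypharmacology and target-coverage summaries, a synthetic
    chemogenomics generator with ground truth and observation-bias masks,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
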