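Package: cstconcord
Title: Concordance of White-Matter Tract Segmentations with nTMS Motor Maps
Version: 0.1.0
Authors@R: person("cstconcord", "maintainers", email = "maintainers@cstconcord.dev", role = c("aut", "cre"))
Description: Tools to assess corticospinal-tract (CST) segmentations and their
    voxelwise ensemble uncertainty against navigated transcranial magnetic
    stimulation (nTMS) motor-response masks. Builds classified nTMS response
    masks (+M1+, -M1+, -M1-) from exported stimulation responses, aggregates
    stochastic segmentation ensembles into mean probability, binary mask and
    uncertainty maps, measures overlap (Szymkiewicz-Simpson coefficient and
    Dice) with paired Wilcoxon method comparison, and relates uncertainty to
    Euclidean distance from the tract via binned joint histograms, Spearman
    rank correlation and a linear trend. Includes a synthetic tubular phantom
    cohort generator so the full pipeline is testable without clinical data,
    and a minimal NIfTI-1 reader/writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
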