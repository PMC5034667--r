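Package: MethylAgeRules
Title: Combinatorial Discovery of Age-Associated DNA Methylation Patterns
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers combinations of CpG sites whose methylation state
    changes between developmental stages. Beta values from methylation
    arrays are discretized into three states (unmethylated, intermediate,
    methylated), CpG sites are ranked by Monte Carlo feature selection
    over sliding binary age cuts, ages are clustered into groups by the
    Jaccard distance between per-cut significant-feature sets, and
    under-sampling-balanced rough-set rule induction produces IF-THEN
    rules that are filtered by hypergeometric significance and scored for
    pairwise condition interactions. Includes a synthetic-cohort
    generator with planted age transitions for method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3), SummarizedExperiment
Imports: methods, stats, utils, Rcpp, S4Vectors, yaml, ape
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, knitr, rmarkdown
biocViews: DNAMethylation, Epigenetics, Classification, FeatureExtraction,
    Clustering
Config/testthat/edition: 3
RoxygenNote: 7.3.3
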