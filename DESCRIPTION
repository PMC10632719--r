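Package: admixclock
Title: Epigenetic Clock Differences Between Admixed and Indigenous Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested re-implementation of a multi-stage analysis of
    epigenetic-aging differences between two co-located populations:
    clock-based age-acceleration estimation from CpG beta-value matrices,
    normality-gated inter-population testing with Benjamini-Hochberg control,
    genotype quality control (exact Hardy-Weinberg test, identity-by-descent
    PiHat, LD pruning), local-ancestry deviation scanning with GWAS-catalog
    discovery and in-cohort replication, kinship/inbreeding association via a
    pairwise delta statistic, and exact LMG (Lindeman-Merenda-Gold)
    decomposition of linear-model R-squared. A synthetic-data module generates
    admixed cohorts, clock definitions, beta matrices, ancestry tracts and
    mock GWAS catalogs with the statistical structure the downstream stages
    assume, so the full pipeline is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
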