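Package: gwaspathnet
Title: Case-Control Allelic Association and Network-Based Pathway
    Ranking for IBD GWAS Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A systems-genetics workflow for targeted case-control SNP
    panels: allelic chi-square association tests with odds ratios and
    Hardy-Weinberg exact-test quality control; construction of
    protein-protein association networks around risk genes with capped
    first- and second-shell interactor enrichment; weighted combination of
    degree, harmonic-closeness and betweenness centralities into a protein
    ranking score; Markov and edge-betweenness clustering; gene-set
    over-representation with complementary pathway-network construction;
    phenotype set comparisons; and disease-disease networks from shared
    pathway profiles. Includes generators for synthetic genotype, network
    and gene-set data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
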