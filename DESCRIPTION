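Package: phylocomm
Title: Community Phylogenetic Diversity, Structure and Distance Decay for
    Plot-Based Vegetation Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies the phylogenetic alpha and beta diversity of plot-based
    plant community surveys against a dated phylogeny: Faith's phylogenetic
    diversity (raw and proportional), relative phylogenetic diversity against
    an equal-branch-length comparison tree, mean pairwise and nearest-taxon
    distances, and the PhyloSor index of phylogenetic similarity. Standardized
    effect sizes (NRI, NTI) and two-tailed significance flags are obtained from
    independent-swap and richness-preserving randomization nulls. A statistics
    stage compares refugial and colonizing plot groups (Mann-Whitney U),
    screens species richness against environmental variables, and relates
    PhyloSor to geographic (haversine) and standardized environmental distance
    with Mantel permutation tests. A seedable generator of ultrametric trees,
    Brownian traits, assembled communities and site tables supports end-to-end
    testing, and a bundled reference table transcribes the per-plot indices of
    a 35-plot grassland survey from the Tianshan Mountains.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
NeedsCompilation: yes
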