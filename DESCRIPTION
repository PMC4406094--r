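Package: dmland
Title: Spatial Clustering of Dobzhansky-Muller Incompatible Genotypes Under
    Limited Dispersal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Spatially explicit, individual-based simulation of a continuously
    distributed, dioecious population on a landscape of fixed home-range sites,
    with distance-limited mate choice and offspring dispersal drawn from a
    truncated inverse-square kernel. Two selected loci carry a classical
    Dobzhansky-Muller incompatibility (carriers of both derived alleles are
    inviable) and twenty neutral diallelic loci track isolation by distance via
    the pooled inbreeding coefficient F = 1 - Ho/He. Density-based spatial
    clustering (DBSCAN) of the two pure double-homozygote genotype classes
    detects per-generation events of spatial reproductive isolation and their
    persistence, and a scenario sweep reproduces the dependence of both F and
    the event rate on maximum movement distance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
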