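Package: genets
Title: Clonal Structure, Population Genetics and Age Dating of
    Microsatellite-Genotyped Plant Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects clonal groups (genets) among diploid multilocus
    microsatellite genotypes while tolerating somatic mutations, quantifies
    the clonal growth excess of a stand, and dates clonal spread by combining
    geographic distances between ramets with lateral growth rates estimated
    from tree-ring counts along branch sections.  Includes per-locus
    diversity summaries (allelic richness, observed and expected
    heterozygosity, evenness), Monte-Carlo exact tests of Hardy-Weinberg
    equilibrium, Weir-Cockerham F-statistics, the index of association with
    a permutation null, distance-decay regressions of genetic versus
    geographic distance, and a synthetic-data generator that emulates a
    sparsely treed krummholz stand for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    geosphere,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
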