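Package: bloodgroupr
Title: Blood Group Phenotype Inference from Phased Genotypes and Read Depth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers red-cell antigen phenotypes across nine blood group
    systems (ABO, Rh, Kell, Kidd, Duffy, Lewis, Lutheran, MNS, P1) from
    phased small-variant genotypes together with read-depth-derived copy
    number at the paralogous RHD/RHCE and glycophorin loci. Implements
    depth-ratio classification of RHD zygosity and C/c antigen state, a
    windowed-coverage hidden Markov model for glycophorin structural
    alleles (GYPB deletion, Dantu), a haplotype-phase-aware rule engine for
    24 antigens, serology concordance statistics, and rare-variant triage
    of discordant samples. A synthetic-cohort generator produces phased
    VCFs, depth tracks and serology tables with the statistical structure
    the analysis assumes, including a deterministic 100-donor cohort that
    reproduces a published serology-versus-genome comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    Rsamtools,
    GenomicRanges,
    IRanges
Config/testthat/edition: 3
RoxygenNote: 7.3.3
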