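Package: admixtract
Title: Ancestry Tracts, Admixture-Pulse Dating and Sex-Biased Admixture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for studying recently admixed populations from phased
    local-ancestry data: forward simulation of admixed genomes under
    explicit multi-pulse migration histories (including sex-specific
    founding contributions and X-chromosome transmission), extraction of
    ancestry tracts from per-site local-ancestry calls, global ancestry
    proportions and short/long tract statistics, maximum-likelihood dating
    of admixture pulses from tract-length histograms with model selection
    across competing demographic scenarios, X-versus-autosome sex-bias
    statistics (admixture difference ratios, signed-rank tests, mechanistic
    inversion to female/male source contributions), ancestry-masked
    subcontinental analyses (allele-sharing dissimilarity, metric MDS,
    haploid Weir-Cockerham FST), windowed haplotype heterozygosity and
    identity-by-descent sharing summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
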