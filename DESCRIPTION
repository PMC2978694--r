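Package: footcode
Title: Amino-Acid to Nucleotide Recognition Codes from Local Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers amino-acid to nucleotide recognition codes within a
    transcription-factor family from locally regulated intergenic regions.
    Regulators are grouped into recognition classes by the specificity
    residues of their DNA-binding helix; binding sites are discovered per
    class with a palindromic Gibbs motif sampler over strict intergenic
    regions and refined by iterative position-weight-matrix scanning
    against an empirical shuffled-sequence null; paired protein/DNA
    alignments are screened by mutual information; and binding-site
    half-site combinations are classified into intrinsic (symmetric or
    asymmetric) and extrinsic degeneracies. A synthetic-data generator
    with planted codes and degeneracy scenarios provides ground truth for
    benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: MotifDiscovery, SequenceMatching, Transcription, GeneRegulation
RoxygenNote: 7.3.3
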