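Package: ctsplice
Title: Kinetic Markov-Chain Modeling of Co-Transcriptional Alternative Splicing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates alternative splicing of cassette exons as a continuous-time
    Markov chain coupled to RNA polymerase II elongation. Gene structures are
    described by exon and intron lengths only; splice-site availability and
    pairing reactions compete within transcriptional phases whose durations are
    set by the elongation rate, and isoform probabilities are obtained by
    matrix-exponential propagation followed by an absorbing-state solve. Includes
    a full engine (availability and pairing reactions, up to three introns), a
    pairing-only engine (up to nine introns), intron-definition and
    exon-definition rate rules, polymerase pausing, a Gillespie stochastic
    oracle, and batch simulation over real or synthetic gene tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    grDevices,
    graphics,
    stats,
    utils
Suggests:
    BiocGenerics,
    rtracklayer,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
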