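Package: fp2mol
Title: Translating Structural Fingerprints Back into Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural fingerprints (MACCS keys, Avalon, atom pairs,
    topological torsions, path-based and circular fingerprints) are lossy
    set representations of molecules. This package treats the inverse
    problem as sequence-to-sequence translation: molecules are featurized
    into ordered fingerprint-token sentences, and a transformer
    encoder-decoder is trained to reconstruct SMILES or SELFIES strings
    from them. It provides a synthetic drug-like corpus generator, a
    registry of thirteen fingerprint featurizers with set-Tanimoto
    similarity, SMILES/SELFIES tokenizers and a robust SELFIES-style
    codec, a pure-R transformer with token-count batching and a cyclic
    decayed learning-rate schedule, beam-search decoding, an evaluation
    suite (Tanimoto exactness, accuracy breakdown, fingerprint-bias
    matrix, similarity significance thresholds), and attribution maps via
    integrated gradients and cross-attention.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
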