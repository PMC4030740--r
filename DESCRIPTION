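Package: ChargeScreen
Title: Ligand-Based Virtual Screening with Sign-Split Autocorrelation of
    Partial Charges
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Encodes 3D molecules carrying atomic partial charges into a
    pair of rotation-translation invariant descriptor vectors by spatial
    autocorrelation of the charge products, sign splitting, and linear
    binning on a fixed distance grid.  Provides cross-correlation at lag
    zero plus continuous Tanimoto and Tversky scoring, rank-ordering of a
    compound database against a query molecule with best-conformer
    filtering, a constant-memory streaming mode for large databases, ROC
    curve and AUC evaluation of active/decoy screens, a TRIPOS MOL2
    reader/writer, and a synthetic fixture generator producing actives,
    decoys and rigid-transformed molecule variants.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
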