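Package: nanometasig
Title: Consensus Transcriptomic Signatures of Engineered Nanomaterial Exposure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Meta-analysis toolkit for deriving a consensus transcriptomic
    signature of engineered nanomaterial (ENM) exposure from many heterogeneous
    differential-expression contrasts, and for characterising that signature.
    Implements an ensemble of effect-size, Fisher sum-of-logs and rank-product
    meta-analyses merged by Borda count; pre-ranked gene-set enrichment with a
    peak-based signature cut; duration-class frequency scores with Ward
    clustering to isolate persistently deregulated genes; promoter extraction
    and a simplified EM motif finder with PWM-library matching and
    zinc-finger-family overrepresentation testing; liquid-drop-model and
    atomistic nanodescriptors with descriptor-gene correlation enrichment;
    adverse-outcome-pathway event enrichment; and benchmark-dose (BMD/BMDL/BMDU)
    dose-response analysis with a filter cascade. A synthetic-data generator
    with planted ground truth makes every stage testable by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
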