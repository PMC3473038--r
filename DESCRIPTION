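Package: shapefold
Title: RNA Secondary Structure Prediction with Probing-Data Soft Constraints
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Predicts RNA secondary structure from chemical probing data
    (SHAPE or in-line probing) using per-nucleotide soft constraints.
    Reactivities are normalized to unpaired probabilities and folded into a
    weighted McCaskill partition function, weighted base-pair probabilities
    and a weighted minimum free energy structure. Includes self-consistency
    diagnostics over the Boltzmann ensemble (expected distance to the probing
    data, critical distance, pointwise entropies, Morgan-Higgs structural
    diversity), a stacking pseudo-energy comparison mode, an exhaustive
    enumeration oracle for validation, and readers/writers for FASTA, CT,
    dot-bracket and reactivity file formats.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, jsonlite, Biostrings
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
biocViews: StructuralPrediction, RNA, Software
RoxygenNote: 7.3.3
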