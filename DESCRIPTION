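Package: carbmotif
Title: Carbonylation Site Prediction from Substrate Motif Decomposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies protein carbonylation sites (oxidised K, R, T and P
    residues) from sequence context. Positive 21-mer site windows are
    recursively partitioned into motif subgroups by maximal chi-squared
    dependence of amino-acid group occurrence between window positions;
    each subgroup trains an ungapped position-specific log-odds profile
    scored in bits, and a second-layer radial-basis-function support
    vector machine combines the subgroup bit scores into a single
    classifier. Includes six sequence feature encoders (amino-acid
    composition, pair composition, one-hot, positional weight matrix,
    PSI-BLAST PSSM aggregation, BLOSUM62), redundancy reduction,
    stratified cross-validation with repeated negative resampling,
    ROC/AUC and Matthews-correlation evaluation, and a seeded
    synthetic-data generator with planted positional motifs for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    e1071,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
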