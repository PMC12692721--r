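Package: featureforge
Title: Descriptor Engineering and Feature Selection for Protein Secondary
    Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Alignment-free descriptor engineering for per-residue protein
    secondary structure prediction. Builds protein-block (structural
    alphabet) reference fragments from dihedral definitions, computes
    pentapeptide backbone RMSD statistics under position-dependent reduced
    sequence alphabets, and turns them into t-statistic and protein-block
    string probability descriptors. Adds periodic and windowed
    physicochemical descriptors over AAindex-style property scales with
    non-canonical amino acid support, one-hot and terminal-proximity
    features, and external disorder scores. Provides two-stage descriptor
    pre-selection (stepwise discriminant analysis on Wilks' lambda followed
    by greedy forward selection under a linear discriminant classifier), a
    compact bidirectional LSTM sequence-labelling head with a masked ninth
    class for unresolved residues, Q-score, per-class and macro F1 and
    confusion-matrix evaluation, and deterministic synthetic-data
    generators for chains, planted-signal feature matrices and property
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
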