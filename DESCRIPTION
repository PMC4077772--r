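Package: rfamide
Title: Discovery and Verification of RFamide Neuropeptide Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mining RFamide neuropeptide precursors from cDNA and
    verifying the predicted mature peptides. Annotates open reading frames,
    signal peptides (Kyte-Doolittle hydropathy plus the (-3,-1) rule),
    prohormone convertase cleavage sites and C-terminal amidation; classifies
    peptides into the PQRFamide and LPXRFamide families; computes monoisotopic
    masses and singly charged b/y fragment-ion ladders and matches them to
    MALDI-TOF peak lists; builds neighbor-joining trees with bootstrap
    supports and outgroup rooting from amino-acid alignments; quantifies
    conserved synteny around focal gene loci with a permutation null; and
    generates ground-truthed synthetic data (precursor cDNAs, spectra,
    alignments evolved on a tree, gene-order tables) so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    phytools,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
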