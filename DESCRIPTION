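Package: paircomm
Title: Ligand-Receptor Crosstalk Inference from Bulk Coculture RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers intercellular communication between two cocultured cell
    populations from bulk RNA-seq read counts. Provides FPKM quantification
    and sample-level quality control, a negative-binomial Wald test for
    two-group differential expression with Benjamini-Hochberg correction,
    screening of differentially expressed ligands, receptors and
    transcription factors against curated catalogs, construction of
    autocrine and paracrine ligand-receptor pairs under two complementary
    strategies scored by the product of ligand and receptor fold changes,
    degree-based transcription-factor hub ranking, and depth-bounded search
    for ligand-receptor-signaling-protein-TF axes over a user-supplied
    directed signaling network. A negative-binomial simulator plants known
    cell-type signatures, coculture-induced regulation and ground-truth
    crosstalk pairs and axes so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
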