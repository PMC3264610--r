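Package: OrganelleDynamics
Title: Structural Dynamics of Plant Organellar Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Structural analysis of circular plant organellar genomes:
    maximal exact repeat discovery (forward and palindromic) on circular
    DNA, decomposition of a mitochondrial master circle into inter-repeat
    segments and enumeration of the isomeric and subgenomic molecules
    producible by intra-molecular recombination, detection of the
    chloroplast quadripartite architecture (IRa/IRb/LSC/SSC), discovery
    and age classification of chloroplast-derived insertions (mtpt) in
    mitochondrial genomes with their GC statistics, classification of
    mitochondrial tRNAs as plastid-derived or native, codon-usage and
    stop-codon tables, and anticodon wobble-based codon decodability.
    Includes seeded simulators that generate genomes with planted repeats,
    quadripartite layouts, plastid insertions and tRNA sets with known
    ground truth for validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
biocViews: Genetics, Alignment, SequenceMatching, Annotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
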