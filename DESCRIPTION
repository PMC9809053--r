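Package: fragmentR
Title: Headless Molecule Fragmentation and Fragment-Frequency Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A scriptable molecule-fragmentation framework for
    cheminformatics and drug-discovery workflows. Provides pluggable
    fragmentation algorithms (functional-group extraction by atom-marking
    rules, glycosidic-moiety detection and removal, Murcko scaffold
    dissection with enumerative parent-scaffold generation), pipeline
    composition of fragmenters, and fragment-frequency analytics over
    molecule sets, with SMILES/SDF/Molfile input, CSV/SDF output and a
    command-line entry point. Structure handling, aromaticity perception
    and canonical SMILES generation are delegated to OpenBabel through
    ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    parallel,
    igraph,
    ChemmineOB,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'molecule.R'
    'smiles-writer.R'
    'rings.R'
    'chemio.R'
    'fragmenter-api.R'
    'ertl.R'
    'sugar.R'
    'scaffolds.R'
    'engine.R'
    'fixtures.R'
    'cli.R'
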