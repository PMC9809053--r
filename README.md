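# fragmentR

A headless, scriptable molecule-fragmentation framework for
cheminformatics and drug-discovery work: import a molecule set, apply
pluggable fragmentation algorithms (alone or as a pipeline), and analyse
the resulting fragment set by frequency — all from R or the shell, with
no GUI required.

Three algorithms are built in, behind one plugin contract:

- **`ertl-fg`** — functional-group extraction by per-atom marking rules
  (heteroatoms; carbons in non-aromatic multiple bonds; carbons multiply
  bonded to heteroatoms; acetal carbons; heteroatom-containing
  three-rings). Connected marked components become FG fragments with
  their first-sphere carbon environment (generalized `[H]Oc`-style or
  full-hydrogen depiction); unmarked components become hydrogen-saturated
  carbon-skeleton remnants.
- **`sugar-removal`** — detection and removal of glycosidic moieties:
  non-fused furanose/pyranose-like rings rich in exocyclic oxygens
  (ratio ≥ 0.5 by default) and optionally open-chain polyol/carbonyl
  sugars, removed terminal-first so the aglycone stays connected.
- **`scaffold`** — Murcko framework dissection (scaffold, side chains,
  rings and linkers) and enumerative parent-scaffold generation by
  terminal-ring removal.

Every fragment is reduced to canonical SMILES (OpenBabel, via
ChemmineOB); deduplication is string equality on that form. For each
distinct fragment the framework reports its **frequency** (total
occurrences over the set) and **molecule frequency** (number of distinct
molecules containing it), plus a seeded sample parent. Runs are
deterministic for any thread count.

## Worked example

```r
library(fragmentR)

tmp <- tempfile(fileext = ".smi")
writeLines(c("CCO ethanol", "OCCO glycol"), tmp)
set <- readSmilesFile(tmp)

run <- runSingle(set, "ertl-fg")
fragmentRecords(run)
#>   fragment_smiles frequency molecule_frequency sample_parent_id sample_parent_name
#> 1              CO         3                  2                0            ethanol
#> 2              CC         2                  2                1             glycol
```

The hydroxy group on an aliphatic carbon (canonical key `CO`, the
generalized depiction `[H]OC`) occurs three times — once in ethanol,
twice in the diol — across two molecules; the ethane remnant `CC` comes
from both skeletons. On phenol the same fragmenter returns exactly one
functional group, the aromatic-environment hydroxy `[H]Oc` (canonical
key `[CH2]O`), plus a benzene remnant:

```r
fragmentMolecule(makeFragmenter("ertl-fg"), parseSmiles("Oc1ccccc1"))
#> [1] "[CH2]O"   "c1ccccc1"
```

Pipelines chain fragmenters; each later stage consumes the previous
stage's fragments. Deglycosylate, keep only ring side chains, then
extract their functional groups:

```r
pl <- list(list(id = "sugar-removal", settings = list()),
           list(id = "scaffold", settings = list(fragmentation_type = "SIDE_CHAINS_ONLY")),
           list(id = "ertl-fg", settings = list()))
run <- runPipeline(set2, pl)   # anisole's methoxy side chain -> methanol -> hydroxy FG
```

From the shell, the same operations are available via the bundled
script:

```sh
Rscript inst/scripts/fragmentr fragment --input molecules.smi \
    --algorithm ertl-fg --threads 4 --seed 0 --output out/
# -> out/fragments.csv, out/items.csv, out/fragments.sdf, out/summary.json
```

A deterministic 26-molecule toy panel with hand-derived expected
fragments ships with the package (`toyPanel()`, `writePanelFiles()`) so
every algorithm is exercisable without any external database.

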