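---
title: "Molecule fragmentation methods in fragmentR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Molecule fragmentation methods in fragmentR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope and data model

fragmentR is a headless, scriptable framework for in silico molecule
fragmentation and fragment-frequency analysis. Molecule sets are imported
from SMILES text files or SD files (V2000 and V3000), fragmented with one
pluggable algorithm or a pipeline of algorithms, and the resulting
fragments are deduplicated, counted and exported as CSV/SD tables.

Canonical SMILES is the only long-term structure representation: every
imported molecule and every emitted fragment is reduced to OpenBabel
canonical SMILES (via ChemmineOB), and all fragment deduplication is
string equality on that form. Structure perception — kekulisation,
aromaticity, hydrogen counts, formal charges — happens once, on import,
and every algorithm operates on that fixed perception. The internal
`Molecule` object is a heavy-atom graph: an atom table (element, formal
charge, aromatic flag, attached hydrogens) and a bond table (kekulised
order 1/2/3 plus an aromatic flag). The two views are reconciled from
paired OpenBabel conversions of the same input (SDF with explicit
hydrogens for the kekulised graph and charges; MOL2 for the aromatic
atom/bond typing), which is safe because OpenBabel preserves input atom
order.

A fragmentation algorithm is a plugin implementing four operations:
typed, documented settings (`settingDescriptors`); an input filter
(`shouldFilter`); a preprocessing step (`preprocessMolecule`); and the
fragmentation itself (`fragmentMolecule`). For every input structure
exactly one of three things happens: it is *filtered* (with a recorded
reason), it *fails* (the error is logged and isolated to that molecule),
or it yields a — possibly empty — fragment list.

# Functional-group extraction

The functional-group fragmenter identifies groups by per-atom marking
rules rather than by a curated pattern list, so the full diversity of
groups present in a set is captured. The rules, applied to the fixed
import-time perception, are:

1. every heteroatom (neither carbon nor hydrogen) is marked;
2. every carbon in a *non-aromatic* C=C or C≡C bond is marked;
3. every carbon double- or triple-bonded to a heteroatom is marked;
4. every acetal-like sp³ carbon — one with at least two single bonds to
   O/N/S atoms that themselves bear only single bonds — is marked;
5. all atoms of three-membered rings containing a heteroatom are marked.

Each marked atom records one primary reason, assigned in the order
HETEROATOM, C_MULTIBOND_HETERO, C_C_MULTIBOND, ACETAL_C,
THREE_RING_HETERO. Connected components of marked atoms become
functional-group fragments; connected components of *unmarked* atoms
become carbon-skeleton remnants, returned by default
(`return_remnants = TRUE`).

Each functional-group fragment carries its first-sphere unmarked carbon
neighbours as *environment* atoms, typed aromatic (lowercase in the
SMILES) or aliphatic. In the default `generalized` mode, environment
carbons are written bare — they carry no hydrogens of their own — and
heteroatom hydrogens are written as explicit `[H]` atoms; the hydroxy
group on an aromatic carbon is thus depicted `[H]Oc`, which is distinct
from the aliphatic `[H]OC`. In `full` mode environment carbons keep
their real hydrogen counts (written in brackets, e.g. `[CH2]`).
Cleaved bonds never carry attachment labels; open valences are saturated
with hydrogen when a fragment is re-parsed. This cut-without-preserving,
saturate-with-hydrogen convention is used by *every* fragmenter in the
package.

Two depiction/numerics details are worth stating. First, a lone aromatic
environment carbon cannot be kekulised on its own; the canonicaliser
deterministically resolves such atoms (e.g. `[H]Oc` canonicalises to
`[CH2]O`), and because both the depiction and any reference string go
through the same canonicaliser, deduplication and comparisons remain
exact. Second, remnant fragments keep aromaticity only for rings wholly
contained in the fragment; an aromatic ring broken by marking (e.g. the
five carbons of pyridine) reverts to its kekulised single/double bond
orders and is hydrogen-saturated like any other cut.

The fragmenter rejects structures containing elements outside
{H, C, N, O, S, P, Se, F, Cl, Br, I} ("metal or metalloid atom"); the
element list is our documented choice of the organic subset plus
selenium. Formal charges are neutralised in preprocessing where hydrogen
bookkeeping permits: anions gain a hydrogen per negative charge, cations
lose one if they have one to give. A charge that cannot be neutralised
this way (e.g. a quaternary ammonium) demotes the molecule to filtered
rather than raising an error.

# Sugar removal

The sugar-removal fragmenter detects glycosidic moieties and returns the
aglycone (optionally also the sugars). A *circular* sugar hit is a
non-fused five- or six-membered ring with exactly one ring oxygen, all
ring carbons sp³, whose count of exocyclic single-bonded oxygens divided
by the ring size reaches `exocyclic_oxygen_ratio_min` (default 0.5 —
β-D-glucopyranose scores 4/6, tetrahydropyran 0/6). A *linear* sugar hit
(off by default) is an acyclic chain of 3–7 carbons, none in a ring,
each bearing exactly one oxygen substituent that is either a terminal
hydroxy or a carbonyl; stereochemistry is ignored. Seven-membered sugar
rings and glycosidically-linked linear sugars are not matched; these
defaults are our documented stand-ins where the literature leaves the
exact pattern set open.

Hits are removed iteratively, smallest first atom index first, each
removal followed by re-detection, until no removable hit remains. In the
default terminal-only mode a hit is removable only if, after deletion,
at most one remainder component of at least `min_aglycone_heavy_atoms`
(default 5) heavy atoms survives — so the aglycone is never returned
disconnected. Sub-threshold leftovers (including the sugar's own
orphaned exocyclic CH2OH) are discarded. The bridging glycosidic oxygen
stays with the aglycone, so cleaving a sugar from an aryl ether leaves a
phenolic hydroxy — which is what makes a downstream functional-group
step see a hydroxy where the intact molecule had an ether. An input with
no hits is returned unchanged regardless of size; removal is idempotent
by construction (the aglycone contains no removable hit).

# Scaffolds

The scaffold fragmenter implements the Murcko framework view: ring
systems plus the acyclic linkers connecting them, with terminal chains
pruned. Ring perception uses the smallest ring through each non-bridge
bond (deduplicated), and ring systems are fused components over those
rings. Pruning iteratively deletes terminal non-ring atoms; atoms
attached to the retained core by a double or triple bond (e.g. a ring
carbonyl oxygen) are kept with the scaffold — a standard convention we
adopt and document, since it affects side-chain output. Acyclic
molecules have no scaffold and dissection yields an empty fragment list
with a logged warning.

Four dissection modes are available: `SCAFFOLD_ONLY` (default; the
scaffold itself), `SIDE_CHAINS_ONLY` (each pruned substituent, cut at
the ring/linker attachment and hydrogen-saturated — anisole's methoxy
side chain becomes methanol), `RINGS_AND_LINKERS` (one fragment per ring
system and per linker), and `ENUMERATIVE_PARENTS`.

Parent-scaffold enumeration removes one terminal ring at a time,
breadth-first: a terminal ring is one whose exclusive atoms (atoms
belonging to no other ring) can be deleted — followed by Murcko
re-pruning of the exposed linker — leaving a connected scaffold. All
distinct canonical parents down to single rings are collected, the input
itself excluded. Every parent has strictly fewer rings than its child,
so enumeration terminates. The 13-rule scaffold-tree prioritisation used
for hierarchical classification is deliberately not implemented; the
enumerative routine covers the scaffold-network use case, and a simple
tie-break (remove the smallest terminal ring, ties by canonical order)
would define a linear tree path if one is needed.

# Runs, pipelines and frequencies

A run processes the molecule set in contiguous chunks that are
recombined in input order, so results are bit-identical for any thread
count — determinism is a contract, not an accident of scheduling. Each
molecule's fragments are counted within the molecule; aggregation groups
by canonical SMILES, summing per-molecule counts into `frequency` and
counting distinct molecules into `molecule_frequency` (so
`molecule_frequency <= frequency`, and the sum of frequencies equals the
sum of per-molecule counts — an invariant the tests enforce on every
run). Fragments are ranked by descending frequency, ties by canonical
key. The sample parent shown for each fragment is drawn from its
containing molecules by a seeded generator (`seed` flag, default 0):
we chose reproducibility over fidelity to an unseeded original.

In a pipeline, stage 1 consumes the input molecules and every later
stage consumes each fragment emitted by the stage before, re-parsed as a
structure. Fragments a later stage filters or cannot parse pass through
unchanged with a logged note, preserving the conservation invariant;
final frequencies are traced back to the *original* input molecules.
A one-stage pipeline is exactly the single run.

Settings are persisted as line-based `key=value` text files, one per
fragmenter. Loading validates every value against the setting
descriptors: unknown keys and invalid values warn and leave the current
value in place, so a damaged file degrades to defaults instead of
failing a session. Strict validation (errors, not warnings) applies when
settings are supplied programmatically or via the command line.

# The fixture panel and what passing means

The built-in panel (`toyPanel()`, 26 hand-curated structures) spans
no-FG alkanes, the classic small functional groups, aromatics with and
without substituents, two- and three-ring scaffolds, a pyranose, a
glycoside, open-chain polyols, an epoxide, a non-neutralisable cation
and a metal-containing salt. Expected fragment multisets were derived by
hand application of the stated rules and cross-checked against an
independent brute-force marker (per-atom rule testing by exhaustive
neighbourhood inspection, three-rings by triple loop) — never by running
the implementation on itself. Thread-invariance checks use a
200-molecule set built by repeating the panel in permuted order.

The panel exercises every rule branch at desk scale, which is what the
tests certify: correctness of the marking rules, the removal and
pruning conventions, frequency semantics and determinism. It does not
emulate the size, stereochemical richness or structural pathology of
real compound collections (natural-product databases, vendor
catalogues); performance characteristics and frequency *distributions*
on such collections are outside what a green suite demonstrates.

# Degenerate inputs and numerical choices

Unparsable import lines are skipped, counted and logged; a file with no
parsable entry is a fatal error. A single leading header line in a
SMILES file is auto-detected by first-token parse failure. Methane-like
single-atom molecules fragment to themselves as remnants; an empty
fragment list (a pure sugar under aglycone-only removal, an acyclic
molecule under scaffold dissection) is legal and preserved through
pipelines as "contributes nothing". All tie-breaks are lexicographic on
canonical SMILES; the only stochastic element anywhere is the seeded
sample-parent draw. There are no floating-point tolerances in the
algorithms themselves — the single float setting
(`exocyclic_oxygen_ratio_min`) is compared with `>=` on exact small
rationals.
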