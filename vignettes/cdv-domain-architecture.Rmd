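---
title: "Domain-level analysis of archaeal Cdv/ESCRT machineries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Domain-level analysis of archaeal Cdv/ESCRT machineries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CdvArch)
```

# The problem and the modelling stance

The archaeal Cdv system (CdvA, the CdvB/ESCRT-III paralogs, CdvC/Vps4)
drives cell division in TACK and Asgard archaea, but the organisms are
mostly unculturable extremophiles, so the machinery has to be compared
*in silico*. The stance taken throughout this package is that a protein's
mechanistic repertoire is the set of domains and short motifs it carries,
and that protein-protein interactions are licensed by domain pairs with
experimentally established binding or polymerization activity. Everything
downstream — interaction networks, assembly scenarios, ancestral
reconstruction — is a deterministic consequence of (i) per-protein domain
architectures and (ii) a small, explicit rule table. This is a qualitative
model: no kinetics, no concentrations, no structure.

The closed domain vocabulary has eleven entries
(`domainVocabulary()`): the CdvA sub-domains (alpha-helix rich, beta-sheet
rich), the broken winged-helix pair (BWI on CdvA, BWH on one CdvB paralog),
the MIT-interacting motifs MIM1 and MIM2, the filament-forming Snf7 domain,
and the CdvC domains (MIT, AAA+ ATPase, Vps4_C), plus the N-terminal ANCHR
membrane-binding motif. Coordinates are 1-based inclusive everywhere and
converted nowhere.

# Motif calling

## MIM2 regular expressions

MIM2 is defined by three templates over the hydrophobic class
φ = `AILMFVPGW` and charged class x = `RKDE`, with literal prolines:
`MIM2_Core` = φPxφP, `MIM2_total` = core immediately followed by xxPφP,
`MIM2_Sulf` = xφxxφφPx immediately followed by the core. Two deliberate
literalisms: φ contains P and G (unusual for a hydrophobicity class, but
that is the published alphabet), and composite templates are *immediate*
concatenations — the composite lengths (10 and 13) match the aligned
proline spacing of the motif family, so no gap is allowed. `X` (unknown
residue) satisfies neither class.

`scanMim2()` reports every match of every requested template at every
offset; overlaps are all reported and downstream assembly deduplicates
(there is no published greediness rule, so the scanner does not invent
one). Two structural consequences are tested as invariants: every
`MIM2_total` match implies a core match at the same start, and every
`MIM2_Sulf` match contains core matches at offsets +5 and +8 (the prefix
ends in φPx which, followed by φP, re-creates the core pattern — an
unavoidable property of the templates, reported as-is). The literal-P count
per template (2/4/3) is the guaranteed lower bound on any match's proline
count; the 4-vs-2 contrast between CdvB-class and CdvB1/2-class motifs is
what the affinity ranking later consumes.

The scanner is validated against an independent symbol-by-symbol
sliding-window oracle on randomly generated sequences (1,000 sequences of
length up to 200 in the deepest check); the two paths share no code.

## Putative MIM2

Some CdvA homologs carry a proline-rich region that aligns with real MIM2
motifs but misses the regular expressions. `detectPutativeMim2()`
operationalises this as: any window of 15 residues lying in the C-terminal
half of the sequence with at least 3 prolines, not overlapping a full MIM2
match, merged into maximal spans. The window length, proline threshold and
C-terminal fraction are *package choices* — the published analyses state no
numeric criterion — and are therefore exposed as arguments and documented
as such. Full regex matches always take precedence.

## ANCHR

The ANCHR call inspects the first 30 residues of a protein given a
per-residue H/E/C secondary-structure track (produced externally; secondary
structure prediction is out of scope). A helix is called when the longest
H-run reaches 8 residues; a proline inside that run (or anywhere in the
window when no run exists) vetoes the call: `anchr = helix AND NOT
proline`. The run threshold and window are package choices calibrated once
so that the two Asgard CdvB clades in the bundled reference table separate
cleanly; both are arguments. This caller never sees Euryarchaeota/TACK
proteins in the default pipeline — there the homologous region carries a
helix-breaking proline and the call is correctly negative.

MIM1 is intentionally *not* regex-detected: no published pattern exists for
it, so inventing one would be fabrication. MIM1 enters only through
annotation input.

# Architecture assembly and classification

`assembleArchitectures()` merges overlapping same-type calls to their
coordinate union (the external scans report sub-hits of larger domains;
union is the least-committal summary), keeps the strongest evidence class
(db_scan > motif_regex > ss_annotation > putative) and deduplicates MIM2
matches to one instance per protein with class precedence total > Sulf >
core > putative. Assembly is idempotent.

The CdvC filter encodes the observation that AAA+ ATPase regions are
ubiquitous: a candidate is accepted only with a Vps4_C or MIT domain, or
via an explicit allowlist (one known exception with strong homology
evidence but a truncated architecture).

CdvB classification is total and deterministic. TACK proteins:
CdvB class = {Snf7, MIM2, BWH}; CdvB1/2 class = {Snf7, MIM2} without BWH
and without ANCHR (the ANCHR exclusion keeps the TACK and Asgard
taxonomies disjoint — the clades are phylogenetically separate); CdvB3
class = {Snf7} alone. Asgard proteins split purely on the ANCHR call.
Anything else is `unclassified`, never forced — outlier architectures
(horizontal transfer, metagenome contamination) stay visible instead of
being absorbed. Putative MIM2 counts as MIM2 for classification: the
regions align with genuine motifs and excluding them would misclassify the
two affected CdvA architectures.

Gene neighbourhood classification ranks genes per organism along the
chromosome and buckets the minimal pairwise rank distance between Cdv genes
(≤1 direct, ≤5 close, else distant; <2 Cdv genes: absent). The two
thresholds are package choices; no numeric criterion is published.

# Interaction networks and mechanism inference

The default rule set carries four validated pairs — MIM2–MIT (binding),
BWI–BWH (binding), Snf7–Snf7 and Vps4_C–Vps4_C (polymerization) — and two
putative ones: CdvA_beta self-polymerization (the experimental record is
contradictory) and MIM1–MIT binding. Putative rules are excluded from
qualitative network counts (they are drawn grey, not counted) but
available to mechanism inference, where the CdvA_beta rule underlies one of
the two Thaumarchaeota-type scenarios.

Qualitative networks collapse proteins to family labels and count each
(family pair, domain pair) once: a family of paralogs polymerising through
Snf7 is one interaction, regardless of paralog number. This is the counting
convention under which both TACK-type ancestral sets have exactly four
qualitative interactions.

`inferMechanism()` expands scenarios from a membrane-binding start protein.
The start is domain-flagged, not organism-flagged: a protein carrying ANCHR
or CdvA_beta can bind the membrane, and `start = "auto"` requires exactly
one such protein. The engine's semantics, chosen where the qualitative
description leaves freedom, are:

1. **Move collapse.** Candidate moves recruiting the same new protein
   collapse to one event, justified by the best rule (validated before
   putative, then affinity). This is what makes the MIM1 and MIM2 routes to
   CdvC one scenario rather than two — both yield CdvC binding.
2. **Affinity order.** Membrane binding > BWI–BWH > Snf7–Snf7 >
   (MIM2/MIM1)–MIT > Vps4_C–Vps4_C; within the MIT tier, descending MIM2
   proline count, MIM1 (uncounted) last, remaining ties lexicographic. The
   order encodes the observed enrichment sequence (ring assembly before
   CdvC arrival; BWH-carrying CdvB before CdvB1/2).
3. **Scenario forks.** A putative-status move is dominated by validated
   moves of the two strong tiers but *incomparable* with MIT-tier moves;
   there the expansion forks (capped by `maxBranches`). Concretely: with a
   BWI–BWH recruitment available, CdvA self-polymerization never competes
   (one scenario); with only a MIT-tier alternative, both orders are
   explored (two scenarios).
4. **One ring.** Self-/group-polymerization moves are available only before
   the first polymerize event: the machinery assembles one ring. Vps4_C
   self-oligomerization is part of the disassembly machinery, not a ring,
   and never appears as an assembly step.
5. **Disassembly and linkers.** When a MIT+AAA protein binds a partner on
   an assembled ring, disassembly fires immediately, removing all
   MIM-linked partners in affinity order, and the scenario ends. A
   disassembler that instead *recruits* a further protein through its MIT
   becomes a linker and cannot also disassemble — a protein cannot bridge
   two partners and sever them at the same time.
6. **Unresolved proteins.** Computed statically: a protein with no enabled
   MIM1/MIM2 route to a disassembler, and no BWI/BWH tether to a protein
   that has one, can never leave the division site. A Snf7-only CdvB3
   paralog is the canonical case.

Determinism is an invariant: identical inputs give identical scenario
lists, events and ordering included.

# Ancestral reconstruction

Characters are family-qualified (`"CdvB:MIM2"` is distinct from
`"CdvA:MIM2"`) because the same domain type on different families evolves
independently. Scoring uses unit-cost Sankoff dynamic programming with an
up/down pass rather than the classical Fitch set rules: the
intersect-or-union shortcut undercounts changes at polytomies (four
children with states {0,0,1,1} cost two changes, not one), whereas the
dynamic program is exact everywhere and reduces to Fitch on binary trees.
The up/down pass yields, per node, the set of states attainable in *some*
most-parsimonious labeling; nodes with both states are reported
`ambiguous`, and no ACCTRAN/DELTRAN convention is silently imposed.

Three resolution policies:

* `none` — keep ambiguity (the honest default; `mapEvents()` refuses it).
* `dollo_single_gain` — one gain on the branch into the most recent common
  ancestor of the presence leaves, losses as shallow as possible below it.
  For a character present at the root itself the gain predates the tree and
  no gain branch exists, so event-count checks use clade-confined
  characters.
* `presence_bias` — an ambiguous root resolves to *present* for characters
  flagged with auxiliary evidence (in the bundled analysis: the characters
  whose genes co-cluster across lineages — Snf7, MIM2 and the three CdvC
  domains), to *absent* otherwise; remaining nodes are then resolved to a
  most-parsimonious labeling consistent with that root, ties toward the
  parent state. This policy is the explicit, reproducible form of resolving
  root ambiguity with gene-cluster and architecture arguments; plain
  ambiguous output remains available.

Branch lengths are ignored (parsimony, not likelihood); likelihood and
Bayesian reconstruction are out of scope, as is tree inference — trees are
consumed as Newick input.

Correctness is checked three ways: exhaustive enumeration of all internal
labelings on trees with up to 7 leaves (including polytomies), agreement
with `phangorn::parsimony` on larger binary trees, and invariance of the
score under rerooting.

# Synthetic data: what it emulates, what it does not

`simulateSequences()` draws background residues i.i.d. uniformly —
deliberately *not* an empirical archaeal composition, because a uniform
null makes the planted-motif benchmark interpretable (any non-planted match
is a background collision, whose probability is controlled by the alphabet).
Planted motifs sample φ/x positions uniformly from their classes with
literal prolines fixed, so recall is 1 by construction, and precision is 1
whenever the background excludes proline (every template requires literal
P). ANCHR planting writes an H-run into the first 30 positions of the
structure track with or without an interior proline.

`simulateDomainEvolution()` flips characters independently per branch with
fixed gain/loss probabilities — no rate heterogeneity, no branch-length
scaling, no correlated gain of interacting domains. Consequently, passing
tests show that the *algorithms* are correct under their own generative
assumptions; they do not show that real archaeal domain evolution satisfies
those assumptions (real sequences have compositional bias and homologous
structure; real domain histories include horizontal transfer, which
parsimony will misread as repeated gain).

The default study conditions used by the tests and the acceptance script:
root-recovery simulations run 500 replicates on the four-lineage tree at
loss probability 0.1 and gain probability 0 from an all-present root (the
recovery threshold of 90% is a property target of this package, not a
published value); the motif benchmark plants one `MIM2_total` per sequence
in 200 sequences of length 80–160 on a proline-free background; scanner
equivalence uses 1,000 random sequences up to length 200. These sizes keep
the full suite in the tens-of-seconds range on one CPU.

# Bundled reference tables

The four tables under `inst/extdata/` (loaded with `loadFixture()`) are
*synthetic constructions*, stated in each file header: they reproduce the
published distribution-level statements about Cdv machineries — 51
organisms of which 37 carry at least one homolog; the eleven-domain
vocabulary; the {Snf7, AAA+ ATPase, MIT, Vps4_C} pan-archaeal core; MIM2
absent from Euryarchaeota, CdvA domains confined to TACK, BWI/BWH to
Crenarchaeota, ANCHR/MIM1 to Asgard; three Crenarchaeota CdvB classes and
two Asgard clades; a Vps4_C/MIT-less CdvC exception on the allowlist — but
invent the per-protein coordinates and the synthetic Asgard sequences.
They are data files, correctable without code changes. Supplementary
per-protein coordinate tables exist in the literature; transcribing them
would change coordinates but none of the distribution-level quantities this
package computes.

# Known limitations

* The mechanism engine is qualitative: it cannot weigh concentrations,
  kinetics or membrane mechanics, and its affinity order is an assumption
  (motivated by observed enrichment sequences), not a measurement.
* Putative-MIM2 and ANCHR thresholds, and the gene-neighbourhood buckets,
  are package defaults without published numeric backing; conclusions
  sensitive to them should be re-run across a range.
* Parsimony reconstruction is blind to branch lengths and to horizontal
  transfer; family-qualified characters treat domain presence as
  independent, which ignores linkage between domains on one protein.
* Family assignment (CdvA/CdvB/CdvC) is consumed as input metadata;
  homology search is out of scope.
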