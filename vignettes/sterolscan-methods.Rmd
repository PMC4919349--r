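---
title: "Surveying bacterial sterol biosynthesis: models and methods"
author: "sterolscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying bacterial sterol biosynthesis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sterolscan)
```

# Scope and data model

`sterolscan` implements the computational workflow of a
bacterial-sterol survey: screen protein collections for sterol-gene
homologs, classify oxidosqualene cyclases (Osc) as lanosterol synthase
(LAS) or cycloartenol synthase (CAS), predict which sterols an enzyme
complement can produce, and confront predictions with observed lipid
profiles. Protein collections are Biostrings `AAStringSet` objects
restricted to the 20 standard residues plus `X` (ambiguities beyond
`X` are rejected at read time and `X` scores as a mismatch downstream,
the conservative treatment for metagenomic fragments). Trees are ape
`phylo` objects; tabular results are `S4Vectors::DataFrame`s; the
central result types (alignment results, diagnostic profiles,
predicted profiles, discrepancy reports) are small S4 classes with
validity checks.

The packaged fixtures transcribe a published survey: 34 genomes with
Osc homologs across four phyla (Proteobacteria sections are normalized
to phylum "Proteobacteria" with the finer grouping — Myxobacteria,
Methylococcales, Rhizobiales — in `taxon_group`), the sterols observed
in 11 lipid-tested strains plus seven previously characterized ones,
and per-strain locus tags for the nine tracked enzyme families. An
`environment_class` column was assigned once during transcription from
the free-text isolation descriptions. Row and column counts are locked
by tests. The survey's own abstract-level accounting mentions a fifth
phylum (Verrucomicrobia) whose strain does not appear as a printed
inventory row; the fixture follows the printed table, so totals here
are 34 records in four phyla.

# Alignment engine and screening statistics

Optimal pairwise alignment (Smith–Waterman local, Needleman–Wunsch
global, affine gaps costing `open + L·extend` per gap of length `L`)
is delegated to `Biostrings::pairwiseAlignment`; the package layer
fixes the reporting conventions and is cross-checked in the test suite
against an independently written full-matrix dynamic-programming
oracle on hundreds of random instances. Defaults are BLOSUM62 with gap
open 11 / extend 1, the common protein-BLAST setting. Two conventions
deserve explicit statement because the screening gates depend on them:

* **Identity and similarity are computed over aligned residue–residue
  columns only** (gap columns excluded). Similarity counts columns
  with a strictly positive substitution score — the BLAST "positives"
  convention. Whether the original survey computed its 30% similarity
  gate over aligned columns or full alignment length is not stated
  anywhere we could verify; the convention used here is documented,
  not asserted as the original one.
* **E-values** use the Karlin–Altschul form `E = K·mn·exp(−λS)` with
  the published gapped-BLOSUM62 constants λ = 0.267 nats per score
  unit and K = 0.041, and a search space defaulting to query length ×
  reference length. Exact reproduction of a BLAST run's e-values would
  require that engine's internal edge-effect corrections; the statistic
  is therefore parameterized (`evalueParams`) rather than hard-coded.

Threshold presets mirror the survey's gates: `osc_genome`
(E ≤ 1e−100, similarity strictly > 30%), `osc_metagenome` (E ≤ 1e−50,
length ≥ 400 aa) and `downstream_erg` (E ≤ 1e−10, identity ≥ 20%).
Comparisons are inclusive for e-value and identity ("equal to or
lower", "minimum") and strict for the similarity gate ("greater
than"), following the gate phrasings. The fragment-length filter is
inclusive (≥ 400) because the retained metagenomic set was described
as "at least 400 amino acids"; a `strictLength` flag switches to the
strict reading.

Redundancy reduction is greedy in input order with founders as
representatives — the original web tool's algorithm is unspecified, so
determinism and simplicity won. The progressive MSA is center-star
(center = maximal summed pairwise score; members merged through their
global alignment to the center, "once a gap, always a gap"): adequate
for the conserved cyclase domains used here, not a MUSCLE replacement,
and a known weakness is joint alignment of unrelated families — the
test suite computes inter-family distances from pairwise alignments
instead. Conserved-block trimming drops columns whose gap fraction
exceeds a threshold, then surviving runs shorter than a minimum block
length; trimming everything yields a zero-width alignment rather than
an error, so callers can distinguish "nothing conserved" from failure.

# Diagnostic-residue classification

Product specificity of Osc correlates with a small set of active-site
residues in human-Osc numbering: T-or-C/Q/V at 381/449/453 indicates a
lanosterol synthase, Y/H/I a cycloartenol synthase, and position 453
alone discriminates (V → LAS, I → CAS). `classifyOsc` maps each query
onto the reference numbering by one global alignment to the single
annotated reference and reads the residues through that mapping.
Design choices:

* Mapping by pairwise global alignment, not an MSA of all queries:
  deterministic and order-independent; for the conserved active-site
  neighborhood the two agree, and an MSA-based cross-check can be
  built from `progressiveMsa` output if wanted.
* "T381/C" is read literally as a two-residue acceptable set at 381
  for LAS. Positions 381/449 never veto the call; they only feed the
  `supportingAgreement` count (0–2).
* A fragment that does not cover position 453 is `indeterminate`,
  never an error; so is any residue other than V/I (parkeol producers,
  for instance, are not classifiable beyond LAS/CAS by this rule, and
  no parkeol-specific diagnostic state is claimed anywhere we could
  verify).
* Reports use 1-based reference numbering throughout; a
  `numberingOffset` supports references whose published numbering does
  not start at their first residue.

The functional-residue audit (`auditFunctionalResidues`) ships with no
default position list beyond the diagnostic triple: the full published
residue set is figure-bound and not reliably enumerable, so users
supply their own table (position, expected residue set) and the tests
exercise synthetic annotations.

# The pathway reachability model

Compounds are feature vectors (`CompoundState`): processing stage
(linear / epoxide / cyclized), C-4 methyl count (0–2), C-14 methyl
flag, ring unsaturations (Δ7, Δ8, Δ9(11), Δ14), side-chain Δ24, and
the 9,19-cyclopropane ring of the cycloartenol route. Reactions are
deterministic state maps guarded by an applicability predicate and an
enzyme-family requirement; reachability is the breadth-first closure
from squalene of reactions the complement satisfies. Choices a reader
should know:

* **Squalene is the root and assumed universally available**; its own
  synthesis genes are out of model (squalene is detected even in
  non-producers, so its observation carries no information here).
  Squalene and oxidosqualene are likewise excluded from
  agreement/orphan accounting.
* **Eukaryotic ordering by default**: C-14 demethylation (ERG11)
  requires the Δ8 (lanosterol-route) skeleton; Δ14 reduction (ERG24)
  requires Δ14; C-4 demethylation removes one methyl per application
  and, in the default ordering, requires C-14 demethylation and Δ14
  reduction to have happened. An `allowC4First` flag lifts the
  ordering to model methanotroph-style single C-4 demethylation at
  other stages. Δ24 reduction (ERG4/DHCR24) applies to any cyclized
  Δ24 state, which is what produces the "-8-en" compound series at
  several demethylation stages.
* **Downstream modifications are gated to the Δ8 route.** The
  cycloartenol branch accepts only Δ24 reduction; this keeps the state
  space within the named compound set and reflects the absence of any
  observed demethylated cyclopropane sterols in the fixtures.
* **Canonical vs relaxed C-4 demethylation**: canonical requires all
  of ERG25/ERG26/ERG27 (the yeast/vertebrate three-protein complex);
  relaxed accepts any non-empty subset, exposing — without asserting a
  mechanism — the open question of how strains missing ERG27 (or all
  three) fully demethylate at C-4.
* **Parkeol** is modeled as an optional LAS product spectrum
  (`parkeolSpectrum`), off by default: parkeol production is observed
  in one planctomycete but no distinct enzyme family is known. The
  Δ8→Δ7 isomerization (lathosterol-type products) exists as an
  optional reaction with no assigned family and is excluded from
  discrepancy logic by default for the same reason.

Naming (`compoundName`) is total: the observation vocabulary and the
Δ14 intermediates get their standard names (lanosterol, cycloartenol,
parkeol, zymosterol, the 4,4-dimethyl/4-methyl cholestenols and
-trienols); any other valid state receives a systematic
cholestane/lanostane descriptor. Naming is bijective over the named
set, which tests verify, so reachable sets can be compared to observed
compound lists by name.

`minimalMissingFamilies` searches subsets of the absent families
exhaustively (≤ 2⁹ closures, each over a state space of a few dozen),
by increasing size and lexicographically within a size — the
deterministic tie-break matters because several five-family
completions can be equivalent.

# Discrepancy analysis

`compareProfile` classifies each accounted observed compound as an
agreement (reachable) or an orphan modification (not reachable). Each
orphan carries the minimal missing family set, the causing unsatisfied
reactions, and a zero-family flag per causing reaction — set when the
genome has *no* member of that reaction's family set, the survey's
strongest discrepancy class (e.g. every tested methanotroph makes
C-4-demethylated sterols with zero C-4 demethylase candidates). Silent
capacity is defined at family granularity: a present family whose
reactions lie on no route from squalene to any observed compound; this
reproduces statements like "C-14 demethylation and C-24 reduction
homologs present but no such sterols observed" without asserting
anything about gene expression. A strain with genes but no sterols at
all is reported as all-silent, not as an error — an unexpressed
pathway is a legitimate observation. One documented consequence of the
model: strains observed to make cycloartenol alongside lanosterol
while carrying only a LAS homolog are flagged with a cycloartenol
orphan in canonical mode; whether that reflects a second cyclase or
Osc side activity is left open.

# Phylogenetics

Distance trees stand in for the original maximum-likelihood analysis,
which depended on an external tool (PhyML, LG+Γ) and a live sequence
database; the package's claims are limited to what neighbor joining
supports — outgroup rooting and clade membership. `neighborJoining`
implements the canonical Saitou–Nei algorithm with two details pinned
down: ties in the Q criterion break by the lexicographically smallest
pair of subtree labels (each subtree represented by its smallest tip
label), and negative branch lengths are clamped to zero with one
warning. NJ exactly recovers additive matrices (topology and path
lengths to 1e−9, tested), and agrees topologically with `ape::nj` on
random matrices. Outgroup rooting verifies that the outgroup is one
side of a split on the unrooted tree and otherwise fails naming the
intruding taxa. Clade monophyly is judged among *labeled* tips, so
unlabeled queries (e.g. metagenomic fragments) nested inside a group
do not break it; each query is assigned the group of its smallest
enclosing clade whose labeled tips are unanimous, else "unassigned".
Poisson-corrected distances −ln(1−p) are capped at 10 as p → 1. No
bootstrap support or model selection is provided, and the original
study's group compositions are not asserted as reproducible (they
depend on external sequence data).

# Synthetic data generator

The generator produces what the survey's sequence side consumed, with
full ground truth, since no machine-readable sequence data are
packaged with the original tables:

* `simulateFamily`: a uniform-random ancestor of 650 residues (cyclases
  run about 600–650 aa), descendants evolved site-independently.
  *Divergence is the per-site replacement probability*: each site is
  replaced by a different residue with probability `d`, so expected
  identity to the ancestor is exactly `1 − d` — a closed form the
  tests verify within ±3 percentage points. `d` is capped at 0.95,
  beyond which pinned class labels stop being meaningful. Diagnostic
  residues at 381/449/453 are pinned to each descendant's intended
  class after mutation. A biased mode weights replacements by
  `exp(BLOSUM62 score)` so that similarity exceeds identity,
  exercising the similarity gate as a distinct criterion. The uniform
  residue background keeps identity expectations closed-form; real
  proteome composition is not emulated.
* `fragmentRecords`: contiguous substrings with lengths drawn from a
  user list (default 350/450, straddling the 400-residue metagenome
  filter) and uniform offsets.
* `simulateCohort`: strains are drawn from base complements chosen so
  that *every present family is used* by the forward-simulated
  observation (the reachable vocabulary compounds under canonical
  mode). Injections then create the only discrepancies: an orphan is
  an observed compound not reachable under the final complement; a
  silent family is added only if it leaves the reachable vocabulary
  unchanged, and orphan candidates that would recruit the injected
  silent family onto a route are excluded so the two injections stay
  independent. Injection rates default to 0.2 each. By construction,
  discrepancy analysis must recover exactly the injected flags —
  precision = recall = 1 — which is the end-to-end test.

What passing these tests shows — and does not show — about real data:
the generators have no indels (fragments, not gaps, model length
variation), no rate heterogeneity across sites, no codon structure,
and lipid "observations" have no detection noise or abundance
dimension. Recovery being exact on synthetic cohorts validates the
bookkeeping, not the biology of borderline cases.

# Orchestration, sizes and limitations

`runPaperReproduction` recomputes the fixture accounting (homolog
totals per phylum/group/environment, tested-strain counts, per-strain
predictions, discrepancy reports, cohort aggregates); every number in
its summary is recomputed from the fixture files at run time.
`runSyntheticValidation` runs the generators and scores recovery
against their truth tables. These two functions, together with the
exported per-stage functions, are the package's interface; there is no
shell entry point — an R analyst drives the pipeline from R scripts,
and `scripts/acceptance.R` shows the canonical invocation.

Default problem sizes — 50-member families at divergences 0.05/0.2/0.3,
100-strain cohorts, 200 random alignment instances of length ≤ 60 for
the oracle cross-check — keep the whole validation in the tens of
seconds on one core while leaving each statistical check comfortably
powered (at family size 50 and sequence length 650, mean identity
estimates have standard errors far below the ±3-point test band).

Known limitations: no profile/HMM search (screening is pairwise
against one reference); no stereochemistry, kinetics or flux in the
pathway model; C-24 alkylation is out of model (no surveyed strain
methylated the side chain); discrepancy analysis is presence/absence
at family level and deliberately silent about expression or growth
conditions; and the phylogenetics module does not attempt to reproduce
ML tree shapes.
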