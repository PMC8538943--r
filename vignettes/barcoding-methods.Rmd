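---
title: "Identifying cryptic insect larvae by COI barcoding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying cryptic insect larvae by COI barcoding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvalID)
```

## The problem

Several turfgrass-feeding billbug species (*Sphenophorus* spp.) co-occur in
North American lawns and sports turf.  Their adults are separable
morphologically, but the damaging, soil-dwelling larvae are not: larvae of
different species look alike, which blocks any direct study of
species-specific seasonal biology.  `larvalID` implements the standard
molecular workaround — COI barcode identification of larvae against a
reference library of sequenced, morphologically identified adults — plus
the downstream analyses that turn identified larvae into phenology and
species-composition tables.

The package covers five stages, each usable on its own:

1. **Consensus contigs** from paired forward/reverse Sanger-style reads
   (`build_consensus()`).
2. **Alignment**, either a built-in progressive aligner
   (`progressive_msa()`) or externally aligned FASTA (`read_alignment()`).
3. **Distances**: p-distance, percent similarity, and Kimura-2-parameter
   (K2P) distances with pairwise deletion (`distance_matrix()`), plus
   barcode-gap analysis (`barcode_gap_analysis()`).
4. **Trees**: neighbour joining with nonparametric bootstrap
   (`neighbor_joining()`, `bootstrap_tree()`).
5. **Assignment and phenology**: threshold and tree-placement species
   calls (`assign_species()`, `assign_batch()`), head-capsule binning and
   seasonal tables (`build_phenology()`, `composition_summary()`).

## Distance model

For two aligned rows, only columns in which both sequences carry an
unambiguous `A/C/G/T` are compared (*pairwise deletion*; gaps and IUPAC
ambiguity codes are excluded).  With $P$ the proportion of transitions
(A↔G, C↔T) and $Q$ the proportion of transversions among compared sites,

$$ d_{K2P} = -\tfrac{1}{2}\log(1 - 2P - Q) - \tfrac{1}{4}\log(1 - 2Q), $$

the classic two-parameter correction.  Percent similarity is
$100\,(1 - P - Q)$ — the uncorrected scale on which the identification
threshold is expressed.  When a logarithm argument is non-positive the
distance is *undefined* (saturation) and the package raises an error
rather than clamping: a silently clamped distance would corrupt the
barcode-gap statistics downstream.  K2P equals the Jukes–Cantor distance
when $Q = 2P$, and never falls below the p-distance; both identities are
verified in the test suite.

## The two identification methods

**Similarity threshold.**  Each query is compared to every labelled
reference row; mean percent similarity is computed per species
(`avg_similarity_by_species()`, the query's own row excluded).  Species
reaching the threshold are candidates and the best-scoring candidate is
called.  The default threshold is **91.25%**, calibrated on the most
variable species in the billbug complex; it is configurable
(`assignment_config()`), and two candidates within 0.5 percentage points
are flagged as a near tie in the report's notes.  Only labelled references
enter the species means: folding co-collected unidentified larvae into the
pool would make assignment circular.

**Supported-clade placement.**  A neighbour-joining tree of the combined
reference + query alignment is bootstrapped (column resampling,
`bootstrap_tree()`), and each query is read off the tree: the call is the
species of the smallest clade — in the unrooted sense, a bipartition
side — that contains the query and at least one reference, has bootstrap
support strictly above the threshold (default **70%**), and contains
references of only one species.  Two wrinkles deserve explanation:

* *Smallest supported clade, not support of the smallest clade.*  Shallow
  intraspecific nodes are rarely bootstrap-supported even when the species
  clade itself is rock solid; gating the very smallest containing clade on
  its support would leave most larvae unassigned.  The implementation
  therefore searches upward for the smallest clade that *is* supported,
  mirroring how a larva is actually read off a published bootstrap tree.
  The full leaf set, trivially present in every replicate, acts as the
  last-resort "clade", which also gives 3-taxon trees (no internal edges)
  a defined behaviour.
* *Ambiguous placements are refused.*  In an unrooted tree a clade is one
  side of an edge, so a query can simultaneously lie in two minimal
  supported clades that carry different species (each being the complement
  of a cohesive group elsewhere — the support then reflects the other
  group's cohesion, not the query's affinity).  When minimal supported
  clades disagree on species the query is left unassigned instead of
  picking a side.

`assign_species()` runs both methods and combines them under a
`conflict_policy`; the default `require_agreement` is conservative: a
disagreement between two species yields `"conflict"`, while a single
unassigned method defers to the other.

**Barcode gap.**  Identification by either method is only meaningful if
intraspecific and interspecific distances separate.
`barcode_gap_analysis()` splits all pairwise distances by label, reports
per-species `max_intra`, `min_inter` and their difference, and bins the
pooled distributions into a shared histogram (30 bins by default over the
pooled range; single-member species get `max_intra = NA` and no gap
claim).  K2P is the default gap metric; the similarity threshold method
deliberately stays on the raw percent scale — the two scales coexist and
are reported separately.

## Alignment machinery

The pairwise aligner is a Needleman–Wunsch/Gotoh dynamic program (C++)
with match +1, mismatch −1 and affine gap cost
`gap_open + (L−1)·gap_extend`; ambiguity codes match whenever their base
sets intersect; tie-breaking is deterministic (diagonal, then up, then
left).  `overlap` mode makes terminal gaps free and is used to join
forward and reverse reads.

The default `gap_open` is **−5**, not the linear −2: on length-conserved
barcodes there are no true indels, and with cheap gap opening the optimal
global alignment of two 640 bp sequences at ~15% divergence occasionally
contains spurious off-by-one gap regions wherever a chance shifted match
outweighs two cheap gaps.  With −5 the simulated no-indel complexes align
gap-free (verified in the tests), and genuinely indel-bearing inputs still
align correctly.

`progressive_msa()` builds a guide tree by neighbour joining on
p-distances of all pairwise alignments and merges profiles leaf-to-root by
profile–profile alignment (profiles are fractional base-frequency columns).
De-gapping any output row always reproduces its input sequence.  This
aligner is intended for the low-divergence, length-conserved inputs the
simulator produces and for self-contained testing; for publication-grade
work on indel-rich loci, align externally and ingest with
`read_alignment()` — every downstream result is defined relative to the
supplied alignment, whose column count is carried in reports.

## Consensus contigs

`build_consensus()` reproduces the classic Sanger chain: quality-trim both
reads, reverse-complement the reverse read, join by overlap alignment,
then resolve each column — agreement wins, then the higher-quality base,
else `N` (with no quality data a disagreement is always `N`; the
conservative stand-in for inspecting chromatograms by hand).  Primers are
excised if found within 60 bp of the ends, exactly or with one mismatch
(Sanger ends are noisy and primers short).  Defaults: trimming threshold
20, window 10 — conventional Sanger practice; within the first acceptable
window, remaining individually sub-threshold end bases are also dropped.
An aligned overlap below 60% identity or shorter than 15 columns raises a
"reads do not overlap" error (a handful of chance matches between
non-overlapping reads should not count as an overlap).  A consensus
outside 600–700 bp — the usual COI barcode span — is flagged with a
warning rather than an error so other loci (ITS2, 18S) remain usable.

## The simulator: what it emulates, and what it does not

`simulate_reference_complex()` generates a six-species complex of 640 bp
COI-like sequences.  A random root is mutated along a star species tree to
half the interspecific distance (default K2P 0.15 between ancestor pairs);
members are mutated from their ancestor at half the species' intraspecific
level (default 0.02).  One species (default the first) is *variable*:
intraspecific K2P 0.06, realised as two subclades with a deep split and
shallow tips — emulating the observed structure where the most variable
billbug species shows similarity down to ~92.5% and splits into two
well-supported geographic subclades, while the rest stay above ~95%.
Substitutions follow the K2P process with transition/transversion rate
ratio κ = 4 (a typical insect mitochondrial bias).  For a target distance
$d$ the per-site event probabilities are

$$ P = \tfrac14 + \tfrac14 e^{-4\beta t} - \tfrac12 e^{-2(\alpha+\beta)t},
   \qquad Q = \tfrac12 - \tfrac12 e^{-4\beta t}, $$

with $\beta t = d/(\kappa+2)$, $\alpha = \kappa\beta$, so the K2P
estimator recovers $d$ exactly in expectation (the tests check this at
10,000 sites).  There are **no indels**: COI barcodes are
length-conserved, and a gap-free generator keeps the aligner's task
honest and checkable (the true homology is the identity mapping).

`simulate_larval_season()` emulates a May–July collection campaign:
per-site species mixtures (defaults follow the published cool-season
0.68/0.12/0.20 and warm-season 0.92/0.06/0.02 compositions), five instars
with head-capsule means 0.5/0.8/1.2/1.6/2.0 mm (sd 0.08) — *synthetic*
values chosen to be consistent with the conventional small/<1.0 mm,
medium/1.0–1.7 mm, large/>1.7 mm bins, not estimates — and a seasonal
progression whose mean instar advances linearly across the window.
`simulate_reads()` wraps templates in real COI primer sites, adds
low-quality 3′ tails and optionally tail-concentrated base-call errors.

What passing tests on these simulations do **not** show: robustness to
real chromatogram artefacts (heterozygous peaks, dye blobs), indel-rich
loci, NUMT contamination, incomplete reference libraries, or species whose
true divergence structure violates the barcode gap.  The gap analysis is
the in-package guard for the last case; the others are out of scope.

## Numerical and design choices

* Distance matrices keep input row order; saturation is an error, never a
  clamp; matrices are exactly symmetrised by construction.
* Negative NJ branch-length estimates are clamped to 0 and counted in the
  `clamped_edges` attribute (standard practice).
* NJ + K2P + bootstrap replaces a maximum-likelihood (GTR+Γ) workflow:
  identification only needs well-supported clades, ML itself is seeded
  from NJ trees, and the substitution keeps the pipeline self-contained
  and fast.  Bootstrap values will differ numerically from ML bootstraps
  on the same data; the >70% rule is what identification depends on.
* Bootstrap replicates whose resampled columns leave a pair with no
  comparable sites (or saturated) are skipped and counted; more than 10%
  skipped raises a warning.  Supports are percentages of *successful*
  replicates.
* Head-capsule boundary widths (exactly 1.0 or 1.7 mm) fall in the
  *medium* bin — the only reading consistent with "< 1.0", "1.0–1.7",
  "above 1.7".
* Composition percentages round half away from zero (so 19.5% → 20%,
  matching the published 28/41 → 68%, 8/41 → 20% table); raw counts are
  always reported alongside so any rounding can be audited.  The shipped
  `billbug_larval_counts.csv` reflects the published per-species counts;
  its warm-season row (33/3/0 of 36) reproduces the dominant species'
  92% exactly, while the published minor-species percentages (6%/2%) do
  not reconcile exactly with any integer counts — the raw counts let
  either reading be audited.
* The similarity threshold defaults to 91.25%; the neighbouring published
  figure of "above 90%" describes the same data more loosely, and the
  threshold is a configurable input, not a fitted quantity.
* All simulators are bit-reproducible given their seeds; the pipeline
  driver derives every stage seed from one master seed, and bootstrap
  resampling restores the caller's RNG state.

## Problem sizes used in the checks

The shipped test suite and acceptance script exercise: 102 simulated
larval queries against 30 references (640 bp, 100 bootstrap replicates)
for parameter recovery; 200 random 5–6-leaf additive matrices for NJ
consistency; 200 simulated read pairs per error regime for consensus
recovery; and exhaustive path enumeration up to 6×6 bp for alignment
scores.  These sizes keep a full run in the low minutes on one core while
leaving each property statistically meaningful.

## Worked example

```{r example, eval = FALSE}
library(larvalID)

out <- run_pipeline(tempfile("run"), seed = 7,
                    config = assignment_config(bootstrap_replicates = 100))
out$gap                    # per-species barcode gap
head(out$report)           # per-larva identification calls
out$composition            # species percentages per grass type
```

Every stage writes its artifact (FASTA, CSV, Newick) into the output
directory, so any intermediate can be audited or re-entered into the
pipeline — the same layout the command-line wrapper
(`inst/scripts/larvalid`) exposes as subcommands.

## Known limitations

* The built-in aligner has no iterative refinement and is not meant for
  indel-rich loci (use an external aligner there).
* Plain NJ only — no BioNJ variance weighting, no ML/Bayesian inference.
* No species-delimitation machinery (ABGD/GMYC/bPTP): the threshold is an
  input, not something the package optimises.
* Instar determination from head-capsule mixtures (Dyar's rule,
  degree-day models) is deliberately out of scope; larvae are reduced to
  the three conventional size classes.
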