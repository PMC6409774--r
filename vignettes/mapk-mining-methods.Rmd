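---
title: "Mining MAPK-cascade kinases from plant proteomes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining MAPK-cascade kinases from plant proteomes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapkminer)
```

## The problem

Mitogen-activated protein kinase (MAPK) cascades relay stress signals in
plants through three kinase tiers; the terminal MAP kinases (MPKs) are
phosphorylated on a T(D/E)Y motif in their activation loop (the
"T-loop"), and their upstream MAP kinase kinases (MKKs) are
dual-specificity kinases activated at an S/TxxxxxS/T motif and
recognizable by a conserved GTxxYMSPER activation segment. Cataloguing
these two families in a newly sequenced genome is a standard comparative
exercise: screen the proteome for kinase-like candidates, confirm them
with family-diagnostic sequence motifs, place them into clades against a
labelled reference panel, name them by orthology, and characterize their
gene structure, physicochemical properties, expression response, and
evolutionary rates. `mapkminer` implements that whole funnel as a set of
composable, individually testable stages.

## The screening model

The first gate is a profile hidden Markov model built from an alignment
of reference kinases (`build_profile()`). The architecture is a
Plan-7-style chain of match/insert/delete states:

* Alignment columns whose gap fraction is below `match_rule`
  (default 0.5) become match states.
* Emissions and transitions receive a Laplace pseudocount
  (default 1.0) and are normalized; the background is uniform (1/20).
* Scoring is local Viterbi in log2-odds (`viterbi_score()`): flanking
  unaligned residues are free, entry into any of the L match states
  costs log2(1/L), exit after any match state is free. The ambiguity
  letter X emits at the background (score 0), so it contributes no
  evidence in either direction; an all-X sequence has no defined score.

Forward/posterior scoring is deliberately omitted: Viterbi-only keeps an
exact brute-force oracle feasible, and the test suite verifies the
dynamic program against full path enumeration on small models.

E-values come from a Gumbel fit (`calibrate()`): `n_null` sequences
(default 1000) are drawn i.i.d. from the reference-set residue
composition with lengths resampled from the reference lengths, scored,
and fitted by moments plus a maximum-likelihood polish. The e-value of a
hit is the database size times the fitted upper tail, and the screening
threshold is an e-value of 0.01 (`search_proteome()`), applied to the
full-sequence score. The Monte-Carlo tail check in the tests accepts the
fit if the predicted and empirical tails at the 99th percentile agree
within a factor of three — extreme-value calibration on a thousand
samples is not more accurate than that, which is also why the screening
gate is followed by motif confirmation rather than trusted on its own.

## Motif confirmation

Signature motifs use a deliberately small grammar (`compile_pattern()`):
capital letters match exactly, `x` matches any residue, `(A/B/...)` is a
single-residue alternation; patterns have fixed width. Fixed width keeps
scanning exactly equivalent to naive sliding-window matching, which the
suite checks by exhaustive enumeration. Windows containing X never match
(conservative evidence). Positions are reported 1-based, consistent with
the 1-based inclusive genomic coordinates used everywhere in the
package.

The catalogs (`signature_catalog()`, shipped as an editable TSV) encode
the family rules: for MPKs the catalytic C-loop `HRD(L/I)KPxN` and the
T-loop `T(D/E)Y` are mandatory, while the P-loop, the ATP anchor,
`DFGLAR` and `TRWYRAPE` are optional and their absence is only flagged —
real families contain members that lack the P-loop, so making it
mandatory would silently discard true kinases. The C-loop accepts the
relaxed form `D(L/I/V)K` (flagged) when the strict pattern fails, with a
one-mismatch tolerance that admits the naturally occurring
phenylalanine variant. For MKKs, `GTxxYMSPER` is mandatory with a
near-match budget of one mismatch at non-wildcard positions, because
single-residue variants of this motif (e.g. `...MAPER`, `...MSPEK`)
occur in real panels; the budget is a package decision, surfaced as a
parameter, and budget 0 reduces everything to exact matching.

Motif order along the kinase domain (C-loop < DFGLAR < T-loop <
TRWYRAPE) encodes the anatomical fact that the activation loop lies
between kinase subdomains VII and VIII without relying on positional
coordinates, so it is robust to length variation. The order check is
applied to whichever of those motifs are present (vacuous when at most
one is found); with all four present it is the strict chain.

A candidate is accepted (`call_family()`) iff its HMM e-value passes,
all mandatory motifs are found, and the order holds. When both family
screens accept the same protein, `identify_families()` resolves the
conflict in favor of the lower e-value — in practice a true MKK scores
orders of magnitude better against the MKK profile than against the MPK
profile, and this resolution is what protects precision against chance
T(D/E)Y tripeptides (about 8% of ~400-residue sequences contain one by
chance).

## Clade assignment and nomenclature

Clades A–D are assigned by the best Smith–Waterman hit against the
same-family references (`assign_clade()`); ties break by reference-table
order. The T-loop convention (TEY in clades A/B, TDY in C/D) is checked
but never overrides the top hit: discordant members are real (clade C
contains TEY carriers), so the discordance is recorded in
`tloop_consistent`, not corrected. For MPKs a 16–17-residue common
docking (CD) site consensus per clade corroborates the call: the
reported `docking_distance` is the minimum Hamming distance of any
window in the C-terminal 60 residues to the assigned clade's consensus
(the consensi are published without coordinates, hence the window
search). MKK candidates are additionally matched against the
clade-specific S/T spacing grammars.

Names follow the orthology convention (`assign_names()`): species
prefix + family + homolog number of the top reference, and a hyphenated
index when several accepted genes share a (family, number). The suffix
order is chromosome natural order, then start coordinate — a
data-derived rule, so renaming is stable under input permutation. The
inverse parser (`parse_gene_name()`) is exact.

## Pairwise alignment and trees

Alignment uses BLOSUM62 (from Biostrings' matrix data) with affine gaps
costing `gap_open + L * gap_extend` per gap of length L (defaults −11
and −1, the BLAST-style charging). The Needleman–Wunsch and
Smith–Waterman kernels are compiled code with a fixed traceback
preference (diagonal, then vertical, then horizontal) so alignments are
deterministic; scores are validated against exhaustive alignment
enumeration on short sequences.

Trees are distance-based: p-distance with pairwise gap deletion, Poisson
correction d = −ln(1 − p), Saitou–Nei neighbor joining (via `ape`), 100
column-resampling bootstrap replicates mapped onto the full-data tree by
bipartition matching, and outgroup rooting. A likelihood tree under a
substitution model with rate heterogeneity would be the more powerful
instrument; the distance stand-in was chosen because the pipeline's
clade calls rest on reference top-hits, with the tree as corroboration,
and because NJ on additive matrices admits an exact oracle. This is a
documented deviation, not an equivalence claim. Two numerical guards
matter: NJ can produce slightly negative branches on non-additive input
(clamped to zero with the deficit moved to the sibling so path lengths
through the parent are preserved), and bootstrap resamples of very
distant pairs can hit p = 1, where the Poisson correction diverges —
`distance_matrix()` caps such pairs at `1 − 0.5/width` before
correction. The two-argument operations `p_distance()` /
`poisson_correct()` keep the strict error so saturation is never
silent at the API surface.

## Protein properties

Net charge is the Henderson–Hasselbalch sum over ionizable groups;
the pKa set is the Bjellqvist-style table used by the standard
compute-pI convention (N-terminus 7.5, C-terminus 3.55, C 9.0, D 4.05,
E 4.45, H 5.98, K 10.0, R 12.0, Y 10.0), shipped as an editable data
frame because published tools do not document a single canonical set;
residue-specific N-terminal variants are not applied. pI is found by
bisection on [0, 14] to 1e-3 (termini guarantee a crossing) and is
validated against a 1e-4 grid search. Molecular weight uses average
(not monoisotopic) residue masses plus one water; sequences containing
X have no defined mass and error out rather than guessing.

Family summaries over an annotation table report means over *all* rows,
short outliers included, with the length mean also integer-rounded since
that is the printed convention of such tables. The packaged sunflower
table (36 genes: 28 MPK, 8 MKK) is the desk fixture: the suite checks
that the summaries reproduce its published aggregates exactly. Computed
pI on arbitrary sequences is validated against the grid-search oracle,
not against the fixture's printed pI column, which was produced by an
external tool with undocumented constants.

## Expression analysis

The expression stage consumes a TPM matrix with a design of two tissues
x {control, SA, NaCl, Peg} and exactly one control per tissue — a pooled
design without replicates. That design supports descriptive contrasts
only, so the package computes `log2((TPM + 1)/(TPM_control + 1))`
(pseudocount 1 TPM, a flag) and deliberately implements no
differential-expression inference; fold-change thresholds are reporting
filters. Profiles are standardized per gene with the sample (n−1) SD
(a switch selects the population convention; the upstream tool's
convention is not documented), clustered with k-means (k = 4, the
reported group count; 50 k-means++ restarts from a seeded generator,
best WCSS kept, each run checked against its initial-assignment WCSS)
and with correlation-distance average linkage, whose merge heights the
suite verifies against a brute-force agglomeration. The display matrix
is clipped at |Z| = 4. Whether to cluster standardized fold changes or
standardized TPM is genuinely ambiguous in this kind of workflow; the
package clusters standardized log2FC and exposes the matrix choice to
the caller, who can pass any matrix into the clustering functions.

## Evolutionary statistics

The relative rate test takes an aligned triplet (two ingroups, one
outgroup), discards sites with any gap or ambiguity, counts
substitutions unique to each ingroup lineage, and refers
`(m_a − m_b)²/(m_a + m_b)` to chi-square with 1 df (`chi2_upper_tail()`
delegates to `pchisq`). Tajima's D runs on amino-acid alignments after a
95% site-coverage filter; S counts columns with ≥2 observed states
(multi-state columns once), π is the mean pairwise difference count with
pairwise deletion, and the full a1…e2 coefficient chain is exposed in
the result and checked coefficient-by-coefficient against an independent
closed-form recomputation for n = 4…30. π is reported on both the count
and per-site scales; D uses the count scale consistently with S. The
infinite-sites assumption behind D is violated on protein data whichever
convention one picks; the package states its convention rather than
correcting for it.

## What the synthetic generators emulate — and what they do not

Every stage is exercised on generated data with planted truth
(`make_reference_set()`, `make_proteome()`, `make_gff()`,
`make_expression()`, `make_triplet()`; all pure functions of their
seed). The generators emulate the study conditions: a reference panel of
one archetype per family and clade carrying the clade-diagnostic motifs
(TEY in A/B, TDY in C/D, clade docking consensi, MKK spacing patterns),
references per homolog number at 5% within-clade divergence; proteomes
of 10 + 5 planted kinases at 15% divergence (motif windows protected),
20 kinase-like decoys with the activation motif ablated, and 200
composition-matched shuffles; clade-conditioned exon counts (e.g.
3-exon clade-B MPKs, intronless MKK clades C/D) with paralog groups
dispersed across chromosomes; control TPM drawn log-normal (meanlog 3,
sdlog 1) with treatment = control × 2^(planted + noise). Accidental
T(D/E)Y tripeptides arising in mutated scaffolds are scrubbed outside
the designated window so that the planted activation loop is the only
one — in decoys, everywhere.

These are deliberately clean worlds. Real proteomes have kinase
paralogs at varying divergence, domain architectures that shift motif
spacing, alternative isoforms, and compositional bias; real reference
panels are gapped alignments; real expression data have replicates (or
should). Passing the planted-truth suites therefore demonstrates that
the algorithms are implemented correctly and that the funnel's logic
(screen → confirm → resolve) behaves as designed, not that these
parameter defaults are optimal on any particular real genome. Identification
precision/recall bounds (≥ 0.95) are evaluated pooled over 20 generator
seeds: per-seed proportions on 15 planted genes are too granular for a
meaningful bound, and chance motif occurrences in decoys make single
seeds noisy.

## Problem sizes and reproducibility

The test suite and the acceptance script use the study-condition sizes
throughout: 235-protein proteomes over 20 (tests) or 10 (script) seeds,
1000-sequence (500 in loops) null calibrations, 100 bootstrap
replicates, 500/200 replicate operating-characteristic runs for the
relative rate test at α = 0.05, and 200-sequence batches for the pI
oracle. Every stochastic step takes an explicit seed and routes through
an RNG-state-preserving wrapper, so identical configurations reproduce
byte-identical outputs (`run_pipeline()` asserts this in the tests).

## Known limitations

* The profile HMM is Viterbi-only, uncalibrated per-domain: multi-domain
  proteins are scored by their best single local hit.
* Gumbel calibration assumes the null composition resembles the
  reference composition; strongly biased proteomes would need a
  proteome-derived null.
* The motif grammar has no variable-length gaps; motifs with variable
  spacers must be expressed at fixed width or as several patterns.
* Trees are distance-based (see above); no rate heterogeneity.
* Homolog-number recovery (and hence naming) inherits the top-hit's
  number; equally scoring references with different numbers resolve to
  the first in the table, which is recorded but arbitrary.
* The expression stage is descriptive; with replicated designs a
  count-model framework should replace it.
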