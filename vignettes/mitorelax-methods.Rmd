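---
title: "Comparative mitogenomics and selective relaxation with mitorelax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative mitogenomics and selective relaxation with mitorelax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorelax)
```

## Scope

mitorelax characterizes annotated avian mitochondrial genomes and tests
for shifts in selective constraint on their protein-coding genes. It was
built around the kind of study that assembles a pair of closely related
mitogenomes (e.g. New World vultures), compares them against related taxa
(composition, skews, codon usage, per-gene identity, control-region
organization), and then asks whether particular clades — say, obligate
soaring scavengers — show *relaxation* of purifying selection (omega =
dN/dS drifting toward 1) in particular genes.

Alignments and trees are inputs: the package deliberately does not
assemble reads, annotate de novo, build multiple alignments, or search
tree space. A complete-codon filter (`cleanCodonColumns`) is the only
alignment hygiene provided.

## Genome representation and transcriptional exceptions

A `Mitogenome` couples a `DNAString` with a typed feature table.
Internally every coordinate is 0-based half-open on the heavy (H) strand;
GenBank and TSV output is 1-based inclusive, BED stays 0-based. Per-gene
statistics are computed on the *sense* strand, which is why the
light-strand ND6 shows its characteristic C+G enrichment and a flipped GC
skew relative to the genome strand.

Two mitochondrial quirks get first-class treatment:

* **Incomplete stop codons.** A CDS ending in `T` or `TA` flush against
  its downstream tRNA is completed to `TAA` by mRNA polyadenylation.
  `detectIncompleteStop` classifies `complete` / `truncated_T` /
  `truncated_TA` from the CDS length modulo 3 and the terminal
  nucleotides, and records whether the feature abuts its neighbor.
* **The ND3 frameshift.** Several bird lineages carry one extra
  nucleotide in ND3 that the ribosome skips. `detectFrameshift` models
  exactly that: if the naive frame hits a premature stop, it searches all
  single-nucleotide skips and reports the *earliest* one that yields a
  stop-free frame ending in a valid (possibly completable) stop. Earliest
  wins because adjacent skips are frequently equivalent and a
  deterministic convention is needed.

The synthetic genome generator plants its frameshift mid-codon
(offset = 1 mod 3) with an inserted `T` followed by `AA`. This makes the
planted offset provably the earliest rescuing skip — any earlier skip
re-reads the inserted T at a codon start as `TAA` — so recovery tests are
exact rather than probabilistic. A codon-aligned plant cannot have this
property (the three nearest skips would all have to turn the same final
codon into a stop, which the stop-codon table does not allow), which is
why the generator requires a mid-codon offset.

## Composition, codon usage, divergence

`baseComposition` excludes Ns from denominators and rejects other
ambiguity codes (assembled mitogenomes should not contain them). RSCU
follows the textbook definition within synonymous families of the
vertebrate mitochondrial code (so the Met family is ATA+ATG and Trp is
TGA+TGG); family mean RSCU is exactly 1 for any used family, a property
the tests assert with exact arithmetic.

Pairwise identity is computed on global alignments
(Needleman–Wunsch with affine gaps via Biostrings) under pair deletion:
columns containing a gap are excluded from the denominator. This choice
stabilizes percentages on indel-rich control regions and is stated
because it changes the number. Default scores are match/mismatch/open/
extend = 1/−1/−5/−1; the identity matrices are parameter-dependent and
the parameters are configurable.

Entropy profiles use per-column Shannon entropy in bits over non-gap
residues (columns with fewer than two non-gap residues contribute 0),
averaged in 50-bp windows with step 1 and centers reported in 1-based
alignment coordinates. Bits were chosen (the base is otherwise
arbitrary) so that a 1:1 split column contributes exactly 1 and a single
such column makes a 50-bp window mean of 0.02.

## Control-region annotation

The three CR domains are anchored on two conserved elements: domain I
runs from the CR start to the F box, domain II to CSB1, domain III to the
CR end. Missing anchors leave boundaries explicitly unresolved — absence
(e.g. of ETAS2, CSB2, CSB3, which several vulture CRs lack) is reported,
never forced.

The motif library is configuration, not code: a TSV of IUPAC consensus
strings with per-motif mismatch allowances, shipped as condensed cores
assembled from the avian D-loop literature. The published record does not
fix exact consensi, so the file is meant to be edited or replaced; the
scanner (`findMotif`, built on `Biostrings::matchPattern` with
pattern-side ambiguity) treats it as data.

`findStr` reports maximal tandem arrays with full copies and the partial
remainder separately; whether a ≥50%-length partial should count as a
copy differs between published repeat counts, so it is a flag
(`countPartial`). Units are reported in lexicographically minimal
rotation plus the as-found phase; overlaps resolve to the longer span,
then the smaller unit. Units whose primitive period is itself a
reportable unit length are suppressed (a `TGTG` unit is just `TG`), but
a homopolymer run is reported at the smallest allowed unit length —
dedicated homopolymer calls belong to `findPolyTract`, which also finds
the TA islands that interrupt raptor poly-C tracts. `findHairpin` is a
structural plausibility screen (perfect complementary arms, G:C = 3,
A:T = 2, greedy non-overlapping selection), not thermodynamic folding.
All three string scanners are validated against exhaustive oracles on
randomized small instances.

## The codon-model engine

The selection machinery is a GY94-style codon model over the 60 sense
codons of the vertebrate mitochondrial code. Rates are
`pi_j`, `kappa pi_j`, `omega pi_j`, `omega kappa pi_j` for synonymous
transversions/transitions and nonsynonymous transversions/transitions;
multi-nucleotide changes are inaccessible. Codon frequencies default to
F3x4 (F61 can be supplied as a `pi` vector). The generator is scaled so a
unit branch length is one expected substitution per codon site; for
mixture models one common factor — the class-proportion-weighted mean
rate of the background-group matrices — rescales all classes, so branch
lengths keep a single interpretation while proportions are optimized.

Likelihoods come from Felsenstein pruning in compiled code, with
per-pattern scaling against underflow and transition matrices from
eigendecomposition of the pi-symmetrized reversible form (falling back
to scaling-and-squaring if the symmetric eigensolver fails). The pruning
path is checked against brute-force enumeration over internal states on
hundreds of random small instances to 1e-8.

Implemented omega structures: `M0`, `branch`, `free_ratios`, `M2a_rel`
(classes omega0 < 1, 1, omega2), clade model C (`CmC`: class 2 omega
divergent per branch group) and branch-site model A with its omega2 = 1
null. LRTs use `2 * delta lnL` against chi-square with df equal to the
free-parameter difference; for branch-site model A the conservative
chi-square(1) reference is used rather than the 50:50 mixture. The CmC
null is M2a_rel with df = number of extra divergent-omega parameters.

### Optimization

Fits maximize over kappa, omega values and class proportions
(additive-logistic transform) with L-BFGS-B under bounds
omega in [1e-4, 50], kappa in [0.1, 99], to |delta lnL| < 1e-6, with
branch lengths fixed to the input tree (joint optimization is out of
scope; reusing a fixed topology and lengths is the common practice the
package mirrors). Ridge-prone mixture surfaces get multi-start
protection: five seeded starts (one informed, four random) are scored,
the two most promising receive short exploratory runs, and the winner is
polished to convergence. Fitting the alternative of a nested pair can be
warm-started from the null fit (`initFrom`), which also guards the
nested-likelihood ordering. All seeds are explicit; fits are
deterministic given `seed`.

Nei–Gojobori (1986) counting (`ng86dnds`, equal pathway weighting,
stop-crossing pathways skipped when avoidable, Jukes–Cantor correction)
is implemented independently of the ML engine and serves as its counting
cross-check; `dS = 0` yields an explicit `undefined` status rather than
an infinite omega.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions and carry machine-readable
truth records.

* `simulateMitogenome` realizes a condor-like record: 37 genes + CR in
  the ancestral avian order (shipped as a chicken-order reference data
  file), heavy-strand composition target A/C/G/T = 31/32/13/23% with a
  C+G-enriched light-strand sense target, truncated stops in COX3, ND4
  and CYTB (completed by two 3' A residues), the ND3 insertion, and a
  1214-bp CR (domains 400/500/314 nt) carrying ETAS1, the F/E/D/C boxes,
  CSBa/CSBb, the Bird Box, CSB1, a poly-C tract with TA island, an
  AACAAAC x 20 repeat array and a GC stem hairpin at planted
  coordinates.
* `simulateCodonAlignment` evolves sites along a labeled tree by
  sampling from `expm(Q t)` per branch with per-site mixture classes;
  the state space contains no stop codons, so none are ever emitted.
  The default tree is a balanced two-clade topology (tip branches 0.3,
  internal 0.15 substitutions/codon) — desk-scale but in the range of
  mitochondrial protein-gene divergences among raptor families.
* `simulateCRHaplotypes` mutates a reference CR with per-domain rates
  (default hot domain I, cold domain III, matching the intraspecific
  variability pattern of condor CRs) or plants an exact number of
  segregating sites per domain.

What the generators do **not** emulate: indels and alignment error,
within-genome rate heterogeneity beyond the modeled site classes,
sequencing artifacts, heteroplasmy, base-composition
non-stationarity, and selection regimes outside the implemented model
family. Passing recovery tests on these data therefore demonstrates
internal correctness of the estimators and detectors — not robustness to
real-data pathologies upstream of the modeled layer.

## Simulation scale and statistical checks

The packaged checks use problem sizes chosen to make the statistical
properties measurable on a desk machine: likelihood-oracle equivalence
on 200 random instances of up to 4 taxa and 3 codons; M0 recovery at 500
codons and 8 taxa over 20 seeds (median omega error within 0.05); LRT
null calibration for CmC vs M2a_rel on 200 replicates of 300 codons
(empirical type-I error within [0.02, 0.09] at alpha = 0.05); clade
model C parameter recovery at 800 codons and 12 taxa (median omega2
error per clade within 0.1 over 20 seeds); and power under the
relaxation regime the package targets (background omega2 = 0.3 vs clade
omega2 = 1.0, 800 codons, 50 replicates, at least 80% rejection).

Taxon counts matter for mixtures. Single-class models (M0, branch) are
well identified even on 6 taxa — their df = 1 LRT calibrates exactly at
these sizes — but the three-class mixture likelihood on a 6-taxon tree
is a ridge: very different (omega2, proportions) combinations sit
within a few log-likelihood units, parameter recovery fails even at
3000 codons, and the chi-square approximation for CmC vs M2a_rel runs
hot. On a 12-taxon two-clade tree the class structure is identifiable,
recovery is accurate and the LRT calibrates. Mixture-model calibration
and recovery checks therefore run on 12 taxa; the power check stays on
the 6-taxon tree, where the planted relaxation is already detected
decisively. `scripts/acceptance.R` re-runs scaled versions of the same
computations from scratch and reports the numbers it measures.

## Known limitations

* Branch lengths are taken from the input tree; misspecified lengths
  bias omega structure fits.
* Mixture-model LRTs (CmC vs M2a_rel) can run mildly hot in finite
  samples even though regular branch-model LRTs calibrate exactly on
  the same data sizes; the packaged calibration study measures the
  empirical rate rather than assuming nominal behavior, and users
  drawing conclusions near alpha should prefer parametric-bootstrap
  p-values.
* The chi-square(1) reference for branch-site model A is conservative.
* The motif library is a pragmatic condensation of published consensi;
  calibrating per-motif mismatch allowances against real deposited
  records is the user's responsibility when absolute coordinates matter.
* `find_hairpin` scores pairing, not free energy; candidates are
  structural hypotheses only.
* The pipeline functions (`runCharacterize`, `runDivergence`,
  `runSelection`, `runSimulate`) are the orchestration surface; they are
  plain R functions over configs rather than a shell executable, which
  keeps them scriptable and testable from R.
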